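#' Experimental design descriptions
#'
#' Constructors for the 2AFC designs used throughout the package. A design
#' is a plain list describing the factorial layout of one task:
#' \describe{
#'   \item{task}{"position" or "speed".}
#'   \item{eccentricities}{stimulus eccentricities in degrees of visual angle.}
#'   \item{durations}{stimulus durations in ms.}
#'   \item{levels}{signed stimulus-difference levels; degrees of vertical
#'     offset for the position task, deg/s of reference-minus-test speed for
#'     the speed task.}
#'   \item{reps_per_level}{repetitions of each level within each design cell.}
#'   \item{include_static_control}{whether a static-texture control condition
#'     (coded as duration 0) is included.}
#' }
#'
#' `exp1_position_design()` is the eccentricity-series position task:
#' 20 equally spaced pair offsets spanning -2 to 1 deg, 8 repetitions, at
#' 5, 10 and 15 deg eccentricity (480 trials). `exp1_speed_design()` is the
#' matching speed task: reference speeds 4 to 13 deg/s in 10 equal steps
#' (levels stored relative to the 10 deg/s test speed), 16 repetitions
#' (480 trials). `exp2_design()` is the duration series at 10 deg
#' eccentricity: durations 31, 55, 98, 175, 313, 559 and 1000 ms plus an
#' optional 31-ms static-texture control, 800 trials in total.
#'
#' @param include_static_control logical; include the static control cell.
#' @return A `mips_design` list as described above.
#' @export
exp1_position_design <- function() {
  new_design(
    task = "position",
    eccentricities = c(5, 10, 15),
    durations = 1000,
    levels = seq(-2, 1, length.out = 20),
    reps_per_level = 8L
  )
}

#' @rdname exp1_position_design
#' @export
exp1_speed_design <- function() {
  new_design(
    task = "speed",
    eccentricities = c(5, 10, 15),
    durations = 1000,
    levels = seq(4, 13, length.out = 10) - 10,
    reps_per_level = 16L
  )
}

#' @rdname exp1_position_design
#' @export
exp2_design <- function(include_static_control = TRUE) {
  # 8 conditions x 20 levels x 5 reps = 800 trials matches the stated total
  new_design(
    task = "position",
    eccentricities = 10,
    durations = c(31, 55, 98, 175, 313, 559, 1000),
    levels = seq(-2, 1, length.out = 20),
    reps_per_level = 5L,
    include_static_control = include_static_control
  )
}

#' @keywords internal
new_design <- function(task, eccentricities, durations, levels,
                       reps_per_level, include_static_control = FALSE) {
  task <- match.arg(task, c("position", "speed"))
  stopifnot(length(levels) > 0, !is.unsorted(levels, strictly = TRUE),
            reps_per_level >= 1, all(eccentricities > 0), all(durations > 0))
  exp2_set <- c(31, 55, 98, 175, 313, 559, 1000)
  if (length(durations) > 1 && !all(durations %in% exp2_set))
    stop("duration-series designs must use durations from {",
         paste(exp2_set, collapse = ", "), "} ms")
  structure(list(
    task = task,
    eccentricities = as.numeric(eccentricities),
    durations = as.numeric(durations),
    levels = as.numeric(levels),
    reps_per_level = as.integer(reps_per_level),
    include_static_control = isTRUE(include_static_control)
  ), class = "mips_design")
}

#' Enumerate the condition cells of a design
#'
#' @param design a `mips_design`.
#' @return data.frame with columns `eccentricity_deg`, `duration_ms` and the
#'   cell label used to index observer parameters (the static control is
#'   coded as duration 0).
#' @export
design_cells <- function(design) {
  cells <- expand.grid(eccentricity_deg = design$eccentricities,
                       duration_ms = design$durations)
  if (design$include_static_control)
    cells <- rbind(cells, data.frame(eccentricity_deg = design$eccentricities[1],
                                     duration_ms = 0))
  cells$cell <- cell_label(cells$eccentricity_deg, cells$duration_ms)
  cells
}

#' @keywords internal
cell_label <- function(ecc, dur) sprintf("ecc%g_dur%g", ecc, dur)

#' Group-level population hyperparameters
#'
#' Describes the population distribution of psychometric parameters within
#' one age group for one design cell: the point of subjective equality mu
#' follows a t distribution (location, scale, df), the slope sigma a gamma
#' distribution (mean/sd parameterisation), and the lapse rate a Gaussian
#' truncated below at 0 and capped at 0.5.
#'
#' @param mu_location,mu_scale,mu_df t-distribution parameters for mu
#'   (stimulus units; `mu_scale > 0`, `mu_df > 0`).
#' @param sigma_mean,sigma_sd gamma mean and sd for sigma (stimulus units,
#'   both > 0).
#' @param lapse_mean,lapse_sd truncated-Gaussian parameters for the lapse
#'   probability (`lapse_sd > 0`).
#' @return A `group_hyper` list.
#' @export
group_hyper <- function(mu_location, mu_scale, mu_df,
                        sigma_mean, sigma_sd,
                        lapse_mean = 0.03, lapse_sd = 0.02) {
  if (!(mu_scale > 0) || !(mu_df > 0))
    stop("mu_scale and mu_df must be positive")
  if (!(sigma_mean > 0) || !(sigma_sd > 0))
    stop("sigma_mean and sigma_sd must be positive")
  if (!(lapse_sd > 0)) stop("lapse_sd must be positive")
  structure(list(mu_location = mu_location, mu_scale = mu_scale,
                 mu_df = mu_df, sigma_mean = sigma_mean, sigma_sd = sigma_sd,
                 lapse_mean = lapse_mean, lapse_sd = lapse_sd),
            class = "group_hyper")
}

#' Reference population hyperparameters for the eccentricity-series tasks
#'
#' Fixture populations for the two age groups on the eccentricity-series
#' position and speed tasks, one `group_hyper` per design cell. The PSE
#' locations are anchored to the group and per-eccentricity means of the
#' study the designs emulate (position: per-stimulus MIPS of 0.26 deg in
#' young and 0.75 deg in older adults, overall 0.34 deg at 5 deg rising to
#' 0.67 deg at 15 deg; speed: overall bias -0.76 deg/s at 5 deg falling to
#' -2.78 deg/s at 15 deg, no group effect). Position locations are stored on
#' the pair-offset axis (PSE = -2 x per-stimulus shift; see
#' [per_stimulus_shift()]). Dispersion and slope levels are calibrated to
#' the reported group ratios of response variability (about 3.5x in the
#' position task, 2x in the speed task) and credible-interval widths; they
#' are package fixtures, not measured quantities.
#'
#' @param group "young" or "older".
#' @param task "position" or "speed".
#' @return Named list of `group_hyper`, keyed by design-cell label.
#' @export
default_group_hyper <- function(group = c("young", "older"),
                                task = c("position", "speed")) {
  group <- match.arg(group)
  task <- match.arg(task)
  ecc <- c(5, 10, 15)
  if (task == "position") {
    # additive decomposition: group mean + eccentricity effect (sums to 0)
    g <- if (group == "young") 0.26 else 0.75
    e <- c(0.34, NA, 0.67) - (17 * 0.75 + 19 * 0.26) / 36
    e[2] <- -(e[1] + e[3])
    shift <- g + e
    mu <- -2 * shift                      # pair-offset PSE
    mu_scale <- if (group == "young") 0.5 else 1.2
    sig <- if (group == "young") sqrt(2) * c(0.20, 0.28, 0.36)
           else sqrt(2) * c(0.89, 0.98, 1.08)
    sig_sd <- 0.3 * sig
  } else {
    mu <- c(-0.76, -1.77, -2.78)          # PSE relative to the 10 deg/s test
    mu_scale <- if (group == "young") 0.9 else 1.4
    sig <- if (group == "young") c(1.45, 1.30, 1.15) else c(2.75, 2.65, 2.55)
    sig_sd <- 0.3 * sig
  }
  out <- lapply(seq_along(ecc), function(i)
    group_hyper(mu_location = mu[i], mu_scale = mu_scale, mu_df = 15,
                sigma_mean = sig[i], sigma_sd = sig_sd[i]))
  names(out) <- cell_label(ecc, 1000)
  out
}

#' Reference temporal-model parameters for the duration-series task
#'
#' Group-mean parameters of the three-line MIPS time course
#' (`t1, m1, t2, m2`) for each age group, matching the reported group means
#' of the duration-series experiment: young 76 ms / 0.46 deg / 180 ms /
#' 0.25 deg; older 56 ms / 1.00 deg / 183 ms / 0.71 deg.
#'
#' @param group "young" or "older".
#' @return A `piecewise_params` object (see [piecewise_params()]).
#' @export
default_piecewise_params <- function(group = c("young", "older")) {
  group <- match.arg(group)
  if (group == "young") piecewise_params(76, 0.46, 180, 0.25)
  else piecewise_params(56, 1.00, 183, 0.71)
}
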