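#' Draw a synthetic observer population
#'
#' Samples per-participant psychometric parameters from group-level
#' distributions: mu from a t distribution, sigma from a gamma distribution
#' (mean/sd parameterisation), and the lapse rate from a Gaussian truncated
#' below at 0 and clipped at 0.5.
#'
#' Reproducibility: a root seed is expanded into one sub-seed per observer
#' (the first `n` draws of `sample.int(.Machine$integer.max)` under the root
#' seed), and each observer's parameters are generated under their own
#' sub-seed. Growing `n` therefore extends the population without perturbing
#' earlier observers.
#'
#' @param hypers a single [group_hyper()] or a named list of them, one per
#'   design-cell label (see [design_cells()]).
#' @param n number of observers (>= 1).
#' @param seed integer root seed.
#' @param group group label attached to each observer ("young"/"older").
#' @param id_prefix prefix for participant identifiers.
#' @return List of observers; each has `participant_id`, `group`, and
#'   `params`, a named list of `(mu, sigma, lapse)` per cell.
#' @export
draw_population <- function(hypers, n, seed, group = "young",
                            id_prefix = group) {
  if (inherits(hypers, "group_hyper")) hypers <- list(cell = hypers)
  stopifnot(n >= 1, length(hypers) >= 1, !is.null(names(hypers)))
  lapply(hypers, function(h) {
    if (!inherits(h, "group_hyper")) stop("hypers must be group_hyper objects")
  })
  sub <- derive_subseeds(seed, n)
  lapply(seq_len(n), function(i) {
    set.seed(sub[i])
    params <- lapply(hypers, function(h) {
      mu <- h$mu_location + h$mu_scale * rt(1, df = h$mu_df)
      shape <- (h$sigma_mean / h$sigma_sd)^2
      rate <- h$sigma_mean / h$sigma_sd^2
      sigma <- rgamma(1, shape = shape, rate = rate)
      lapse <- min(rnorm_left_trunc(1, h$lapse_mean, h$lapse_sd), 0.5)
      list(mu = mu, sigma = sigma, lapse = lapse)
    })
    list(participant_id = sprintf("%s%02d", id_prefix, i),
         group = group, params = params)
  })
}

#' @keywords internal
derive_subseeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

# Gaussian truncated below at 0, by inverse-CDF sampling.
#' @keywords internal
rnorm_left_trunc <- function(n, mean, sd) {
  p0 <- pnorm(0, mean, sd)
  u <- runif(n, p0, 1)
  qnorm(u, mean, sd)
}

#' Simulate 2AFC trials for one observer
#'
#' Generates Bernoulli responses under the cumulative-Gaussian-with-lapse
#' psychometric model: `P(response = 1 | x) = lapse/2 +
#' (1 - lapse) * pnorm((x - mu) / sigma)`, where `response = 1` is the
#' choice consistent with a positive stimulus difference.
#'
#' @param truth an observer as returned by [draw_population()].
#' @param design a `mips_design`.
#' @param seed integer seed.
#' @return data.frame of trials with columns `participant_id`, `group`,
#'   `task`, `eccentricity_deg`, `duration_ms`, `level`, `response`.
#' @export
simulate_trials <- function(truth, design, seed) {
  cells <- design_cells(design)
  missing <- setdiff(cells$cell, names(truth$params))
  if (length(missing))
    stop("observer lacks parameters for design cells: ",
         paste(missing, collapse = ", "))
  set.seed(as.integer(seed))
  out <- lapply(seq_len(nrow(cells)), function(k) {
    p <- truth$params[[cells$cell[k]]]
    lev <- rep(design$levels, each = design$reps_per_level)
    pr <- psychometric_probability(lev, p$mu, p$sigma, p$lapse)
    data.frame(participant_id = truth$participant_id,
               group = truth$group,
               task = design$task,
               eccentricity_deg = cells$eccentricity_deg[k],
               duration_ms = cells$duration_ms[k],
               level = lev,
               response = rbinom(length(lev), 1, pr))
  })
  do.call(rbind, out)
}

#' Simulate a full group of observers on one design
#'
#' Convenience wrapper: draws a population and simulates every observer,
#' using per-observer sub-seeds derived from the root seed.
#'
#' @inheritParams draw_population
#' @param design a `mips_design`.
#' @return List with `trials` (one tidy data.frame) and `truth` (the
#'   population as drawn).
#' @export
simulate_group <- function(hypers, n, design, seed, group = "young") {
  pop <- draw_population(hypers, n, seed, group = group)
  trial_seeds <- derive_subseeds(seed + 1L, n)
  trials <- do.call(rbind, lapply(seq_len(n), function(i)
    simulate_trials(pop[[i]], design, trial_seeds[i])))
  list(trials = trials, truth = pop)
}

#' Sample a noisy MIPS-versus-duration profile
#'
#' Evaluates the three-line temporal model (see [piecewise_value()]) at the
#' requested durations and adds Gaussian measurement noise.
#'
#' @param params a [piecewise_params()].
#' @param durations durations in ms, within (0, 1000].
#' @param noise_sd Gaussian noise sd in deg (>= 0).
#' @param seed integer seed (ignored when `noise_sd = 0`).
#' @return data.frame with columns `duration_ms`, `shift_deg`.
#' @export
generate_piecewise_profile <- function(params, durations, noise_sd = 0,
                                       seed = 1) {
  stopifnot(all(durations > 0), all(durations <= 1000), noise_sd >= 0)
  mu <- piecewise_value(params, durations)
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    mu <- mu + rnorm(length(mu), 0, noise_sd)
  }
  data.frame(duration_ms = durations, shift_deg = mu)
}

#' Noiseless response-variability profile of the optimal integrator
#'
#' Delegates to [forward_profile()]: the model's predicted response
#' standard deviation at each duration.
#'
#' @param params an [integrator_params()].
#' @param durations durations in ms.
#' @return data.frame with columns `duration_ms`, `sigma_deg`.
#' @export
generate_variability_profile <- function(params, durations) {
  forward_profile(params, durations)
}

#' Read or write the tidy trial table
#'
#' The on-disk interchange format is a plain CSV with one row per trial and
#' columns `participant_id, group, task, eccentricity_deg, duration_ms,
#' level, response`.
#'
#' @param trials trial data.frame.
#' @param path file path.
#' @return `read_trials` returns the trial data.frame.
#' @export
write_trials <- function(trials, path) {
  cols <- c("participant_id", "group", "task", "eccentricity_deg",
            "duration_ms", "level", "response")
  stopifnot(all(cols %in% names(trials)))
  write.csv(trials[cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(tr$response %in% c(0, 1)))
  tr
}

#' Persist ground-truth observer parameters
#'
#' Writes the population drawn by [draw_population()] as a YAML sidecar
#' mapping participant to per-cell `(mu, sigma, lapse)`.
#'
#' @param truth population list.
#' @param path output file path.
#' @export
write_truth <- function(truth, path) {
  obj <- lapply(truth, function(o)
    list(group = o$group,
         params = lapply(o$params, function(p)
           list(mu = p$mu, sigma = p$sigma, lapse = p$lapse))))
  names(obj) <- vapply(truth, `[[`, "", "participant_id")
  yaml::write_yaml(obj, path)
  invisible(path)
}
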