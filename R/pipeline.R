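#' Deterministic per-stage sub-seed
#'
#' Derives a stage seed from the root seed and the stage name: the UTF-8
#' code points of the name are folded with a multiplicative hash
#' (multiplier 131) and combined with the root seed modulo 2^31 - 2.
#' Every stochastic stage of [run_pipeline()] draws its seed through this
#' function, so runs are bit-reproducible and stages are decoupled.
#'
#' @param root integer root seed.
#' @param stage stage name.
#' @return Integer sub-seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(root, stage) {
  h <- 0
  for (cp in utf8ToInt(stage)) h <- (h * 131 + cp) %% (2^31 - 2)
  as.integer((h + as.numeric(root)) %% (2^31 - 2) + 1)
}

#' Reference hyperparameters for the duration-series position task
#'
#' Fixture populations for the duration-series design: per-duration pair
#' PSE locations follow the group-mean three-line time course (see
#' [default_piecewise_params()]), and per-duration pair sigma levels follow
#' an exponential decay toward an asymptote, with the older group's levels
#' scaled to the reported variability ratios. The static control (duration
#' 0) has zero true shift.
#'
#' @inheritParams default_group_hyper
#' @param include_static_control include the control cell.
#' @return Named list of [group_hyper()] keyed by design-cell label.
#' @export
default_group_hyper_exp2 <- function(group = c("young", "older"),
                                     include_static_control = TRUE) {
  group <- match.arg(group)
  pw <- default_piecewise_params(group)
  dec <- if (group == "young") decay_params(0.8, 0.01, 0.35)
         else decay_params(2.2, 0.01, 1.0)
  dur <- c(31, 55, 98, 175, 313, 559, 1000)
  if (include_static_control) dur <- c(dur, 0)
  out <- lapply(dur, function(d) {
    shift <- if (d == 0) 0 else piecewise_value(pw, d)
    sig1 <- decay_value(dec, max(d, 31))
    group_hyper(mu_location = -2 * shift,
                mu_scale = if (group == "young") 0.4 else 0.9,
                mu_df = 15,
                sigma_mean = sqrt(2) * sig1,
                sigma_sd = 0.3 * sqrt(2) * sig1)
  })
  names(out) <- cell_label(10, dur)
  out
}

#' Run the full simulate-screen-fit-analyse pipeline
#'
#' Orchestrates one end-to-end run from a single config: simulate both
#' groups on the requested design, screen participants, fit psychometric
#' functions, derive the task-specific measures, and write all intermediate
#' tables plus a JSON manifest to the output directory. All randomness is
#' governed by `config$seed` through [derive_seed()]; re-running the same
#' config reproduces every artifact bit-identically.
#'
#' @param config list (or path to a YAML file) with fields:
#'   \describe{
#'     \item{experiment}{"exp1", "exp2" or "recovery".}
#'     \item{seed}{root seed (integer).}
#'     \item{n_young, n_older}{group sizes (defaults 19 and 17 for exp1;
#'       8 and 10 for exp2).}
#'     \item{fit_method}{"mle" (default) or "hierarchical".}
#'     \item{sampler}{list of [fit_hierarchical()] settings when
#'       hierarchical.}
#'     \item{out_dir}{output directory.}
#'   }
#' @return The run manifest (list), invisibly written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  experiment <- match.arg(config$experiment, c("exp1", "exp2", "recovery"))
  stopifnot(!is.null(config$seed), !is.null(config$out_dir))
  out_dir <- config$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fit_method <- if (is.null(config$fit_method)) "mle" else config$fit_method
  n_young <- if (is.null(config$n_young)) {
    if (experiment == "exp2") 8L else 19L
  } else config$n_young
  n_older <- if (is.null(config$n_older)) {
    if (experiment == "exp2") 10L else 17L
  } else config$n_older
  seeds <- list(simulate_young = derive_seed(config$seed, "simulate_young"),
                simulate_older = derive_seed(config$seed, "simulate_older"),
                fit = derive_seed(config$seed, "fit"))
  if (experiment %in% c("exp1", "recovery")) {
    design <- exp1_position_design()
    hy <- default_group_hyper("young", "position")
    ho <- default_group_hyper("older", "position")
  } else {
    design <- exp2_design()
    hy <- default_group_hyper_exp2("young")
    ho <- default_group_hyper_exp2("older")
  }
  gy <- simulate_group(hy, n_young, design, seeds$simulate_young, "young")
  go <- simulate_group(ho, n_older, design, seeds$simulate_older, "older")
  trials <- rbind(gy$trials, go$trials)
  write_trials(trials, file.path(out_dir, "trials.csv"))
  write_truth(c(gy$truth, go$truth), file.path(out_dir, "truth.yaml"))

  params <- fit_all_participants(trials, fit_method, seeds$fit,
                                 config$sampler)
  params$mips_deg <- mips_size(params$mu)
  params$noise_deg <- per_stimulus_noise(params$sigma)
  write.csv(params, file.path(out_dir, "psychometric_params.csv"),
            row.names = FALSE)

  metrics <- list()
  if (experiment %in% c("exp1", "recovery")) {
    byg <- split(params, params$group)
    metrics$group_mean_mips <- lapply(byg, function(p)
      mean(tapply(p$mips_deg, p$participant_id, mean)))
    metrics$fold_ratio <-
      metrics$group_mean_mips$older / metrics$group_mean_mips$young
    avg <- tapply(params$mips_deg, params$participant_id, mean)
    grp <- params$group[match(names(avg), params$participant_id)]
    wt <- welch_t(avg[grp == "older"], avg[grp == "young"])
    metrics$welch_age <- wt[c("t", "df", "p", "d")]
    if (experiment == "recovery") {
      truth_tab <- truth_table(c(gy$truth, go$truth))
      cmp <- merge(params, truth_tab,
                   by = c("participant_id", "eccentricity_deg",
                          "duration_ms"), suffixes = c("_hat", "_true"))
      write.csv(cmp, file.path(out_dir, "recovery.csv"), row.names = FALSE)
      metrics$mu_rmse <- sqrt(mean((cmp$mu_hat - cmp$mu_true)^2))
    }
  } else {
    shifts <- params[params$duration_ms %in% c(31, 55), ]
    by_gd <- tapply(shifts$mips_deg, list(shifts$group, shifts$duration_ms),
                    mean)
    metrics$initial_rate <- list(
      young = initial_rate(by_gd["young", "31"], by_gd["young", "55"]),
      older = initial_rate(by_gd["older", "31"], by_gd["older", "55"]))
  }
  manifest <- list(package_version = as.character(utils::packageVersion("mipsage")),
                   experiment = experiment, seed = config$seed,
                   seeds = seeds, n_young = n_young, n_older = n_older,
                   fit_method = fit_method,
                   files = list(trials = "trials.csv", truth = "truth.yaml",
                                params = "psychometric_params.csv"),
                   metrics = metrics)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' @keywords internal
truth_table <- function(truth) {
  do.call(rbind, lapply(truth, function(o) {
    cells <- names(o$params)
    ecc <- as.numeric(sub("ecc([0-9.]+)_dur.*", "\\1", cells))
    dur <- as.numeric(sub(".*_dur([0-9.]+)", "\\1", cells))
    data.frame(participant_id = o$participant_id, group = o$group,
               eccentricity_deg = ecc, duration_ms = dur,
               mu = vapply(o$params, `[[`, 0, "mu"),
               sigma = vapply(o$params, `[[`, 0, "sigma"),
               lapse = vapply(o$params, `[[`, 0, "lapse"),
               row.names = NULL)
  }))
}

# Fit every participant x cell; MLE path, or hierarchical per group.
#' @keywords internal
fit_all_participants <- function(trials, method, seed, sampler = NULL) {
  method <- match.arg(method, c("mle", "hierarchical"))
  if (method == "mle") {
    cells <- unique(trials[c("participant_id", "group", "eccentricity_deg",
                             "duration_ms")])
    rows <- lapply(seq_len(nrow(cells)), function(i) {
      sub <- trials[trials$participant_id == cells$participant_id[i] &
                    trials$eccentricity_deg == cells$eccentricity_deg[i] &
                    trials$duration_ms == cells$duration_ms[i], ]
      f <- fit_single_mle(sub)
      data.frame(cells[i, ],
                 mu = if (f$converged) f$params$mu else NA_real_,
                 sigma = if (f$converged) f$params$sigma else NA_real_,
                 lapse = if (f$converged) f$params$lapse else NA_real_,
                 converged = f$converged, row.names = NULL)
    })
    return(na.omit(do.call(rbind, rows)))
  }
  sampler <- utils::modifyList(
    list(chains = 4, n_adapt = 500, n_burn = 500, n_draws = 1000),
    if (is.null(sampler)) list() else sampler)
  out <- lapply(unique(trials$group), function(g) {
    fit <- fit_hierarchical(trials[trials$group == g, ], seed = seed,
                            chains = sampler$chains,
                            n_adapt = sampler$n_adapt,
                            n_burn = sampler$n_burn,
                            n_draws = sampler$n_draws)
    pp <- participant_posterior(fit)
    pp$group <- g
    pp$converged <- TRUE
    pp
  })
  do.call(rbind, out)
}
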