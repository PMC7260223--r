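# Hierarchical Bayesian psychometric model, one JAGS model per design cell.
#
# Participant-level (mu_j, sigma_j, lapse_j) are drawn from group-level
# distributions: t (location, scale, df) for mu, gamma (mean/sd) for sigma,
# left-truncated Gaussian for the lapse. Hyperpriors: uniform on the group
# means, gamma on the group SDs, exponential (mean 30) on the t df.
hier_model_string <- "model {
  for (i in 1:N) {
    r[i] ~ dbin(psi[i], n[i])
    psi[i] <- lapse[pid[i]] / 2 +
      (1 - lapse[pid[i]]) * phi((x[i] - mu[pid[i]]) / sigma[pid[i]])
  }
  for (j in 1:P) {
    mu[j] ~ dt(mu_loc, pow(mu_scale, -2), mu_df)
    sigma[j] ~ dgamma(g_shape, g_rate) T(sig_floor, )
    lapse[j] ~ dnorm(lapse_mean, pow(lapse_sd, -2)) T(0, 0.5)
  }
  mu_loc ~ dunif(mu_lo, mu_hi)
  mu_scale ~ dgamma(sd_shape, sd_rate)
  mu_df ~ dexp(df_rate)
  sigma_mean ~ dunif(sig_floor, sig_cap)
  sigma_sd ~ dgamma(sd_shape, sd_rate)
  g_shape <- pow(sigma_mean / sigma_sd, 2)
  g_rate <- sigma_mean / pow(sigma_sd, 2)
  lapse_mean ~ dunif(0, 0.5)
  lapse_sd ~ dgamma(2, 40)
  mu_mean <- mean(mu)
}"

#' Hierarchical Bayesian psychometric fit for one age group
#'
#' Fits, independently for every design cell (eccentricity x duration) in
#' the supplied trials, a hierarchical cumulative-Gaussian-with-lapse model
#' in which participant-level parameters follow group-level distributions
#' (t for mu, gamma for sigma, left-truncated Gaussian for the lapse) whose
#' hyperparameters carry weakly informative hyperpriors: uniform group means
#' spanning five times the stimulus range, gamma priors on group SDs, and an
#' exponential prior (mean 30) on the t degrees of freedom. Posteriors are
#' sampled with JAGS; runs are deterministic given `seed` and the sampler
#' settings.
#'
#' @param trials tidy trial data.frame for one group (columns
#'   `participant_id`, `eccentricity_deg`, `duration_ms`, `level`,
#'   `response`).
#' @param seed integer seed; per-chain RNG seeds are derived from it.
#' @param chains number of MCMC chains (default 4).
#' @param n_adapt,n_burn,n_draws adaptation, burn-in and retained
#'   iterations per chain.
#' @param screen if `TRUE`, participants failing [screen_participant()] in a
#'   cell are dropped from that cell's fit (with a message).
#' @param rhat_threshold convergence threshold on the split-chain potential
#'   scale reduction factor (default 1.01). Exceeding it triggers a warning;
#'   results are still returned with `converged = FALSE`.
#' @param level credible-interval mass for the summaries.
#' @param quiet suppress JAGS progress output.
#' @return Object of class `mips_hfit`: a list with one element per cell,
#'   each containing `eccentricity_deg`, `duration_ms`, `participants`,
#'   `summary` (posterior mean, central CI, Rhat and effective sample size
#'   for every monitored parameter), `draws` (iterations x parameters
#'   matrix, chains stacked), `rhat_max` and `converged`.
#' @export
fit_hierarchical <- function(trials, seed, chains = 4, n_adapt = 500,
                             n_burn = 500, n_draws = 1000, screen = TRUE,
                             rhat_threshold = 1.01, level = 0.95,
                             quiet = TRUE) {
  stopifnot(length(unique(trials$participant_id)) >= 2)
  cells <- unique(trials[c("eccentricity_deg", "duration_ms")])
  cells <- cells[order(cells$eccentricity_deg, cells$duration_ms), ]
  out <- lapply(seq_len(nrow(cells)), function(k) {
    sub <- trials[trials$eccentricity_deg == cells$eccentricity_deg[k] &
                  trials$duration_ms == cells$duration_ms[k], ]
    fit_hier_cell(sub, seed = (as.numeric(seed) + k) %% (2^31 - 1),
                  chains = chains, n_adapt = n_adapt,
                  n_burn = n_burn, n_draws = n_draws, screen = screen,
                  rhat_threshold = rhat_threshold, level = level,
                  quiet = quiet)
  })
  names(out) <- cell_label(cells$eccentricity_deg, cells$duration_ms)
  structure(out, class = "mips_hfit")
}

#' @keywords internal
fit_hier_cell <- function(sub, seed, chains, n_adapt, n_burn, n_draws,
                          screen, rhat_threshold, level, quiet) {
  ids <- sort(unique(sub$participant_id))
  if (screen) {
    keep <- vapply(ids, function(id)
      screen_participant(sub[sub$participant_id == id, ])$pass, logical(1))
    if (any(!keep))
      message("dropping non-systematic participant(s): ",
              paste(ids[!keep], collapse = ", "))
    ids <- ids[keep]
    sub <- sub[sub$participant_id %in% ids, ]
  }
  if (length(ids) < 2) stop("need at least 2 screened participants")
  agg <- do.call(rbind, lapply(seq_along(ids), function(j) {
    a <- aggregate_levels(sub[sub$participant_id == ids[j], ])
    a$pid <- j
    a
  }))
  span <- diff(range(agg$level))
  dat <- list(N = nrow(agg), P = length(ids), r = agg$k, n = agg$n,
              x = agg$level, pid = agg$pid,
              mu_lo = min(agg$level) - 2 * span,
              mu_hi = max(agg$level) + 2 * span,
              sig_floor = span / 1000, sig_cap = 5 * span,
              sd_shape = 2, sd_rate = 2 / span, df_rate = 1 / 30)
  inits <- lapply(seq_len(chains), function(ch)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer((as.numeric(seed) * 10 + ch) %% (2^31 - 1)),
         mu_loc = mean(agg$level), mu_scale = span / 4, mu_df = 10,
         sigma_mean = span / 4, sigma_sd = span / 8,
         lapse_mean = 0.03, lapse_sd = 0.02,
         mu = rep(mean(agg$level), length(ids)),
         sigma = rep(span / 4, length(ids)),
         lapse = rep(0.03, length(ids))))
  run <- function() {
    m <- rjags::jags.model(textConnection(hier_model_string), data = dat,
                           inits = inits, n.chains = chains,
                           n.adapt = n_adapt, quiet = quiet)
    update(m, n_burn, progress.bar = "none")
    rjags::coda.samples(
      m, c("mu", "sigma", "lapse", "mu_loc", "mu_scale", "mu_df",
           "sigma_mean", "sigma_sd", "lapse_mean", "mu_mean"),
      n.iter = n_draws, progress.bar = "none")
  }
  samp <- if (quiet) suppressWarnings(run()) else run()
  summ <- summarise_posterior(samp, level)
  rhat_max <- max(summ$rhat, na.rm = TRUE)
  converged <- is.finite(rhat_max) && rhat_max < rhat_threshold
  if (!converged)
    warning(sprintf("max Rhat = %.3f exceeds threshold %.3f", rhat_max,
                    rhat_threshold))
  list(eccentricity_deg = sub$eccentricity_deg[1],
       duration_ms = sub$duration_ms[1],
       participants = ids,
       summary = summ,
       draws = do.call(rbind, lapply(samp, as.matrix)),
       rhat_max = rhat_max,
       converged = converged)
}

#' @keywords internal
summarise_posterior <- function(samp, level = 0.95) {
  mat <- do.call(rbind, lapply(samp, as.matrix))
  a <- (1 - level) / 2
  est <- colMeans(mat)
  lo <- apply(mat, 2, quantile, probs = a)
  hi <- apply(mat, 2, quantile, probs = 1 - a)
  rhat <- rep(NA_real_, ncol(mat))
  if (length(samp) >= 2) {
    gd <- tryCatch(coda::gelman.diag(samp, autoburnin = FALSE,
                                     multivariate = FALSE)$psrf[, 1],
                   error = function(e) rep(NA_real_, ncol(mat)))
    rhat <- gd[colnames(mat)]
  }
  neff <- tryCatch(coda::effectiveSize(samp)[colnames(mat)],
                   error = function(e) rep(NA_real_, ncol(mat)))
  data.frame(param = colnames(mat), mean = unname(est), ci_low = unname(lo),
             ci_high = unname(hi), rhat = unname(rhat),
             n_eff = unname(neff), row.names = NULL)
}

#' Extract posterior summaries of group-level quantities
#'
#' @param fit a `mips_hfit`.
#' @param param monitored quantity: `"mu_loc"` (group-level t location),
#'   `"mu_mean"` (mean of participant-level mu), `"sigma_mean"`, or
#'   `"lapse_mean"`.
#' @return data.frame with one row per cell: `eccentricity_deg`,
#'   `duration_ms`, posterior `mean`, `ci_low`, `ci_high`, `rhat`.
#' @export
group_posterior <- function(fit, param = "mu_mean") {
  stopifnot(inherits(fit, "mips_hfit"))
  do.call(rbind, lapply(fit, function(cell) {
    row <- cell$summary[cell$summary$param == param, ]
    data.frame(eccentricity_deg = cell$eccentricity_deg,
               duration_ms = cell$duration_ms, mean = row$mean,
               ci_low = row$ci_low, ci_high = row$ci_high, rhat = row$rhat,
               row.names = NULL)
  }))
}

#' Posterior means of participant-level psychometric parameters
#'
#' @param fit a `mips_hfit`.
#' @return data.frame with one row per participant x cell: posterior means
#'   of `mu`, `sigma` and `lapse`.
#' @export
participant_posterior <- function(fit) {
  stopifnot(inherits(fit, "mips_hfit"))
  do.call(rbind, lapply(fit, function(cell) {
    idx <- seq_along(cell$participants)
    pick <- function(stub) {
      nm <- if (length(idx) > 1) sprintf("%s[%d]", stub, idx) else stub
      cell$summary$mean[match(nm, cell$summary$param)]
    }
    data.frame(participant_id = cell$participants,
               eccentricity_deg = cell$eccentricity_deg,
               duration_ms = cell$duration_ms,
               mu = pick("mu"), sigma = pick("sigma"), lapse = pick("lapse"),
               row.names = NULL)
  }))
}
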