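#' Optimal sequential-integrator parameters
#'
#' The observer updates a position estimate from discrete sensory samples
#' arriving every `dt` ms. Each sample carries Gaussian sensory noise of
#' variance `sigma_s2`; between samples the internal estimate accrues
#' Gaussian propagation noise of variance `sigma_p2` (memory/prediction
#' noise). The estimate is combined with each new sample using the optimal
#' (inverse-variance) weights.
#'
#' @param sigma_s2 per-sample sensory noise variance, deg^2 (> 0).
#' @param sigma_p2 per-step propagation noise variance, deg^2 (>= 0).
#' @param dt step duration in ms (> 0); defaults to one 360-Hz display
#'   frame, 1000/360 ms.
#' @return An `integrator_params` object.
#' @export
integrator_params <- function(sigma_s2, sigma_p2, dt = 1000 / 360) {
  if (!(sigma_s2 > 0)) stop("sigma_s2 must be positive")
  if (sigma_p2 < 0) stop("sigma_p2 must be non-negative")
  if (!(dt > 0)) stop("dt must be positive")
  structure(list(sigma_s2 = sigma_s2, sigma_p2 = sigma_p2, dt = dt),
            class = "integrator_params")
}

#' One variance-update step of the optimal integrator
#'
#' Applies the coupled variance recursions. With prior variance
#' `sigma_n2 + sigma_p2` (internal estimate plus propagation noise) and
#' sample variance `sigma_s2`, the optimal weights are
#' `w_prior = sigma_s2 / S` and `w_sample = (sigma_n2 + sigma_p2) / S` with
#' `S = sigma_n2 + sigma_p2 + sigma_s2`. The internal (percept) variance
#' updates as `w_prior^2 * (sigma_n2 + sigma_p2) + w_sample^2 * sigma_s2`;
#' the variance of measurable responses updates with the same weights but
#' carries forward the previous response variance without the propagation
#' term: `w_prior^2 * sigma_m2 + w_sample^2 * sigma_s2`.
#'
#' @param state list with `sigma_n2`, `sigma_m2` (deg^2) and `step`.
#' @param params an [integrator_params()].
#' @return Updated state with incremented `step`.
#' @export
propagate <- function(state, params) {
  stopifnot(state$sigma_n2 > 0, state$sigma_m2 > 0)
  prior <- state$sigma_n2 + params$sigma_p2
  S <- prior + params$sigma_s2
  w_prior <- params$sigma_s2 / S
  w_sample <- prior / S
  list(sigma_n2 = w_prior^2 * prior + w_sample^2 * params$sigma_s2,
       sigma_m2 = w_prior^2 * state$sigma_m2 + w_sample^2 * params$sigma_s2,
       step = state$step + 1L)
}

#' Predicted response-variability profile
#'
#' Initialises both variances at `sigma_s2` after the first sample and
#' iterates [propagate()] in steps of `dt`, reporting the response standard
#' deviation `sqrt(sigma_m2)` at the last step completed within each
#' requested duration. A duration shorter than one step uses the
#' single-sample value, with a warning.
#'
#' @param params an [integrator_params()].
#' @param durations positive durations in ms, sorted increasing.
#' @return data.frame with columns `duration_ms`, `sigma_deg`, `n_steps`.
#' @export
forward_profile <- function(params, durations) {
  stopifnot(all(durations > 0), !is.unsorted(durations))
  ks <- pmax(floor(durations / params$dt), 1L)
  if (any(durations < params$dt))
    warning("duration(s) shorter than dt: using the single-sample value")
  # inlined variance recursion (see propagate()) for speed
  s2 <- params$sigma_s2; p2 <- params$sigma_p2
  n2 <- s2; m2 <- s2
  sig <- numeric(length(ks))
  step <- 1L
  for (i in seq_along(ks)) {
    while (step < ks[i]) {
      prior <- n2 + p2
      S <- prior + s2
      wp <- s2 / S; ws <- prior / S
      n2 <- wp^2 * prior + ws^2 * s2
      m2 <- wp^2 * m2 + ws^2 * s2
      step <- step + 1L
    }
    sig[i] <- sqrt(m2)
  }
  data.frame(duration_ms = durations, sigma_deg = sig, n_steps = ks)
}

#' Estimate sensory and propagation noise from a variability profile
#'
#' Least-squares fit of the integrator's predicted response SD to measured
#' response SDs, over `(sigma_s2, sigma_p2)` on a log/bounded scale with a
#' multi-start grid followed by a quasi-Newton polish. The loss is on the
#' sigma scale (the scale on which variability is measured). The model can
#' only produce non-increasing profiles; a measured profile that never
#' decreases is fitted anyway and flagged, as is a fit that runs into the
#' propagation-noise search bound.
#'
#' @param durations durations in ms (>= 3 points).
#' @param sigmas measured response SDs, deg (> 0), same length.
#' @param dt integration step in ms (see [integrator_params()]).
#' @return List with `params` ([integrator_params()]), `rss` and `flag`
#'   (`"ok"`, `"nondecreasing_profile"` or `"sigma_p2_at_bound"`).
#' @export
fit_noise_components <- function(durations, sigmas, dt = 1000 / 360) {
  stopifnot(length(durations) == length(sigmas), all(sigmas > 0))
  if (length(durations) < 3) stop("need at least 3 (duration, sigma) points")
  ord <- order(durations)
  t <- as.numeric(durations)[ord]; y <- as.numeric(sigmas)[ord]
  flag <- if (!any(diff(y) < 0)) "nondecreasing_profile" else "ok"
  p2_cap <- 1e4 * max(y)^2
  obj <- function(lp) {
    s2 <- exp(lp[1]); p2 <- exp(lp[2])
    if (!is.finite(s2) || !is.finite(p2) || p2 > p2_cap) return(1e12)
    pred <- forward_profile(integrator_params(s2, p2, dt), t)$sigma_deg
    sum((pred - y)^2)
  }
  starts <- as.matrix(expand.grid(
    log(c(0.5, 1, 2, 4) * max(y)^2),
    log(c(1e-6, 1e-3, 0.1, 1, 5e3) * max(y)^2)))
  vals <- apply(starts, 1, obj)
  best <- NULL
  for (i in order(vals)[1:4]) {
    fit <- tryCatch(suppressWarnings(
      optim(starts[i, ], obj, method = "Nelder-Mead",
            control = list(maxit = 1000, reltol = 1e-13))),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  stopifnot(!is.null(best))
  best <- suppressWarnings(
    optim(best$par, obj, method = "Nelder-Mead",
          control = list(maxit = 1000, reltol = 1e-13)))
  s2 <- unname(exp(best$par[1])); p2 <- unname(exp(best$par[2]))
  # beyond ~1e3 x the measured variance the propagation noise is no longer
  # identifiable: the profile is flat at sigma_s for any larger value
  if (p2 > 0.1 * p2_cap) flag <- "sigma_p2_at_bound"
  list(params = integrator_params(s2, min(p2, p2_cap), dt),
       rss = best$value, flag = flag)
}
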