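#' Cumulative-Gaussian psychometric function with lapses
#'
#' Probability of the response consistent with a positive stimulus
#' difference: `lapse/2 + (1 - lapse) * pnorm((x - mu) / sigma)`. The lapse
#' is split symmetrically between the two alternatives, so the point of
#' subjective equality (P = 0.5) stays at `mu` for any lapse rate, and the
#' function is bounded in `[lapse/2, 1 - lapse/2]`.
#'
#' @param x stimulus-difference level(s), in stimulus units.
#' @param mu point of subjective equality (PSE), stimulus units.
#' @param sigma slope parameter (> 0), stimulus units.
#' @param lapse lapse probability in [0, 0.5].
#' @return Vector of response probabilities.
#' @export
psychometric_probability <- function(x, mu, sigma, lapse = 0) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  if (any(lapse < 0 | lapse > 0.5)) stop("lapse must be in [0, 0.5]")
  lapse / 2 + (1 - lapse) * pnorm((x - mu) / sigma)
}

# Aggregate trials of one participant x condition to per-level counts.
#' @keywords internal
aggregate_levels <- function(trials) {
  agg <- stats::aggregate(response ~ level, data = trials,
                          FUN = function(r) c(k = sum(r), n = length(r)))
  data.frame(level = agg$level, k = agg$response[, "k"], n = agg$response[, "n"])
}

#' Maximum-likelihood psychometric fit for one participant and condition
#'
#' Maximises the Bernoulli log-likelihood of the
#' cumulative-Gaussian-with-lapse model over `(mu, sigma, lapse)` with a
#' bounded quasi-Newton search started from several probit-regression-based
#' points. The lapse is restricted to `[0, lapse_max]` (default 0.1) for
#' stability of the single-subject path.
#'
#' @param trials trial data.frame for a single participant x condition with
#'   columns `level` and `response`.
#' @param lapse_max upper bound for the lapse rate.
#' @return List with `params` (mu, sigma, lapse), `loglik`, `converged`,
#'   and `message`.
#' @export
fit_single_mle <- function(trials, lapse_max = 0.1) {
  agg <- aggregate_levels(trials)
  if (nrow(agg) < 2) stop("need at least 2 distinct stimulus levels")
  if (sum(agg$k) == 0 || sum(agg$k) == sum(agg$n)) {
    return(list(params = NULL, loglik = NA_real_, converged = FALSE,
                message = "degenerate data: all responses identical"))
  }
  nll <- function(par) {
    p <- psychometric_probability(agg$level, par[1], par[2], par[3])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(agg$k * log(p) + (agg$n - agg$k) * log(1 - p))
  }
  span <- diff(range(agg$level))
  # probit-regression start plus a spread of slopes
  emp <- (agg$k + 0.5) / (agg$n + 1)
  z <- qnorm(emp)
  co <- coef(lm(z ~ agg$level))
  mu0 <- if (is.finite(co[2]) && abs(co[2]) > 1e-8) -co[1] / co[2] else
    mean(agg$level)
  sig0 <- if (is.finite(co[2]) && co[2] > 1e-8) 1 / co[2] else span / 4
  starts <- rbind(
    c(mu0, max(min(sig0, 5 * span), span / 50), 0.02),
    c(mean(agg$level), span / 4, 0.02),
    c(mean(agg$level), span / 10, 0.05))
  lower <- c(min(agg$level) - 2 * span, span / 1000, 0)
  upper <- c(max(agg$level) + 2 * span, 20 * span, lapse_max)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    p0 <- pmin(pmax(starts[s, ], lower), upper)
    fit <- tryCatch(
      optim(p0, nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  if (is.null(best))
    return(list(params = NULL, loglik = NA_real_, converged = FALSE,
                message = "optimisation failed"))
  list(params = list(mu = unname(best$par[1]), sigma = unname(best$par[2]),
                     lapse = unname(best$par[3])),
       loglik = -best$value,
       converged = best$convergence == 0,
       message = if (best$convergence == 0) "ok" else best$message)
}

#' Screen a participant's data for systematic responding
#'
#' Computes the per-level response proportion and its Pearson correlation
#' with the stimulus level. A condition passes when the correlation is
#' significant at `alpha` (two-sided); non-systematic responders (e.g. pure
#' guessers) fail. Constant proportions fail with a zero-variance note.
#'
#' @param trials trial data.frame for a single participant x condition.
#' @param alpha significance threshold (default 0.05).
#' @return List with `pass`, `r`, `p_value`, `n_levels`, `note`.
#' @export
screen_participant <- function(trials, alpha = 0.05) {
  agg <- aggregate_levels(trials)
  if (nrow(agg) < 3) stop("need at least 3 distinct stimulus levels")
  prop <- agg$k / agg$n
  if (sd(prop) == 0) {
    return(list(pass = FALSE, r = NA_real_, p_value = NA_real_,
                n_levels = nrow(agg), note = "zero variance in proportions"))
  }
  ct <- cor.test(agg$level, prop, method = "pearson")
  list(pass = unname(ct$p.value < alpha), r = unname(ct$estimate),
       p_value = unname(ct$p.value), n_levels = nrow(agg), note = "ok")
}

#' Pair-level to per-stimulus conversions
#'
#' In the position task the judged quantity is the vertical offset between
#' two stimuli whose textures drift in opposite directions, so the fitted
#' pair PSE reflects the shift of both stimuli and the fitted pair slope
#' compounds two independent position estimates. `per_stimulus_shift()`
#' halves the pair PSE (each stimulus shifts by half the pair offset, sign
#' preserved); `per_stimulus_noise()` divides the pair sigma by `sqrt(2)`
#' (difference of two independent equal-variance estimates).
#'
#' @param pair_pse fitted pair-level PSE, deg.
#' @param pair_sigma fitted pair-level sigma, deg (> 0).
#' @return Per-stimulus shift (deg) or noise (deg).
#' @export
per_stimulus_shift <- function(pair_pse) pair_pse / 2

#' @rdname per_stimulus_shift
#' @export
per_stimulus_noise <- function(pair_sigma) {
  if (any(pair_sigma <= 0)) stop("pair_sigma must be positive")
  pair_sigma / sqrt(2)
}

#' MIPS size from the pair-offset PSE
#'
#' The level axis is the physical offset of the stimulus moving in the
#' positive direction minus its partner; the illusion pulls the PSE to the
#' opposite sign of the perceived shift, so the one-stimulus MIPS size is
#' `-pair_pse / 2`.
#'
#' @param pair_pse fitted pair-level PSE, deg.
#' @return Signed one-stimulus MIPS size, deg (positive = shift in the
#'   motion direction).
#' @export
mips_size <- function(pair_pse) per_stimulus_shift(-pair_pse)

#' Central credible interval for a difference of posterior draws
#'
#' @param draws_a,draws_b equal-length vectors of posterior draws from a
#'   joint posterior.
#' @param level interval mass (default 0.95).
#' @return Named vector `lower`, `upper` of the central interval of
#'   `draws_a - draws_b`.
#' @export
contrast_ci <- function(draws_a, draws_b, level = 0.95) {
  if (length(draws_a) != length(draws_b))
    stop("draw vectors must have equal length")
  d <- draws_a - draws_b
  a <- (1 - level) / 2
  setNames(quantile(d, c(a, 1 - a), names = FALSE), c("lower", "upper"))
}
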