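#' Three-line temporal model of the MIPS
#'
#' The MIPS-versus-duration profile is modelled by three connected line
#' segments: from the origin (0, 0) to a first bending point `(t1, m1)`,
#' from there to a second bending point `(t2, m2)`, and flat at `m2` out to
#' 1000 ms. `piecewise_params()` validates and bundles the four parameters;
#' `piecewise_value()` evaluates the model.
#'
#' @param t1,t2 bending-point times in ms, `0 < t1 < t2 <= 1000`.
#' @param m1,m2 shift values at the bending points, deg.
#' @return `piecewise_params()`: a `piecewise_params` object.
#' @export
piecewise_params <- function(t1, m1, t2, m2) {
  if (!(t1 > 0 && t1 < t2 && t2 <= 1000))
    stop("need 0 < t1 < t2 <= 1000")
  structure(list(t1 = t1, m1 = m1, t2 = t2, m2 = m2),
            class = "piecewise_params")
}

#' @rdname piecewise_params
#' @param params a `piecewise_params`.
#' @param t duration(s) in ms, within [0, 1000].
#' @return `piecewise_value()`: the model shift (deg) at each `t`.
#' @export
piecewise_value <- function(params, t) {
  if (any(t < 0 | t > 1000)) stop("t must lie in [0, 1000] ms")
  with(params, ifelse(t <= t1, m1 * t / t1,
                ifelse(t <= t2, m1 + (m2 - m1) * (t - t1) / (t2 - t1), m2)))
}

# Given knots, the model is linear in (m1, m2); solve that inner problem
# exactly and return the conditional RSS.
#' @keywords internal
piecewise_inner <- function(knots, t, y) {
  t1 <- knots[1]; t2 <- knots[2]
  b1 <- ifelse(t <= t1, t / t1, ifelse(t <= t2, (t2 - t) / (t2 - t1), 0))
  b2 <- ifelse(t <= t1, 0, ifelse(t <= t2, (t - t1) / (t2 - t1), 1))
  X <- cbind(b1, b2)
  m <- tryCatch(qr.solve(crossprod(X), crossprod(X, y)),
                error = function(e) NULL)
  if (is.null(m)) return(list(rss = Inf, m = c(NA, NA)))
  r <- y - X %*% m
  list(rss = sum(r^2), m = as.numeric(m))
}

#' Least-squares fit of the three-line temporal model
#'
#' Profiles the shift parameters out of the least-squares problem (for
#' fixed bending times the model is linear in `m1`, `m2`), searches a grid
#' of candidate knot pairs built from the measured durations and their
#' midpoints, and polishes the best candidates with a bounded continuous
#' optimisation of `(t1, t2)`.
#'
#' @param durations durations in ms (>= 5 points recommended).
#' @param shifts measured shifts in deg, same length.
#' @param n_polish number of top grid candidates refined continuously.
#' @return List with `params` (a [piecewise_params()]) and `rss`.
#' @export
fit_piecewise <- function(durations, shifts, n_polish = 8) {
  stopifnot(length(durations) == length(shifts))
  if (length(durations) < 5)
    stop("need at least 5 (duration, shift) points")
  t <- as.numeric(durations); y <- as.numeric(shifts)
  ord <- order(t); t <- t[ord]; y <- y[ord]
  ts <- sort(unique(t))
  cand <- sort(unique(c(ts, (ts[-1] + ts[-length(ts)]) / 2)))
  cand <- cand[cand > 0 & cand <= 1000]
  grid <- expand.grid(t1 = cand, t2 = cand)
  grid <- grid[grid$t1 < grid$t2, ]
  gr <- vapply(seq_len(nrow(grid)), function(i)
    piecewise_inner(c(grid$t1[i], grid$t2[i]), t, y)$rss, numeric(1))
  top <- order(gr)[seq_len(min(n_polish, length(gr)))]
  eps <- 1e-6
  obj <- function(k) {
    if (!(k[1] > 0 && k[1] + eps < k[2] && k[2] <= 1000)) return(1e10)
    piecewise_inner(k, t, y)$rss
  }
  best <- NULL
  for (i in top) {
    k0 <- c(grid$t1[i], grid$t2[i])
    fit <- tryCatch(optim(k0, obj, method = "Nelder-Mead",
                          control = list(maxit = 2000, reltol = 1e-14)),
                    error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) best <- fit
  }
  stopifnot(!is.null(best))
  inner <- piecewise_inner(best$par, t, y)
  list(params = piecewise_params(best$par[1], inner$m[1],
                                 best$par[2], inner$m[2]),
       rss = inner$rss)
}

#' Initial rate of the MIPS increase
#'
#' Averages the origin-anchored rates at the two shortest durations: the
#' mean of `shift_31 / 31 ms` and `shift_55 / 55 ms`, returned in deg/s.
#' Averaging the two secant rates is more reliable than dividing the fitted
#' `m1` by the noisy bending time `t1`.
#'
#' @param shift_31,shift_55 measured shifts (deg) at 31 and 55 ms.
#' @return Initial rate in deg/s.
#' @export
initial_rate <- function(shift_31, shift_55) {
  stopifnot(is.finite(shift_31), is.finite(shift_55))
  mean(c(shift_31 / 0.031, shift_55 / 0.055))
}

#' Exponential decay of response variability
#'
#' `decay_params()` bundles the parameters of the decay model
#' `sigma(t) = a * exp(-b t) + c`, where `a + c` is the initial value, `b`
#' the decay rate (1/ms) and `c` the asymptote. `decay_value()` evaluates
#' it; `fit_decay()` fits it by constrained least squares (`a, b, c >= 0`)
#' with the linear parameters `(a, c)` profiled out over a multi-start grid
#' in `b`, followed by a bounded polish.
#'
#' @param a initial excess over the asymptote, deg (>= 0).
#' @param b decay rate, 1/ms (>= 0).
#' @param c_ asymptote, deg (>= 0).
#' @return `decay_params()`: a `decay_params` object.
#' @export
decay_params <- function(a, b, c_) {
  if (a < 0 || b < 0 || c_ < 0) stop("a, b and c must be non-negative")
  structure(list(a = a, b = b, c = c_), class = "decay_params")
}

#' @rdname decay_params
#' @param params a `decay_params`.
#' @param t durations in ms.
#' @export
decay_value <- function(params, t) params$a * exp(-params$b * t) + params$c

#' @rdname decay_params
#' @param durations durations in ms (>= 4 points).
#' @param sigmas measured response SDs in deg (> 0), same length.
#' @export
fit_decay <- function(durations, sigmas) {
  stopifnot(length(durations) == length(sigmas), all(sigmas > 0))
  if (length(durations) < 4) stop("need at least 4 (duration, sigma) points")
  t <- as.numeric(durations); y <- as.numeric(sigmas)
  inner <- function(b) {
    # for fixed b the model is linear in (a, c) with a, c >= 0
    e <- exp(-b * t)
    X <- cbind(e, 1)
    ab <- tryCatch(qr.solve(crossprod(X), crossprod(X, y)),
                   error = function(e2) NULL)
    cands <- list()
    if (!is.null(ab) && all(ab >= 0)) cands <- c(cands, list(as.numeric(ab)))
    cands <- c(cands, list(c(0, max(mean(y), 0)),
                           c(max(sum(e * y) / sum(e * e), 0), 0)))
    best <- NULL
    for (p in cands) {
      r <- sum((y - p[1] * e - p[2])^2)
      if (is.null(best) || r < best$rss) best <- list(rss = r, a = p[1], c = p[2])
    }
    best
  }
  # profile out (a, c): 1-d search over the decay rate, grid then refine
  bgrid <- c(0, 10^seq(-5, 0, length.out = 41))
  rss <- vapply(bgrid, function(b) inner(b)$rss, numeric(1))
  i0 <- which.min(rss)
  lo <- bgrid[max(i0 - 1, 1)]
  hi <- bgrid[min(i0 + 1, length(bgrid))]
  b_best <- bgrid[i0]
  if (hi > lo) {
    op <- stats::optimize(function(b) inner(b)$rss, interval = c(lo, hi),
                          tol = 1e-12)
    if (op$objective <= rss[i0]) b_best <- op$minimum
  }
  fin <- inner(b_best)
  if (fin$a == 0 || b_best == 0) b_best <- max(b_best, 0)
  list(params = decay_params(fin$a, b_best, fin$c), rss = fin$rss)
}
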