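test_that("psychometric probability matches the cumulative-Gaussian form", {
  expect_equal(psychometric_probability(0.5, mu = 0.5, sigma = 0.3), 0.5)
  expect_equal(psychometric_probability(0.8, mu = 0.5, sigma = 0.3),
               pnorm(1))
  # symmetric lapse preserves the PSE and sets the asymptotes
  expect_equal(psychometric_probability(0.5, 0.5, 0.3, lapse = 0.2), 0.5)
  expect_equal(psychometric_probability(1e6, 0.5, 0.3, lapse = 0.1), 0.95)
  expect_error(psychometric_probability(0, 0, -1), "sigma")
  expect_error(psychometric_probability(0, 0, 1, lapse = 0.7), "lapse")
})

test_that("MLE recovers parameters at large trial counts", {
  tr <- simulate_bernoulli(seq(-1, 2, length.out = 20), reps = 200,
                           mu = 0.5, sigma = 0.3, lapse = 0, seed = 31)
  f <- fit_single_mle(tr)
  expect_true(f$converged)
  expect_lt(abs(f$params$mu - 0.5), 0.05)
  expect_lt(abs(f$params$sigma - 0.3), 0.05)
})

test_that("exactly mirrored responses give a zero PSE", {
  lev <- c(-2, -1, 0, 1, 2)
  k <- c(1, 3, 5, 7, 9); n <- rep(10, 5)  # k(x) = n - k(-x)
  tr <- data.frame(level = rep(lev, n),
                   response = unlist(mapply(function(ki, ni)
                     c(rep(1, ki), rep(0, ni - ki)), k, n,
                     SIMPLIFY = FALSE)))
  f <- fit_single_mle(tr)
  expect_lt(abs(f$params$mu), 1e-4)
})

test_that("MLE attains the brute-force grid optimum on a small instance", {
  tr <- simulate_bernoulli(seq(-1, 1, length.out = 5), reps = 8,
                           mu = 0.2, sigma = 0.5, lapse = 0, seed = 8)
  f <- fit_single_mle(tr)
  agg <- mipsage:::aggregate_levels(tr)
  ll <- function(mu, sigma) {
    p <- pmin(pmax(psychometric_probability(agg$level, mu, sigma), 1e-12),
              1 - 1e-12)
    sum(agg$k * log(p) + (agg$n - agg$k) * log(1 - p))
  }
  grid <- expand.grid(mu = seq(-1.5, 1.5, by = 0.05),
                      sigma = seq(0.05, 3, by = 0.05))
  best_grid <- max(mapply(ll, grid$mu, grid$sigma))
  expect_gte(f$loglik, best_grid - 1e-6)
})

test_that("degenerate (all-identical) responses are flagged, not fitted", {
  tr <- data.frame(level = rep(c(-1, 0, 1), each = 5), response = 1)
  f <- fit_single_mle(tr)
  expect_false(f$converged)
  expect_match(f$message, "degenerate")
})

test_that("screening passes systematic observers and rejects guessers", {
  # monotone observer with the standard 160-trial condition
  npass <- sum(vapply(1:60, function(r) {
    tr <- simulate_bernoulli(seq(-2, 1, length.out = 20), reps = 8,
                             mu = -0.5, sigma = 0.6, lapse = 0.02,
                             seed = 600 + r)
    screen_participant(tr)$pass
  }, logical(1)))
  expect_gte(npass, 59)
  # lapse-1 guesser: level-independent responding fails at the alpha rate
  nfail <- sum(vapply(1:200, function(r) {
    tr <- simulate_bernoulli(seq(-2, 1, length.out = 20), reps = 8,
                             mu = 0, sigma = 1, lapse = 1, seed = 9000 + r)
    !screen_participant(tr)$pass
  }, logical(1)))
  expect_gt(nfail / 200, 0.88)   # null retention rate ~ 1 - alpha = 0.95
  expect_lt(nfail / 200, 1.0)
  # constant proportions fail with a note
  tr0 <- data.frame(level = rep(c(-1, 0, 1), each = 4),
                    response = rep(c(0, 1), 6))
  s <- screen_participant(tr0)
  expect_false(s$pass)
  expect_match(s$note, "zero variance")
})

test_that("exclusion bookkeeping matches a mixed cohort of guessers and responders", {
  # 24 older observers of which 7 guess, 21 young of which 2 guess:
  # screening across conditions should retain exactly the systematic ones
  des <- one_cell_design()
  survives <- function(mu, sigma, lapse, seed) {
    tr <- simulate_bernoulli(des$levels, des$reps_per_level, mu, sigma,
                             lapse, seed)
    screen_participant(tr)$pass
  }
  older <- c(vapply(1:17, function(i)
    survives(-1.4, 1.4, 0.03, 100 + i), logical(1)),
    vapply(1:7, function(i) survives(0, 1, 1, 200 + i), logical(1)))
  young <- c(vapply(1:19, function(i)
    survives(-0.5, 0.4, 0.03, 300 + i), logical(1)),
    vapply(1:2, function(i) survives(0, 1, 1, 400 + i), logical(1)))
  expect_equal(sum(older[1:17]), 17)
  expect_equal(sum(young[1:19]), 19)
  expect_lte(sum(older[18:24]), 2)   # most guessers rejected
  expect_lte(sum(young[20:21]), 1)
})

test_that("per-stimulus conversions follow the pair geometry", {
  expect_equal(per_stimulus_shift(0), 0)
  expect_equal(per_stimulus_shift(1.5), 0.75)
  expect_equal(per_stimulus_shift(-0.52), -0.26)
  expect_equal(mips_size(-1.5), 0.75)
  expect_equal(per_stimulus_noise(sqrt(2)), 1)
  expect_equal(per_stimulus_noise(0.2), 0.2 / sqrt(2))
  expect_error(per_stimulus_noise(0), "positive")
  # variance-addition oracle: the pair difference of two independent
  # estimates of sd s has sd s*sqrt(2)
  set.seed(12)
  s <- 0.7
  pair <- rnorm(20000, 0, s) - rnorm(20000, 0, s)
  expect_lt(abs(per_stimulus_noise(sd(pair)) - s), 0.02)
})

test_that("contrast intervals behave as central difference intervals", {
  x <- rnorm(5000)
  expect_equal(unname(contrast_ci(x, x)), c(0, 0))
  ci <- contrast_ci(x + 1, x)
  expect_equal(unname(ci), c(1, 1), tolerance = 1e-10)
  set.seed(3)
  a <- rnorm(1e5); b <- rnorm(1e5)
  ci2 <- contrast_ci(a, b)
  expect_equal(unname(ci2), c(-1.96, 1.96) * sqrt(2), tolerance = 0.03)
  expect_error(contrast_ci(1:5, 1:4), "equal length")
})
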