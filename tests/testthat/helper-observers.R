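# Shared fixtures for the test suite: tiny designs and canned observers.

one_cell_design <- function(levels = seq(-2, 1, length.out = 20), reps = 8,
                            task = "position") {
  mipsage:::new_design(task = task, eccentricities = 10, durations = 1000,
                       levels = levels, reps_per_level = reps)
}

make_observer <- function(mu, sigma, lapse = 0, id = "obs01",
                          group = "young", cell = "ecc10_dur1000") {
  params <- list(list(mu = mu, sigma = sigma, lapse = lapse))
  names(params) <- cell
  list(participant_id = id, group = group, params = params)
}

# Direct Bernoulli simulation of one participant x condition (independent
# of simulate_trials) for oracle-style comparisons.
simulate_bernoulli <- function(levels, reps, mu, sigma, lapse, seed) {
  set.seed(seed)
  lev <- rep(levels, each = reps)
  p <- lapse / 2 + (1 - lapse) * pnorm((lev - mu) / sigma)
  data.frame(level = lev, response = rbinom(length(lev), 1, p))
}

exp2_durations <- c(31, 55, 98, 175, 313, 559, 1000)
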