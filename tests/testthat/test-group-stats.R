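# Direct sums-of-squares oracle for a balanced split-plot layout:
# between factor A (group), within factor B, subjects nested in A.
splitplot_ss <- function(d) {
  gm <- mean(d$value)
  nB <- length(unique(d$within))
  subj_means <- tapply(d$value, d$participant_id, mean)
  subj_group <- tapply(as.character(d$group), d$participant_id, unique)
  a_means <- tapply(d$value, d$group, mean)
  a_n <- table(d$group) / nB                      # subjects per group
  SS_A <- sum(nB * a_n * (a_means[names(a_n)] - gm)^2)
  SS_subj <- nB * sum((subj_means - a_means[subj_group])^2)
  b_means <- tapply(d$value, d$within, mean)
  nsubj <- length(subj_means)
  SS_B <- nsubj * sum((b_means - gm)^2)
  ab_means <- tapply(d$value, list(d$group, d$within), mean)
  SS_AB <- sum(rep(a_n, nB) *
                 (sweep(sweep(ab_means, 1, a_means), 2, b_means) + gm)^2)
  SS_tot <- sum((d$value - gm)^2)
  SS_err <- SS_tot - SS_A - SS_subj - SS_B - SS_AB
  list(A = SS_A, subj = SS_subj, B = SS_B, AB = SS_AB, err = SS_err,
       tot = SS_tot)
}

make_table <- function(nA1, nA2, nB, values) {
  d <- expand.grid(within = paste0("w", seq_len(nB)),
                   participant_id = sprintf("s%02d", seq_len(nA1 + nA2)))
  d$group <- ifelse(as.integer(sub("s", "", d$participant_id)) <= nA1,
                    "young", "older")
  d$value <- values
  d
}

test_that("split-plot ANOVA matches the hand-worked SS decomposition", {
  set.seed(5)
  d <- make_table(4, 4, 3, rnorm(24, mean = rep(c(0, 0.5), c(12, 12))))
  out <- split_plot_anova(d, within = "within")
  ss <- splitplot_ss(d)
  nB <- 3; nsubj <- 8
  F_A <- (ss$A / 1) / (ss$subj / (nsubj - 2))
  F_B <- (ss$B / (nB - 1)) / (ss$err / ((nsubj - 2) * (nB - 1)))
  F_AB <- (ss$AB / (nB - 1)) / (ss$err / ((nsubj - 2) * (nB - 1)))
  expect_equal(out$F, c(F_A, F_B, F_AB), tolerance = 1e-10)
  expect_equal(out$df2, c(nsubj - 2, (nsubj - 2) * (nB - 1),
                          (nsubj - 2) * (nB - 1)))
  expect_equal(out$pes,
               c(ss$A / (ss$A + ss$subj), ss$B / (ss$B + ss$err),
                 ss$AB / (ss$AB + ss$err)), tolerance = 1e-10)
  # sums of squares partition exactly
  expect_equal(ss$A + ss$subj + ss$B + ss$AB + ss$err, ss$tot,
               tolerance = 1e-10)
})

test_that("degenerate and invalid ANOVA inputs are handled", {
  d <- make_table(3, 3, 2, rep(1, 12))
  out <- split_plot_anova(d, within = "within")
  expect_equal(out$F, c(0, 0, 0))
  expect_equal(out$p, c(1, 1, 1))
  d2 <- make_table(3, 3, 2, rnorm(12))
  expect_error(split_plot_anova(d2[-1, ], within = "within"), "unbalanced")
})

test_that("ANOVA p-values are invariant under affine rescaling", {
  set.seed(9)
  d <- make_table(5, 4, 3, rnorm(27) + rep(c(0, 0.8), c(15, 12)))
  o1 <- split_plot_anova(d, within = "within")
  d$value <- 3.7 * d$value - 11
  o2 <- split_plot_anova(d, within = "within")
  expect_equal(o1$p, o2$p, tolerance = 1e-10)
  expect_equal(o1$F, o2$F, tolerance = 1e-8)
})

test_that("Welch's t-test matches the closed form and flags degeneracy", {
  a <- c(1.1, 2.3, 1.9, 2.8, 1.4)
  b <- c(0.6, 1.0, 0.4)
  w <- welch_t(a, b)
  se2 <- var(a) / 5 + var(b) / 3
  t_hand <- (mean(a) - mean(b)) / sqrt(se2)
  df_hand <- se2^2 / ((var(a) / 5)^2 / 4 + (var(b) / 3)^2 / 2)
  expect_equal(w$t, t_hand, tolerance = 1e-12)
  expect_equal(w$df, df_hand, tolerance = 1e-10)
  sp <- sqrt((4 * var(a) + 2 * var(b)) / 6)
  expect_equal(w$d, (mean(a) - mean(b)) / sp, tolerance = 1e-12)
  expect_lte(w$df, 6)                      # Welch df <= pooled df
  same <- welch_t(a, a)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  deg <- welch_t(rep(1, 3), rep(2, 3))
  expect_true(deg$degenerate)
  expect_equal(deg$mean_diff, -1)
})

test_that("eccentricity deltas subtract 15 minus 5 degrees per participant", {
  tab <- data.frame(participant_id = rep(c("a", "b", "c"), each = 2),
                    eccentricity_deg = rep(c(5, 15), 3),
                    value = c(0.34, 0.67, 0.2, 0.2, -0.5, -1.5))
  d <- eccentricity_deltas(tab)
  expect_equal(d$delta[d$participant_id == "a"], 0.33)
  expect_equal(d$delta[d$participant_id == "b"], 0)
  expect_equal(d$delta[d$participant_id == "c"], -1)   # more negative at 15
  tab2 <- rbind(tab, data.frame(participant_id = "d", eccentricity_deg = 5,
                                value = 1))
  expect_message(d2 <- eccentricity_deltas(tab2), "dropping")
  expect_equal(nrow(d2), 3)
})

test_that("correlation, transforms and Tukey contrasts behave standardly", {
  x <- 1:10
  expect_equal(pearson_r(x, 2 * x + 3)$r, 1)
  expect_error(pearson_r(1:2, 1:2), "at least 3")
  z <- zscore(rnorm(20, 5, 2))
  expect_equal(mean(z), 0, tolerance = 1e-12)
  expect_equal(sd(z), 1, tolerance = 1e-12)
  expect_error(log_z(c(1, -1)), "positive")
  set.seed(31)
  tab <- data.frame(participant_id = rep(sprintf("s%d", 1:8), each = 3),
                    eccentricity_deg = rep(c(5, 10, 15), 8),
                    value = rep(c(0, 0.4, 0.8), 8) + rnorm(24, 0, 0.05))
  th <- tukey_hsd(tab)
  expect_equal(nrow(th), 3)
  r15_5 <- th[th$contrast == "15-5", ]
  expect_equal(r15_5$diff,
               mean(tab$value[tab$eccentricity_deg == 15]) -
                 mean(tab$value[tab$eccentricity_deg == 5]),
               tolerance = 1e-10)
  expect_lt(r15_5$p_adj, 0.01)
})

test_that("negatively coupled eccentricity changes yield negative correlations", {
  set.seed(44)
  neg <- 0
  for (r in 1:20) {
    delta_mips <- runif(36, 0.1, 0.6)
    delta_speed <- -2.5 * delta_mips + rnorm(36, 0, 0.45)
    if (pearson_r(delta_mips, delta_speed)$r < 0) neg <- neg + 1
  }
  expect_gte(neg, 19)
})

test_that("age effects on simulated position measures reach significance reliably", {
  # measure-level power check at the reference group means and spreads
  hy <- default_group_hyper("young", "position")
  ho <- default_group_hyper("older", "position")
  sig <- 0
  nrep <- 20
  for (r in 1:nrep) {
    gy <- draw_population(hy, 19, seed = 5000 + r, group = "young")
    go <- draw_population(ho, 17, seed = 6000 + r, group = "older")
    rows <- lapply(c(gy, go), function(o) {
      data.frame(participant_id = o$participant_id,
                 group = o$group,
                 within = names(o$params),
                 value = vapply(o$params, function(p) mips_size(p$mu), 0))
    })
    tab <- do.call(rbind, rows)
    out <- split_plot_anova(tab, within = "within")
    if (out$p[out$effect == "group"] < 0.01) sig <- sig + 1
  }
  expect_gte(sig / nrep, 0.8)
})
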