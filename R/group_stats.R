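#' Split-plot (mixed) ANOVA
#'
#' Univariate split-plot ANOVA with one between-subject factor (e.g. age
#' group), one within-subject factor (e.g. eccentricity), and participant
#' as the random blocking unit. Requires a balanced design: exactly one
#' value per participant x within-factor level. Reports F, the df pair, the
#' p value and partial eta squared (`SS_effect / (SS_effect + SS_error)`,
#' each error term taken from the stratum in which the effect is tested).
#'
#' @param table data.frame with columns named by `participant`, `between`,
#'   `within`, `value`.
#' @param between,within,participant,value column names.
#' @return data.frame with rows for the between main effect, the within
#'   main effect and their interaction: `effect`, `F`, `df1`, `df2`, `p`,
#'   `pes`.
#' @export
split_plot_anova <- function(table, between = "group", within = "within",
                             participant = "participant_id",
                             value = "value") {
  d <- data.frame(y = table[[value]],
                  g = factor(table[[between]]),
                  w = factor(table[[within]]),
                  id = factor(table[[participant]]))
  counts <- table(d$id, d$w)
  if (any(counts != 1))
    stop("unbalanced design: need exactly one value per participant and ",
         "within-factor level; aggregate replicates first")
  per_group <- unique(d[c("id", "g")])
  if (any(table(per_group$id) != 1))
    stop("each participant must belong to exactly one between-group level")
  effects <- c(between, within, paste0(between, ":", within))
  if (var(d$y) == 0) {
    nw <- nlevels(d$w); np <- nlevels(d$id); ng <- nlevels(d$g)
    return(data.frame(effect = effects, F = 0,
                      df1 = c(ng - 1, nw - 1, (ng - 1) * (nw - 1)),
                      df2 = c(np - ng, rep((np - ng) * (nw - 1), 2)),
                      p = 1, pes = 0))
  }
  fit <- aov(y ~ g * w + Error(id / w), data = d)
  s <- summary(fit)
  btw <- as.data.frame(s[["Error: id"]][[1]])
  wth <- as.data.frame(s[["Error: id:w"]][[1]])
  row_of <- function(tab, name) tab[trimws(rownames(tab)) == name, , drop = FALSE]
  mk <- function(tab, name, err) {
    r <- row_of(tab, name)
    Fv <- r[["F value"]]; pv <- r[["Pr(>F)"]]
    pes <- r[["Sum Sq"]] / (r[["Sum Sq"]] + err[["Sum Sq"]])
    if (r[["Sum Sq"]] == 0) { Fv <- 0; pv <- 1; pes <- 0 }
    data.frame(effect = name, F = Fv, df1 = r$Df, df2 = err$Df, p = pv,
               pes = pes)
  }
  err_b <- row_of(btw, "Residuals")
  err_w <- row_of(wth, "Residuals")
  out <- rbind(mk(btw, "g", err_b), mk(wth, "w", err_w),
               mk(wth, "g:w", err_w))
  out$effect <- c(between, within, paste0(between, ":", within))
  rownames(out) <- NULL
  out
}

#' Welch's t-test with Cohen's d
#'
#' Unequal-variance two-sample t-test (Welch-Satterthwaite df) plus
#' Cohen's d computed with the pooled standard deviation.
#'
#' @param a,b numeric vectors (>= 2 values each).
#' @return List with `t`, `df`, `p`, `d`, `mean_diff`, and `degenerate`
#'   (TRUE when both groups have zero variance, in which case the test
#'   statistics are NA).
#' @export
welch_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (var(a) == 0 && var(b) == 0)
    return(list(t = NA_real_, df = NA_real_, p = NA_real_, d = NA_real_,
                mean_diff = mean(a) - mean(b), degenerate = TRUE))
  tt <- t.test(a, b, var.equal = FALSE)
  sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
               (length(a) + length(b) - 2))
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, d = (mean(a) - mean(b)) / sp,
       mean_diff = mean(a) - mean(b), degenerate = FALSE)
}

#' Per-participant change between the extreme eccentricities
#'
#' Subtracts each participant's estimate at 5 deg from the one at 15 deg
#' (15 - 5), for any measure. Participants missing either eccentricity are
#' dropped with a message. Comparing eccentricity-to-eccentricity changes
#' (rather than raw values) cancels participant-specific offsets such as
#' the perceived speed of the reference stimulus.
#'
#' @param table data.frame with columns `participant_id`,
#'   `eccentricity_deg`, `value`.
#' @param ecc_low,ecc_high the two eccentricities to difference.
#' @return data.frame `participant_id`, `delta`.
#' @export
eccentricity_deltas <- function(table, ecc_low = 5, ecc_high = 15) {
  lo <- table[table$eccentricity_deg == ecc_low, c("participant_id", "value")]
  hi <- table[table$eccentricity_deg == ecc_high, c("participant_id", "value")]
  m <- merge(hi, lo, by = "participant_id", suffixes = c("_hi", "_lo"))
  dropped <- setdiff(unique(table$participant_id), m$participant_id)
  if (length(dropped))
    message("dropping participant(s) missing an eccentricity: ",
            paste(dropped, collapse = ", "))
  data.frame(participant_id = m$participant_id,
             delta = m$value_hi - m$value_lo)
}

#' Pearson correlation test
#'
#' @param x,y numeric vectors, length >= 3.
#' @return List with `r`, `df`, `p`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) < 3 || length(y) < 3)
    stop("need at least 3 observations")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), df = unname(ct$parameter), p = ct$p.value)
}

#' Tukey HSD across a within-subject factor
#'
#' Pairwise Tukey honest-significant-difference comparisons across the
#' levels of one factor, with participant as an additive block (the
#' standard randomized-block formulation for repeated measures).
#'
#' @param table data.frame with columns `participant_id`, a factor column
#'   named by `factor_col`, and `value`.
#' @param factor_col the within-subject factor column name.
#' @return data.frame of pairwise contrasts: `contrast`, `diff`, `lwr`,
#'   `upr`, `p_adj`.
#' @export
tukey_hsd <- function(table, factor_col = "eccentricity_deg") {
  d <- data.frame(y = table$value, f = factor(table[[factor_col]]),
                  id = factor(table$participant_id))
  fit <- aov(y ~ f + id, data = d)
  th <- TukeyHSD(fit, which = "f")$f
  data.frame(contrast = rownames(th), diff = th[, "diff"],
             lwr = th[, "lwr"], upr = th[, "upr"], p_adj = th[, "p adj"],
             row.names = NULL)
}

#' Standardisation transforms
#'
#' `zscore()` centres and scales to unit SD; `log_z()` z-scores the natural
#' log of (positive) values. Used to make measures with different units
#' (position vs speed; sensory vs propagation variance) commensurable
#' before interaction tests: standardise within each measure across all
#' participants of both groups.
#'
#' @param values numeric vector.
#' @return Transformed vector.
#' @export
zscore <- function(values) {
  s <- sd(values)
  if (s == 0) stop("zero variance")
  (values - mean(values)) / s
}

#' @rdname zscore
#' @export
log_z <- function(values) {
  if (any(values <= 0)) stop("log_z needs positive values")
  zscore(log(values))
}
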