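---
title: "Models and methods behind mipsage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mipsage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The scientific problem

When a static-envelope object contains a drifting texture, its perceived
position shifts in the direction of the motion — the motion-induced position
shift (MIPS). The size of that shift indexes how strongly the visual system
lets predictive motion signals bias position estimates, which makes it a
sensitive probe of how position/motion integration changes with healthy
aging: observers with noisier position signals are expected to weight motion
more, and hence show a larger MIPS. `mipsage` implements the full analysis
chain needed to study this with two-alternative forced-choice (2AFC) data:
synthetic observers, psychometric fitting (single-subject maximum likelihood
and hierarchical Bayes), piecewise modelling of the MIPS time course, an
optimal sequential-integrator decomposition of response variability, and the
group-level statistics used to compare young and older cohorts.

# Psychometric model

Every binary response is modelled by a cumulative Gaussian with a lapse
rate,

$$\psi(x) = \frac{\lambda}{2} + (1-\lambda)\,\Phi\!\left(\frac{x-\mu}{\sigma}\right),$$

where $x$ is the signed stimulus difference (degrees of vertical offset in
the position task, deg/s of reference-minus-test speed in the speed task),
$\mu$ is the point of subjective equality (PSE), $\sigma$ the response
variability, and $\lambda \in [0, 0.5]$ the probability of a
stimulus-independent response. The lapse is split symmetrically between the
two alternatives; this is the standard reading of "an arbitrary response"
and keeps the PSE at $\mu$ for any $\lambda$.

In the position task the judged quantity is the offset between *two*
stimuli whose textures drift in opposite vertical directions, so the level
axis is asymmetric (20 equally spaced offsets spanning $-2°$ to $1°$) and
the pair PSE is $-2\times$ the one-stimulus MIPS ([`mips_size()`]).
Likewise the pair-level $\sigma$ compounds two independent position
estimates, so the one-stimulus noise is $\sigma/\sqrt2$
([`per_stimulus_noise()`]). Dividing by $\sqrt2$ rather than 2 is forced by
the variance-addition argument for differencing two independent
equal-variance estimates; any common scale factor cancels from group
ratios, so downstream ratio statements are insensitive to this choice.

## Hierarchical Bayesian fit

Single-subject maximum likelihood (`fit_single_mle()`) is a fast bounded
quasi-Newton search ($\lambda \le 0.1$ for stability) used for smoke tests
and the pipeline's quick path. The robust path, `fit_hierarchical()`,
shares information across the participants of one age group: for each
design cell,

* $\mu_j \sim t(\mathrm{loc}, \mathrm{scale}, \nu)$ — heavy tails
  accommodate outlying observers;
* $\sigma_j \sim \mathrm{Gamma}$, parameterised by mean and SD;
* $\lambda_j \sim \mathcal{N}(m_\lambda, s_\lambda)$ truncated to
  $[0, 0.5]$.

Hyperpriors are deliberately weak: uniform distributions on the group means
spanning five times the stimulus range, Gamma(2, 2/range) on the group SDs,
and an exponential with mean 30 on the t degrees of freedom. Posteriors are
drawn with JAGS (Gibbs/slice sampling); runs are reproducible because every
chain receives an explicit RNG seed derived from the user seed. Convergence
is monitored with the split-chain potential scale-reduction factor
($\hat{R} < 1.01$ on all monitored quantities; 4 chains by default), and
non-convergence produces a warning while still returning results.
Monitored derived quantities include `mu_mean`, the mean of the
participant-level PSEs — the estimand matching a "group mean" of individual
observers.

# Temporal dynamics of the MIPS

The shift-versus-duration profile is summarised by three connected line
segments through the origin: $(0,0) \to (t_1, m_1) \to (t_2, m_2) \to
(1000, m_2)$, capturing the early peak (around 60 ms) and the decay to a
plateau. `fit_piecewise()` exploits that, for fixed bending times, the
model is linear in $(m_1, m_2)$: the inner problem is solved exactly and
only $(t_1, t_2)$ is searched — first on a grid of measured durations and
midpoints (bending times are only identifiable relative to the sampling
grid), then with a continuous Nelder-Mead polish. On noiseless profiles
sampled at the seven standard durations (31–1000 ms) this recovers the
generating parameters to optimizer precision.

The initial rate of the MIPS rise is estimated as the mean of the two
origin-anchored secant rates at 31 and 55 ms
(`initial_rate()` = mean of shift/duration, in deg/s). Dividing the fitted
$m_1$ by $t_1$ is avoided because $t_1$ is a small, noisy estimate. The
static-texture control (plotted at 0 ms) is not part of the piecewise fit:
the model already anchors the origin.

Response variability over duration is summarised by
$\sigma_t = a e^{-bt} + c$ (`fit_decay()`, constrained $a,b,c \ge 0$,
fitted by profiling the linear parameters over a 1-D search in $b$).

# Optimal sequential integrator

To split response variability into interpretable sources, the observer is
modelled as an optimal (inverse-variance-weighted) integrator of discrete
position samples. Each sample carries sensory noise $\sigma^2_s$; between
steps the internal estimate accrues propagation noise $\sigma^2_p$ (memory
or prediction error). With prior variance $\sigma^2_{n_t} + \sigma^2_p$
and sample variance $\sigma^2_s$, the internal and measurable response
variances update as

$$\sigma^2_{n_{t+1}} = w_1^2\,(\sigma^2_{n_t}+\sigma^2_p) + w_2^2\,\sigma^2_s,
\qquad
\sigma^2_{m_{t+1}} = w_1^2\,\sigma^2_{m_t} + w_2^2\,\sigma^2_s,$$

with $w_1 = \sigma^2_s / S$, $w_2 = (\sigma^2_{n_t}+\sigma^2_p)/S$ and
$S = \sigma^2_{n_t}+\sigma^2_p+\sigma^2_s$. The response-variance recursion
shares the gains but does not receive the propagation-noise term itself.
With $\sigma^2_p = 0$ the recursion collapses to the ideal
$\sigma^2_s / k$ after $k$ samples, which the test suite verifies to
relative error $10^{-10}$ over $10^4$ steps, alongside a Monte-Carlo
simulation of the scalar filter itself.

Numerical choices: the step size defaults to one display frame at 360 Hz
($\Delta t = 1000/360$ ms) and is configurable — per-step sensory noise
scales with the discretisation, so $\sigma^2_s$ estimates are only
comparable at a common $\Delta t$. Both variances initialise at
$\sigma^2_s$ after the first sample (flat prior before any data).
Durations falling between steps use the last completed step: the observer
cannot use samples not yet received. `fit_noise_components()` fits
$(\sigma^2_s, \sigma^2_p)$ by least squares on the $\sigma$ scale (the
scale on which variability is measured), with a log-scale multi-start;
propagation noise beyond $\sim 10^3 \times$ the measured variance is
reported as at-bound because the predicted profile is then flat at
$\sigma_s$ for any larger value.

# Synthetic observers

Because the human data this design emulates are not publicly deposited,
`mipsage` ships a first-class generator. `draw_population()` draws
per-participant $(\mu, \sigma, \lambda)$ from the group-level distributions
above; `simulate_trials()` produces Bernoulli 2AFC responses under
$\psi(x)$. Reproducibility uses one root seed with per-observer substreams,
so enlarging a cohort never perturbs existing observers.

The reference populations (`default_group_hyper()`) pin the PSE locations
to the group and per-eccentricity means the emulated study reports
(per-stimulus MIPS 0.26° young / 0.75° older; overall 0.34° at 5° rising
to 0.67° at 15°; speed bias $-0.76$ to $-2.78$ deg/s across eccentricity).
The 10°-eccentricity means are not reported; they are chosen so the
additive group-plus-eccentricity decomposition reproduces every reported
number simultaneously (eccentricity effects sum to zero across the three
eccentricities for the position task; midpoint for speed). Dispersion
levels (t scales, gamma means/SDs) are calibrated once from the reported
credible-interval widths and variability ratios (position noise about
3.5× larger in older adults, speed noise about 2×); they are documented
fixtures, not measured quantities. The speed task's group effect on the
bias is set to zero, matching its reported non-significance.

What the generator does *not* emulate: serial dependencies between trials,
attention lapses that cluster in time, eye-movement contamination, learning
across blocks, and any non-Gaussian psychometric shape. Passing recovery
tests therefore demonstrates correctness of the estimators under the
stated model, not robustness to these real-data features.

## Screening and its interaction with recovery studies

`screen_participant()` reproduces the study's inclusion rule: a Pearson
correlation between per-level response proportion and stimulus level,
significant at $p < 0.05$, per condition. Applied to pure guessers it
rejects at the nominal 95% rate; applied to systematic observers on the
standard 160-trial conditions it passes essentially always. In recovery
studies the fits force all simulated observers in (`screen = FALSE`):
every generated observer is systematic by construction, and re-screening a
heavy-tailed cohort would selectively remove the largest-MIPS older
observers — those whose pair PSE approaches the edge of the $[-2, 1]°$
level range — biasing recovered group means low. The reported group means
of the emulated study describe observers who had already survived
screening, so forcing survivors in is the faithful simulation of that
bookkeeping.

# Group inference

`split_plot_anova()` implements the univariate mixed (split-plot) ANOVA
with participant as the random blocking unit, reporting $F$, the df pair,
$p$ and partial $\eta^2 = SS_\mathrm{eff}/(SS_\mathrm{eff}+SS_\mathrm{err})$
with each error term taken from its own stratum; sums of squares partition
exactly, which the tests assert. `welch_t()` adds the unequal-variance
companion test with Cohen's d (pooled-SD convention — the convention is a
package choice). Tukey HSD uses the randomized-block formulation within
one group. For interaction tests across measures with different units
(position vs speed; sensory vs propagation variance), values are z-scored
— optionally after a log transform — within each measure across all
participants of both groups; standardising within measure is the only
reading that makes the two measures commensurable.

For individual-differences correlations, `eccentricity_deltas()` contrasts
each participant's estimate at 15° against 5°. Differencing across
eccentricity cancels participant-specific constants — in the speed task,
the unknown perceived speed of the reference stimulus — so the MIPS change
and the speed-bias change can be correlated meaningfully.

# Problem sizes and reproducibility

The bundled recovery studies simulate cohorts of 19 young and 17 older
observers on the eccentricity-series designs (480 trials per task per
observer) and fit the hierarchical model with 2 chains × 600 retained
draws after 300 adaptation and 300 burn-in iterations — enough for
$\hat{R}$ near 1.00 on the group-level means in this model, and small
enough that a full cohort refits in well under a minute. The acceptance
script averages recovered group quantities over several independent
cohorts (12 for the position task, 4 for the speed task) to report
population-level values with small Monte Carlo error; single-cohort
recovery is what the test suite checks. Full-scale posterior coverage
calibration (hundreds of replicates) is expressible with the same
functions but is not run routinely.

# Known limitations

* The hierarchical model fits each design cell independently; it does not
  model within-participant correlation across eccentricities or durations.
* The piecewise model's bending times are weakly identified when a segment
  contains fewer than two sampled durations; the multi-start grid mitigates
  but cannot remove this.
* $\sigma^2_s$ and $\sigma^2_p$ trade off strongly when profiles are short
  or noisy; at-bound propagation estimates should be treated as censored.
* The MLE path caps the lapse at 0.1 and can be biased when the PSE sits
  outside the sampled level range; the hierarchical path is preferred for
  inference.
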