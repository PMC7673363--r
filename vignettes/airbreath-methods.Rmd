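---
title: "Methods: metabolic rate, air-breathing synchrony and group kinematics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: metabolic rate, air-breathing synchrony and group kinematics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airbreath)
```

## Scope

`airbreath` implements the full quantitative workflow of a group
air-breathing study on a facultatively air-breathing social fish: oxygen
uptake and standard metabolic rate (SMR) from intermittent-flow
respirometry, air-breathing frequency (ABF) and its temporal clustering
(synchrony) from coded surfacing events, activity and social cohesion from
video trajectories, and the mixed-effects inference layer that ties the
per-fish and per-trial measures to temperature and oxygen treatments. A
synthetic-data module generates all four input streams from known
parameters, so every estimator in the package can be validated against
ground truth without any external data.

The reference design throughout is 6 groups of 7 fish, each group measured
at two acclimation temperatures (25 and 30 °C) and filmed for 12 min at
each of three ambient oxygen saturations (100, 60, 20 %), with one 16-h
overnight respirometry run per fish per temperature.

## Respirometry and SMR

An intermittent-flow system alternates a flush phase (re-oxygenation) with
a sealed measurement phase. Defaults follow a 2-min flush every 8 min, an
oxygen sample every 2 s, and a 16-h run — 120 measurement cycles. Within
each closed phase the first minute is discarded (mixing transient) and an
ordinary least-squares line is fitted to O~2~ concentration against time;
the slope $b$ (mg O~2~ L^-1^ h^-1^, negative while the animal consumes
oxygen) is the cycle's raw signal. `fit_slope()` reports $r^2$ alongside,
defining $r^2 = 0$ for a zero-variance trace; no $r^2$-based cycle
filtering is applied by default (a threshold is available via `r2_min`).

Microbial (background) respiration is measured as blank slopes in the empty
system before and after the animal run and assumed to drift linearly in
between (`background_model()`, `background_at()`); with only one blank the
background is held constant, with a warning. No extrapolation outside the
run is permitted. Whole-animal uptake per cycle is

$$\dot{M}\mathrm{O}_2 = (|b_\mathrm{fish}| - |b_\mathrm{blank}|)\, V_\mathrm{eff},
\qquad V_\mathrm{eff} = V_\mathrm{chamber} + V_\mathrm{tubing} - V_\mathrm{fish},$$

with volumes in litres. Fish volume defaults to mass at a tissue density of
1 g mL^-1^. Cycles where the background exceeds the fish slope yield
negative uptake; these are retained and flagged rather than clamped, so the
quantile estimator below sees the raw distribution (a clamp is available).

SMR is the *lowest 20th percentile* of the per-cycle uptake values. The
package reads that as the 0.2-quantile with sorted-order linear
interpolation (plotting position $(k-1)/(n-1)$, i.e. `quantile(type = 7)`),
the dominant convention in fish respirometry; the alternative reading —
the mean of the lowest 20 % of values — is available via
`method = "mean_lowest"`, and the method actually used is recorded in every
`smr_estimate`. With a symmetric per-cycle error of relative size
$\sigma$, the 0.2-quantile of a flat uptake profile is biased low by about
$0.84\sigma$; at probe-level noise (1 % of the hourly decline) this keeps
the median SMR error near 3 %.

## Air-breathing synchrony

A surfacing event table (trial, fish, time) is binned into half-open 5-s
intervals over the 12-min trial; 5 s is short enough that one fish is very
unlikely to breathe twice within a bin, so bin counts approximate the
number of distinct breathers. An event at exactly the trial end is folded
into the last bin so boundary events never vanish. The coefficient of
dispersion is

$$\mathrm{CD} = \frac{s^2}{\bar{x}}$$

over the bin counts, with $s^2$ the sample variance ($n-1$ denominator; a
population-variance switch exists — the difference is below 1 % at 144
bins). CD > 1 (strict) flags temporally clustered, i.e. synchronised,
breathing; a homogeneous Poisson process gives CD = 1 in expectation, which
the test suite verifies by simulation. A trial with zero events has no
defined CD and is reported as missing, never as zero. Binning starts at the
trial start ($t=0$); a half-bin-offset recomputation
(`cd_bin_shift_check()`) is provided as a diagnostic for origin
sensitivity.

## Activity and cohesion

Trajectories (frame, fish, x, y) are calibrated from pixels to cm by a
scalar scale. Activity is mean speed: per fish, the mean over consecutive
valid frame pairs of displacement × frame rate; the group value is the
unweighted mean over fish, which is robust to unequal valid-frame counts
(pooled-step averaging is a switch). Cohesion is the mean pairwise
Euclidean distance among group members, per frame and then averaged over
frames — smaller values mean a tighter group. It is deliberately pairwise
rather than distance-to-centroid. Missing positions are skipped and the
denominators renormalised; nothing is interpolated. Raw tracking jitter
inflates speed, so an optional centred moving-average smoother exists but
is off by default. Frame rate and pixel calibration have no defaults: they
are properties of the recording and must be supplied.

## Mixed-effects inference

The model battery (`battery_spec()`) mirrors the study's analysis: a
Gaussian LMM of log SMR on log mass and temperature with random intercepts
for fish nested in group; a negative-binomial (log link) GLMM of the group
breath total on temperature, oxygen level, activity and cohesion with a
group random intercept; a Gaussian LMM for CD; a negative-binomial GLMM of
individual breath counts on log mass, log SMR, oxygen and temperature with
all interactions (Poisson available as a family switch, since count data
are not always over-dispersed); and Gaussian LMMs for activity and
cohesion with a temperature × oxygen interaction. Gaussian models are
fitted by maximum likelihood by default so likelihood-ratio tests are
valid; REML is a switch for final reported fits. The negative-binomial
GLMM uses Laplace-approximate ML (`lme4::glmer.nb`); adaptive quadrature
is out of scope.

Model selection (`select_model()`) is backward elimination by LRT at
α = 0.05, respecting marginality (no main effect is dropped under a
retained interaction) and one substantive rule: mass is never dropped while
SMR remains in a model, so allometric scaling stays accounted for. Ties
among droppable terms are broken by the largest p-value. Every test is
logged in a selection trace.

Variance-explained summaries use the variance-components R²:
$R^2_m = \sigma^2_f / (\sigma^2_f + \Sigma\sigma^2_\alpha + \sigma^2_\varepsilon)$
for fixed effects and $R^2_c$ adding the random-intercept variances to the
numerator, where $\sigma^2_f$ is the variance of the fixed-effect linear
predictor. For count families the observation-level variance has no exact
form; the default is the log-normal approximation
$\ln(1 + 1/\bar\lambda + 1/\theta)$ with $\bar\lambda$ the mean observed
count and $\theta$ the NB size parameter, with the trigamma form
$\psi_1\big((1/\bar\lambda + 1/\theta)^{-1}\big)$ as a switch (for Poisson,
$1/\theta = 0$).

Residual diagnostics are written as plots by the pipeline
(`model_*_residuals.png`), for visual inspection; they are not an automated
gate.

## The synthetic-data generators

The generators exist to make the statistical structure the analysis
assumes available with known truth; their defaults are synthetic choices,
not estimates from any real dataset.

* **O~2~ traces** (`simulate_o2_trace()`): during closed phases oxygen
  declines linearly at `uptake / V_eff + |background(t)|`; flushes relax
  exponentially back to saturation with a time constant set so a full
  flush reaches ≥ 99 % saturation (only closed phases are analysed, so the
  exact flush shape is immaterial). Gaussian probe noise is added last.
  An uptake that would drive the chamber to zero oxygen within a phase is
  an error, not silently clipped.
* **Breath events** (`simulate_breath_events()`): a superposition of
  independent per-fish Poisson breathing at rate $r(1-p)$ and group
  triggers at rate $r$, each joined by each fish with probability $p$
  within a 2-s jitter window. The expected per-fish rate is $r$ for every
  $p$, so synchrony can be varied at fixed overall breathing rate — the
  property the CD sensitivity checks rely on. Batch arrivals are the
  mechanism because CD responds directly to batch size; self-exciting
  processes are out of scope.
* **Trajectories** (`simulate_trajectories()`): a persistent random walk
  (step `speed_scale` cm per frame, heading noise `heading_sd`) with
  social attraction implemented as relaxation — each frame a fish closes
  a fraction $1 - e^{-\kappa}$ of its distance to the group centroid.
  The relaxation form (rather than a fixed-length step toward the
  centroid) keeps the dynamics stable and group spread strictly
  decreasing for arbitrary $\kappa \ge 0$; a fixed-length attraction step
  overshoots and oscillates once it exceeds typical inter-fish distances.
  Positions reflect at the circular arena wall (radius from the 3117 cm²
  arena area). With $\kappa = 0$ the long-run spread approaches that of
  independent uniform points in the disc (mean pairwise distance
  $128R/45\pi$), which the tests verify.
* **Full study** (`simulate_study()`): masses are log-normal around
  1.65 g; true SMR follows
  `smr_baseline * mass^mass_exponent * temp_factor^(warm)` with log-normal
  individual noise; trials get breath events and trajectories per the
  factorial design, and the tidy per-fish/per-trial tables are computed
  with the package's own analysis functions. `raw = TRUE` additionally
  emits the four raw streams (with per-cycle uptake as SMR plus sporadic
  non-negative activity bursts, so the 0.2-quantile sits at the baseline)
  for end-to-end pipeline runs.

Default effect sizes (all in `effect_config()`): SMR baseline
0.2 mg O~2~ h^-1^ at 1 g, allometric exponent 0.9, warm-acclimation factor
1.4 (≈ Q~10~ of 2 over 5 °C), breath rate 0.5 min^-1^ fish^-1^, oxygen
rate multipliers (1, 1.01, 1.46) so severe hypoxia yields ~46 % more
breaths, group-level warm multiplier 1.2, participation $p = 0.1$ (weak
synchrony: mean CD just above 1, most trials unclustered), attraction
$\kappa = 0.005$ (group spread ≈ 9 cm), step 0.12 cm frame^-1^ at 25
frames s^-1^ (≈ 3 cm s^-1^ routine swimming), probe noise 0.02 mg L^-1^,
blank slopes −0.25 to −0.60 mg L^-1^ h^-1^ (background ≈ 10–15 % of fish
uptake). These choices qualitatively mirror the directional biology —
more air breathing in hypoxia and after warm acclimation, higher SMR when
warm, weak clustering — at realistic magnitudes for a small social
catfish.

What the generators do *not* emulate: tracking identity swaps and
systematic dropouts, probe drift and calibration error, diel rhythms in
uptake, behavioural non-stationarity within a trial, refractory periods
after a breath (real surfacing is slightly under-dispersed, which is why
empirical CDs often fall below 1), and among-group behavioural
heterogeneity beyond the random intercepts. Passing tests therefore
demonstrate correctness of the estimators under the assumed structure, not
robustness to every artefact of real video and probe data.

## Numerical and design notes

* Tubing volume is rarely reported with chamber volume; the synthetic
  default is 5 mL against a 75-mL chamber. It enters only through
  $V_\mathrm{eff}$.
* Trailing partial respirometry cycles are dropped, never extrapolated.
* `estimate_smr()` requires at least 5 cycles (configurable) and refuses
  to guess from fewer.
* All generators take an explicit integer seed and restore the caller's
  RNG state; identical seeds give bit-identical outputs, which the test
  suite asserts end to end (including written CSVs).
* LRTs with zero parameter difference return p = 1; a negative statistic
  beyond floating tolerance is an error (non-nested or non-converged
  models), not a silent clamp to zero.
* Simulation scale in the validation suite: 50 noisy 16-h traces for SMR
  recovery, 1000 Poisson trials for CD calibration, 300 trials per
  participation level for CD sensitivity, 200/120/500 replicates for the
  LMM-coverage / NB-coverage / LRT-null studies. These sizes give
  Monte-Carlo error comfortably below the property margins being checked.

## Known limitations

* The negative-binomial R² residual-variance term is an approximation;
  marginal R² values for count models should be compared only within one
  approximation choice.
* `glmer.nb` on small designs (36 trials, 6 groups) can sit at a variance
  boundary; the package treats singular fits as legitimate boundary
  estimates and reports them rather than failing.
* Backward LRT selection inherits the usual caveats of stepwise
  procedures; the selection trace is always returned so the full path is
  auditable.
* The CD is origin-dependent in principle; the bin-shift diagnostic
  quantifies (but does not correct) that dependence.
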