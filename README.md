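# airbreath

Analysis toolkit for studies of **facultative air breathing in social
fishes** — species that survive on aquatic respiration in well-oxygenated
water but surface to gulp air under hypoxia, and that often do so in
groups. The package is aimed at behavioural ecophysiologists who have
three kinds of raw data — intermittent-flow respirometry oxygen traces,
time-stamped surfacing-event tables coded from video, and tracked 2-D
trajectories — and need the standard quantitative chain from those streams
to mixed-model inference about temperature and oxygen effects.

## What it computes

**Standard metabolic rate (SMR).** An intermittent-flow system alternates
flush and sealed phases (default: 2-min flush every 8 min, 16-h run, one
O₂ sample every 2 s). For each closed phase, after discarding the first
minute, the O₂ decline slope *b* (mg O₂ L⁻¹ h⁻¹) is fitted by OLS,
corrected for microbial background respiration (blank slopes before/after
the run, interpolated linearly), and converted to whole-animal uptake

    MO2 = (|b_fish| − |b_blank|) · (V_chamber + V_tubing − V_fish)

SMR is the lowest 20th percentile of the per-cycle uptake values — the
0.2-quantile with sorted-order linear interpolation (a mean-of-lowest-20%
switch exists, and the method used is recorded in the output).

**Air-breathing frequency and synchrony.** Surfacing events are tallied
per fish and per group, and binned into 5-s intervals over each 12-min
trial. Temporal clustering is the coefficient of dispersion

    CD = variance / mean

of the bin counts (sample variance, n−1): CD > 1 indicates synchronised
(clustered) breathing, CD ≈ 1 is the Poisson expectation, CD < 1 a more
uniform spread. Zero-event trials are reported as missing CD, not zero.

**Activity and cohesion.** From calibrated trajectories: group activity is
the unweighted mean over fish of per-fish mean speed (displacement ×
frame rate, cm s⁻¹); cohesion is the mean pairwise inter-individual
distance per frame averaged over frames (cm; smaller = tighter group).
Missing positions are skipped, never interpolated.

**Inference.** The mixed-model battery of such studies: Gaussian LMMs
(log SMR ~ log mass + temperature, random intercepts for fish nested in
group; CD, activity, cohesion models) and negative-binomial GLMMs with log
link for breath counts (Laplace ML via `lme4::glmer.nb`), likelihood-ratio
backward selection with a mass-retained-while-SMR-remains rule, and
marginal/conditional R² from variance components.

**Synthetic data.** `simulate_study()` generates the full factorial design
(6 groups × 7 fish × 2 temperatures × 3 oxygen levels by default) with
known ground truth — allometric SMR with log-normal noise, a
common-trigger (batch-arrival) breathing process whose participation
parameter controls synchrony at fixed breath rate, and a persistent random
walk with centroid attraction for trajectories — so every estimator can be
validated without any external dataset.

## Worked example

```r
library(airbreath)

## 1. SMR from a (here: simulated) 16-h respirometry trace
ch   <- chamber_config(75, 5, fish_mass = 1.65)   # 75 mL chamber, 5 mL tubing
plan <- cycle_plan()                              # 2 min flush / 6 min closed
trace <- simulate_o2_trace(ch, plan, uptake = rep(0.282, 120),
                           noise_sd = 0.036, seed = 42)
estimate_smr(trace_to_mo2(trace, plan, ch))
#> SMR estimate: 0.2738 mg O2/h (quantile_p0.2, 120 cycles, mean background 0.0%)

## 2. Synchrony of a fully trigger-driven trial
ev <- simulate_breath_events(7, 720, rate = 0.5, p = 1, seed = 42)
coefficient_of_dispersion(bin_events(ev, 720, 5))$cd
#> [1] 6.096878

## 3. Temperature effect on SMR across the whole synthetic study
sim <- simulate_study(seed = 42)
fit <- fit_battery_model("smr", sim$smr_table, select = FALSE)
fit$fit
#> gaussian mixed model: log(smr) ~ log(mass) + temp + (1 | group/fish_id)
#>   n = 84, logLik = 41.795 (df = 6)
#>              Estimate Std. Error  t value
#> (Intercept) -1.596908   0.060637 -26.3355
#> log(mass)    0.868611   0.113404   7.6594
#> temp30       0.325886   0.032104  10.1508
#> ...
```

The SMR estimate sits ~3 % below the generating uptake of 0.282 mg O₂ h⁻¹
(the 0.2-quantile of noisy per-cycle values is slightly conservative by
construction); the CD of 6.1 flags strong clustering, as expected when
every breath is trigger-driven; and the fitted warm-acclimation effect
0.326 on log SMR recovers the simulated multiplicative factor 1.4
(log 1.4 = 0.336) with the allometric exponent (true 0.9) alongside.

A full pipeline run — respirometry → synchrony → kinematics → join →
inference → manifest — is orchestrated by `run_all(run_config(...))` on
CSV inputs, or from a shell via the thin wrapper
`inst/scripts/airbreath.R` (subcommands `simulate`, `smr`, `synchrony`,
`kinematics`, `fit`, `run`).

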