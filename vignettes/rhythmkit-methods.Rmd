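---
title: "Circadian and heart-rate digital biomarkers from minute-level wearable data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Circadian and heart-rate digital biomarkers from minute-level wearable data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhythmkit)
```

## The problem

Consumer wrist wearables record step counts and heart rate at one-minute
resolution over free-living days. From such recordings one can compute
*digital biomarkers* of the rest-activity rhythm (RAR) and of heart-rate
physiology, and relate them to health states — here, social frailty in
community-dwelling older adults, classified by a five-item social frailty
index (score 0 = robust, 1 = social prefrailty, 2–5 = social frailty).
`rhythmkit` implements the full pipeline: ingestion and validity rules,
nonparametric rhythm indexes, an extended (sigmoidally transformed) cosinor
model, heart-rate biomarkers, the cohort statistics, and a seeded synthetic
cohort generator with known ground truth so that every stage is testable
without access to any participant data.

## Preprocessing and validity rules

Wearable minutes are trustworthy only when both streams were recorded:
minutes without heart rate have their step count marked invalid, and only
concurrent-data minutes count toward validity. The rules, all configurable:

* **Valid day**: at least 20 h of concurrent data in a calendar day
  (local midnight boundary; the boundary is inclusive, 1200 valid minutes
  qualify).
* **Inclusion**: at least 5 valid days per participant.
* **Hourly cell**: an hourly aggregate exists only when the clock hour has
  at least 30 valid minutes. Step sums from partial hours are rescaled by
  60/(valid minutes) so partially worn hours are not systematically
  underestimated; whether the original analyses rescaled is not documented,
  so `rescale_partial = FALSE` preserves raw sums.
* A heart rate of 0 is treated as missing: devices emit gaps, not zeros.

Timestamps are naive local time; no time-zone or DST arithmetic is applied
(single-region studies; the internal POSIXct representation is pinned to a
fixed zone so calendar arithmetic can never shift an hour).

## Nonparametric rhythm indexes

All operate on the valid-day × 24 hourly matrix or on the masked minute
stream; undefined metrics are returned as `NA` with a reason attribute,
never as zeros.

* **IS** (interdaily stability): variance of the mean 24-h profile over the
  total hourly variance, in [0, 1]; 1 means perfectly repeated days.
* **IV** (intradaily variability): normalized mean square of successive
  hourly differences; ≈2 for white noise, exactly 4 for strict hourly
  alternation. Differences are only taken between time-adjacent present
  hours — never across a gap or an excluded day.
* **M10 / L5 / RA**: means of the most-active 10 and least-active 5
  consecutive hours of the mean 24-h profile (circular window scan);
  RA = (M10 − L5)/(M10 + L5).
* **ICV** (intradaily coefficient of variation): for each clock hour, the
  across-day CV of the hourly values (hours with ≥2 present days and
  positive mean); ICV is the mean of these CVs. The literature also uses a
  *within-hour* reading (CV of minute values inside each hourly cell,
  averaged); both conflict in places, so the across-day formula — the one
  stated as an explicit formula in the source methods — is the default and
  `icv_mode = "within_hour"` provides the alternative.
* **Day-lag autocorrelation**: Pearson correlation of the 15/30/60-minute
  binned series with itself shifted by exactly 24 h, pairwise complete.
* **Peaks**: a smoothed robust z-score detector (window `lag = 60` samples,
  `threshold = 3` z units, `influence = 0.1`) counts maximal runs of
  positive signals per day; missing samples are skipped without resetting
  the detector state, so gaps cannot split or spuriously create peaks. The
  source literature cites the algorithm without printing its parameters;
  the defaults here are the algorithm's customary ones and are exposed as
  arguments.

## The extended cosinor model

The classic cosinor fits `mes + amp·cos((t − φ)π/12)`. Real activity and
heart-rate profiles are flatter at night and steeper at the morning rise
than any cosine, so the extended model passes the cosine through an
antilogistic (logistic-sigmoid) transform:

$$r(t) = \min + \mathrm{amp}\cdot\frac{e^{\beta(c(t)-\alpha)}}{1+e^{\beta(c(t)-\alpha)}},\qquad c(t)=\cos\!\big((t-\phi)\tfrac{\pi}{12}\big)$$

with five parameters: `minimum` (trough level), `amplitude` (trough-to-peak
range), `alpha` in (−1, 1) (peak width: small α = wide peaks, narrow
troughs), `beta` > 0 (transition steepness; large β approaches a square
wave), and the acrophase φ (peak time). Derived quantities:

* **MESOR** = minimum + amplitude/2 — the rhythm midline of the extended
  model (distinct from the classic-cosinor MESOR). Published tables in this
  area occasionally typeset the formula as `[minimum + amplitude]/2`; the
  midline definition (minimum plus *half* the amplitude) is the one that is
  internally consistent with printed group means, and is what
  `derive_phase_metrics()` implements.
* **UpMesor / DownMesor** = φ ∓ (12/π)·arccos(α) mod 24 — the clock times
  where the curve crosses the MESOR ascending/descending; surrogates for
  activity onset and offset. They are undefined when |α| ≥ 1.
* **F_pseudo** = ((RSS₀ − RSS)/4)/(RSS/(n − 5)) against the intercept-only
  null (4 numerator degrees of freedom, following the transformed-cosinor
  origin literature); larger values mean a more robust rhythm.

### Fitting

`fit_extended_cosinor()` pools all valid minutes with time-of-day as the
sole predictor (no day-level random effects) and minimizes the residual sum
of squares with a bounded quasi-Newton search (`nlminb` with analytic
gradients). Numerical choices:

* Initialization from the closed-form linear cosinor (cos/sin regression),
  with α₀ = 0 and β₀ = 2; multi-start over 4 acrophase offsets
  (0, 6, 12, 18 h) guards against phase-reflection local minima.
* Bounds: amplitude ≥ 0, α ∈ (−0.999, 0.999), β ∈ (0.001, 100]. The β cap
  prevents square-wave runaway on near-binary profiles; fitted β values in
  this domain sit well below it. φ is unconstrained during optimization
  (the model is periodic) and reported mod 24.
* Degeneracy: a fit is flagged (and its phase metrics withheld) when the
  amplitude is negligible against the data spread
  (`amplitude < 0.05·sd(x)`) *or* the pseudo-F falls below 10. The second
  rule matters because the best-fit amplitude on pure noise shrinks with
  sample size while never reaching zero; rhythm-bearing fits in this domain
  have pseudo-F in the tens to thousands, optimized pure-noise fits stay
  near the null range (≈2–3).
* Heart rate is fitted at minute resolution. Step counts are zero-inflated
  at minute level, which the Gaussian least-squares criterion handles
  poorly, so the step fit runs on the hourly aggregates by default
  (`cosinor_steps_resolution = "minute"` switches it).

## Heart-rate biomarkers

* **RHR**: mean heart rate over 15-minute blocks aligned to
  :00/:15/:30/:45 in which every minute is valid and has 0 steps. Fixed
  alignment is deterministic; whether a sliding window was ever used in
  the source scripts is undocumented, and `require_complete = FALSE`
  relaxes the completeness rule to blocks with ≥10 present zero-step
  minutes.
* **dRHR** = overall mean heart rate − RHR; a small value means a blunted
  activity–rest contrast. The overall mean is taken over all valid minutes
  of valid days (not a mean of daily means).
* **Day/night heart rate**: day = mean over [14:00, 16:00); night = the
  unweighted mean of the three window means over [0,2), [2,4), [4,6);
  missing if any window is empty.
* **RMSSD**: root mean square of successive differences over consecutive
  present pairs (gap-spanning pairs excluded), on the raw minute stream and
  on the hourly means (adjacent clock hours within the same day only).
  These are bpm-sample RMSSDs, not beat-to-beat HRV.

## The synthetic cohort generator

`simulate_cohort()` is first-class, tested code — it defines the study
conditions under which the pipeline is exercised. Per group
(robust / prefrail / frail) a `group_profile()` fixes the ground truth:

* an extended-cosinor heart-rate baseline centered on published cohort
  means (e.g. all-participants minimum ≈58.7 bpm, α ≈ −0.41, acrophase
  ≈ 14 h);
* a two-state (rest/active) minute-level Markov chain whose occupancy
  follows an antilogistic activity waveform, with geometric burst lengths
  of mean 10 + 60·fragmentation minutes — higher fragmentation produces
  longer, sparser bursts, which raises the across-day hourly variability
  (ICV) and lowers IS, the planted frail signature;
* negative-binomial step counts in active minutes (intensity calibrated
  analytically so expected daily totals hit the published group means
  9080/7809/6005);
* heart rate = baseline + coupling × 5-minute rolling step rate + AR(1)
  noise (lag-1 coefficient 0.7, innovation SD 3 bpm). AR noise rather than
  white noise keeps the raw RMSSD a nontrivial target;
* Poisson-placed non-wear blocks (mean 45 min) masking both streams at
  1.0–1.6 h/day by group.

Group questionnaires plant the frailty items so the score-based classifier
reproduces the planted label for ≥90% of draws, and the word-list-memory
score is generated as `28.3 − 0.15·age − 0.04·(ICV.st×100) + N(0, 2.5)`,
matching the fitted cognitive effect size being recovered in tests. Each
participant derives a child RNG stream from the master seed, so cohorts are
reproducible member by member and under parallel generation.

What the generator does *not* emulate: physiological sleep architecture,
accelerometry waveforms, posture artefacts, device quantization, seasonal
or weekday structure. Passing tests therefore demonstrate algorithmic
correctness and direction-level cohort behaviour, not device-level realism.

## Cohort statistics

* Frailty classification follows the index thresholds exactly
  (0 / 1 / 2–5).
* Correlations are Shapiro-Wilk-gated at α = 0.05: Pearson only when
  *both* variables pass (the conservative reading when a pair is mixed),
  Spearman otherwise, pairwise-complete.
* Group tests: Kruskal-Wallis H with tie correction; Dunn pairwise z
  statistics on the joint ranks, Bonferroni-multiplied by 3 (the three
  contrasts per variable, matching the per-variable presentation of the
  published tables) and capped at 1. The Dunn test is implemented
  in-package (no post-hoc package is depended on) and verified against an
  independently computed oracle.
* The WLM linear model is OLS with the ICV term entered ×100 for
  interpretability; the multinomial logit (robust reference, via
  `nnet::multinom`) reports Wald 95% CIs per term (the CI method is not
  documented in the source; Wald is the convention of the reporting
  format), a likelihood-ratio test against the intercept-only model for
  whole-model fit, Nagelkerke R² = (1 − (L0/L1)^{2/n})/(1 − L0^{2/n}), and
  AIC. Apparent separation (any |β| > 15) flags the model and withholds
  estimates. Complete-case analysis throughout, with dropped rows counted
  in a message.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run entirely on synthetic data:
7-day minute-level recordings; parameter-recovery over 50 seeded
simulations at noise SD 2–3 bpm; brute-force oracle comparisons over 1000
random hourly matrices; a 1000-replicate type-I-error study at n = 20 per
group; effect-recovery over 50 replicates at n = 300 (multinomial) and
n = 86 (linear); and direction checks on a seeded cohort at the published
group sizes 28/39/19 (plus 16 planted-excluded participants for the
inclusion arithmetic). These sizes give stable medians and rates while
keeping a full run in the low minutes on one CPU.

## Known limitations

* The ICV definition is contested between the across-day and within-hour
  readings; both are provided, defaults documented above.
* Cosinor fits assume a single 24-h component; multi-harmonic rhythms,
  shift-work-like schedules and free-running periods are out of scope.
* RHR requires at least one fully valid zero-step block; extremely active
  or fragmented recordings can leave it (and dRHR) undefined.
* The peak detector's counts depend on its lag/threshold/influence
  parameters; cross-study comparability requires fixing them.
* Correlation and regression helpers assume one row per participant;
  repeated-measures designs are not modelled.
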