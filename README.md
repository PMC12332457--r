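# rhythmkit

Rest-activity rhythm and heart-rate digital biomarkers from minute-level
wearable data, plus the cohort statistics used in social-frailty research.

Consumer wrist wearables (Fitbit-class devices) expose per-minute step
counts and heart rate. `rhythmkit` turns such recordings into the digital
biomarkers used to screen for social frailty in community-dwelling older
adults, and runs the accompanying cohort-level analysis:

* **Preprocessing** — concurrent-validity masking (a minute counts only
  when both streams are present), valid days (≥ 20 h of concurrent data),
  participant inclusion (≥ 5 valid days), hourly aggregates (≥ 30 valid
  minutes per cell).
* **Nonparametric rhythm indexes** — interdaily stability (IS), intradaily
  variability (IV), M10/L5 and relative amplitude RA = (M10−L5)/(M10+L5),
  intradaily coefficient of variation (ICV), day-lagged autocorrelation at
  15/30/60-minute bins, and robust z-score peak counts — each for the step
  and heart-rate streams.
* **Extended cosinor model** — the antilogistic-transformed cosine
  r(t) = min + amp · l(c(t)) with l(c) = e^{β(c−α)}/(1+e^{β(c−α)}) and
  c(t) = cos((t−φ)π/12), fitted by bounded least squares with multi-start;
  derived MESOR = min + amp/2, acrotime, UpMesor/DownMesor
  (= φ ∓ (12/π)·arccos α, the midline crossings), and a pseudo-F rhythm
  statistic.
* **Heart-rate biomarkers** — overall mean/SD/CV, resting heart rate (RHR,
  zero-step 15-minute blocks), delta RHR (dRHR = mean HR − RHR), day/night
  heart rate windows, RMSSD on raw minutes and hourly means.
* **Cohort analysis** — social frailty index classification (0 robust /
  1 prefrail / 2–5 frail), Shapiro-Wilk-gated Pearson/Spearman correlation
  matrices, Kruskal-Wallis with Dunn post hoc tests (Bonferroni over the
  three contrasts), linear models of word-list memory, and multinomial
  logistic models with the robust group as reference (OR, Wald 95% CI,
  likelihood-ratio fit, Nagelkerke R², AIC).
* **Synthetic cohorts** — a seeded generator producing minute-level
  recordings and questionnaires with group-dependent ground truth, so the
  entire pipeline is testable end to end without any participant data.

## Worked example

Simulate a small cohort, preprocess one participant and extract the full
biomarker record:

```r
library(rhythmkit)

cohort <- simulate_cohort(n_per_group = c(robust = 2, prefrail = 2, frail = 2),
                          days = 7, seed = 11)
s <- cohort$series$P001          # a robust-profile participant
s
#> <participant_series> P001
#>   10080 minutes from 2024-03-04 00:00 to 2024-03-10 23:59
#>   9300 valid minutes (92.3%)

compute_valid_days(s)
#> <valid_day_set> P001
#>   5 of 7 days valid (>= 20 h); included = TRUE

feat <- extract_biomarkers(s)
round(feat[, c("Steps", "IS.st", "IV.st", "ICV.st", "RA.st")], 3)
#>    Steps IS.st IV.st ICV.st RA.st
#> 1 8897.4 0.643 0.891  0.679     1
round(feat[, c("HR.mean", "RHR", "dRHR", "DHR", "NHR", "RMSSD.raw")], 2)
#>   HR.mean   RHR dRHR   DHR   NHR RMSSD.raw
#> 1   74.12 64.45 9.67 82.24 59.35      3.72
```

The participant walks ~8,900 steps on a valid day, rests at 64.5 bpm and
averages 74.1 bpm overall, so the activity–rest contrast dRHR is 9.7 bpm —
the robust-profile signature the generator plants. Fitting the extended
cosinor to the heart-rate stream:

```r
t <- as.numeric(format(s$time, "%H")) + as.numeric(format(s$time, "%M")) / 60
fit_extended_cosinor(t, s$heart_rate)
#> <cosinor_fit> n = 9300
#>   minimum 59.054  amplitude 22.917  alpha -0.447  beta 11.601
#>   acrotime 14.01 h  MESOR 70.512  UpMesor 6.24  DownMesor 21.78  F_pseudo 4554.6
```

The fitted curve bottoms out near 59 bpm, peaks at 14:00, and crosses its
midline (MESOR ≈ 70.5 bpm) ascending at 06:14 (UpMesor, activity onset) and
descending at 21:47 (DownMesor). The recovered parameters sit close to the
generator's planted ground truth for the robust group.

Cohort-level statistics start from the joined analysis table:

```r
feats <- extract_cohort_features(cohort$series)
cls   <- classify_frailty(cohort$questionnaire)
tab   <- build_feature_table(feats, cls, cohort$questionnaire)
kruskal_dunn(tab, tab$group, vars = c("ICV.st", "dRHR"))
multinomial_frailty_model(tab, terms = c("ICV.st", "dRHR"))
```

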