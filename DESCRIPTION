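Package: rhythmkit
Title: Rest-Activity Rhythm and Heart-Rate Digital Biomarkers from
    Minute-Level Wearable Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for turning minute-resolution step-count and heart-rate
    streams from consumer wrist wearables into circadian and heart-rate
    digital biomarkers, and for the cohort-level statistics used in social
    frailty research. Implements concurrent-validity preprocessing (valid
    days with at least 20 h of paired data, inclusion at 5 or more valid
    days), nonparametric rest-activity rhythm indexes (interdaily stability,
    intradaily variability, M10, L5, relative amplitude, intradaily
    coefficient of variation, day-lagged autocorrelation, robust z-score
    peak counts), an extended cosinor model with antilogistic transformation
    (minimum, amplitude, alpha, beta, acrophase, MESOR, UpMesor, DownMesor,
    pseudo-F), heart-rate biomarkers (resting heart rate from zero-step
    windows, delta RHR, day and night heart rate, RMSSD), a seeded synthetic
    cohort generator with known ground truth, and the cohort analysis
    pipeline (social frailty index classification, normality-gated
    correlations, Kruskal-Wallis with Dunn post hoc tests, linear and
    multinomial logistic regression).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
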