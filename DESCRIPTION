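Package: hdspeech
Title: Acoustic Analysis of Hypokinetic Dysarthria and Prediction of Freezing of Gait
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of hypokinetic dysarthria from speech recordings in
    Parkinson's disease. Extracts acoustic measures of phonation (maximum phonation time,
    jitter PPQ5, shimmer APQ5, harmonics-to-noise ratio, degree of unvoiced segments,
    relative F0 variability), articulation (formant standard deviations and 1st-99th
    interpercentile ranges, diadochokinetic rate and regularity) and prosody (intensity
    and pitch variability, pause rate, total and net speech rates) from mono WAV
    recordings of a 14-task vocal protocol. Screens features against Freezing-of-Gait
    Questionnaire items via Pearson, Spearman and Kendall partial correlations
    controlling for clinical covariates, and predicts two-year change in FOG-Q scores
    with gradient-boosted trees under repeated stratified cross-validation, reporting
    MAE, RMSE, estimation error rate, SSE and R-squared. Includes deterministic
    synthetic generators (source-filter phonation, diadochokinetic bursts,
    pseudo-read-speech, cohorts with planted partial-correlation structure) that emit
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    signal,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
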