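Package: afrr
Title: Atrial Fibrillation Discrimination from Equine RR Intervals
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating atrial fibrillation from sinus rhythm in
    horses using beat-to-beat (RR) interval variability. Implements time-domain
    heart rate variability metrics (RMSSD, SDNN, Poincare SD1), threshold-based
    artifact correction with a median-filtered local average and cubic-spline
    replacement, smoothness-priors detrending, a synthetic generator of paired
    AF/sinus-rhythm equine recordings with pace-dependent beat-detection error,
    and the diagnostic-evaluation layer: exact Wilcoxon signed-rank tests with
    Bonferroni correction, ROC curves with Mann-Whitney-consistent AUC, cutoff
    selection under a specificity floor, and exact Clopper-Pearson confidence
    intervals for sensitivity and specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Matrix, jsonlite
Suggests: testthat (>= 3.0.0), pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'rr-core.R'
    'artifact-filter.R'
    'detrend.R'
    'synthetic.R'
    'diagnostics.R'
    'study.R'
    'io.R'
    'cli.R'
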