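# afrr — atrial fibrillation discrimination from equine RR intervals

`afrr` asks a practical veterinary-cardiology question: can a short-term
heart rate variability statistic computed from beat-to-beat (RR) intervals —
as consumer heart rate monitors record them — tell atrial fibrillation (AF)
from sinus rhythm (SR) in horses, and how do the artifact-correction filters
built into HRV software help or hurt that discrimination?

AF produces an irregularly irregular ventricular response, so the root mean
square of successive differences,

```
RMSSD = sqrt( 1/(N-1) * sum_{j=1..N-1} (RR_{j+1} - RR_j)^2 ),
```

is far larger in AF than in SR. But automatic beat detection merges and
splits beats (worst during trotting), inflating SR variability, while
aggressive artifact filtering blunts the AF variability the classifier needs.
The package implements the whole evaluation pipeline:

* **RR data model & metrics** — `RRSeries`, `extractWindow()` (half-open,
  onset-based 2-min windows), `computeRMSSD()`, `computeSDNN()`,
  `computeSD1()` (Poincaré short-axis, `SD1 = RMSSD/sqrt(2)` at zero-mean
  differences), `hrvSummary()`.
* **Artifact correction** — median-filtered local average
  (`localAverage()`), strict deviation thresholds of 0.45/0.35/0.25/0.15/
  0.05 s for the `very_low` … `very_high` levels (`flagArtifacts()`),
  natural-cubic-spline replacement over unflagged support
  (`correctArtifacts()`, `applyCorrectionLevel()`), the non-destructive 8%
  successive-difference flagger (`flagSuccessiveOutliers()`), and
  smoothness-priors detrending (`smoothnessPriorsDetrend()`, lambda 500).
* **Synthetic paired study** — `synthConfig()` / `simulateStudy()` generate
  14 subjects x {rest, walk, trot} x {AF, SR} x {manually corrected ECG,
  automatic ECG, heart rate monitor}, with AV blocks, premature couplets,
  and pace-dependent missed/split-beat detection error.
* **Diagnostics** — exact paired Wilcoxon signed-rank tests
  (`wilcoxonSignedRankExact()`), Bonferroni adjustment, ROC curves whose
  trapezoidal AUC equals Mann-Whitney `U/(n1*n2)` (`rocCurve()`), cutoff
  selection maximising sensitivity at >= 80% specificity (`selectCutoff()`),
  exact Clopper-Pearson intervals (`clopperPearson()`), and the 24-cell
  study summary (`summarizeStudy()`).
* **IO / CLI** — RR text and CSV formats (`readRRFile()`, `writeRRFile()`),
  JSON run configs, and the `afrr` command (`afrrMain()`; thin wrapper in
  `inst/scripts/afrr`) with `simulate`, `hrv`, `filter` and `study`
  subcommands.

## Worked example

A small synthetic resting tachogram with second-degree AV blocks ships with
the package:

```r
library(afrr)
rr <- readRRFile(system.file("extdata", "example_sr_rest.rr", package = "afrr"))
rr
#> RRSeries with 37 intervals spanning 61.1 s
#>   mean RR 1652.1 ms; flags: original=37

hrvSummary(rr)                              # no filtering
#> HRVSummary: RMSSD 391.91 ms | SDNN 270.06 ms | SD1 277.12 ms (37 intervals, 0 corrected)

hrvSummary(rr, filterConfig("very_low"))    # 0.45 s threshold
#> HRVSummary: RMSSD 59.17 ms | SDNN 41.64 ms | SD1 41.84 ms (37 intervals, 1 corrected)
```

The unfiltered RMSSD (392 ms) is dominated by one blocked beat — a doubled
RR interval — that even the loosest correction level removes, dropping RMSSD
to the true sinus level (59 ms). This is exactly why *some* filtering helps:
frequent AV blocks at rest push SR variability into the AF range.

The full study-level evaluation:

```r
ds  <- simulateStudy(synthConfig(seed = 42))
res <- summarizeStudy(ds)
res$table1[res$table1$method == "ECG_man",
           c("pace", "median_af", "median_sr", "p_bonferroni")]
#>    pace median_af median_sr p_bonferroni
#> 1  rest     701.6    180.20      0.00293
#> 9  walk     230.6    123.54      0.00879
#> 17 trot      85.7      9.32      0.00293
```

Gold-standard AF medians exceed SR medians at every pace, surviving the
24-fold Bonferroni correction. The filtering story shows up in the ROC
table:

```r
subset(res$table2, pace == "trot" & method == "ECG_aut" & level %in% c("none", "low"),
       c(level, auc, cutoff, sens, spec))
#>    level   auc cutoff  sens  spec
#> 18  none 0.694  160.4 0.214 0.929
#> 20   low 1.000   74.1 1.000 1.000
```

Unfiltered automatic trot analysis is badly degraded by detection error;
the `low` (0.35 s) filter restores perfect separation — mirroring the
observed clinical pattern.

The same pipeline is scriptable:

```sh
Rscript inst/scripts/afrr study --seed 42 --out results/study
Rscript inst/scripts/afrr hrv --in recording.rr --filter-level low
```

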