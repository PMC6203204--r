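#' @include AllGenerics.R
NULL

## Closed vocabularies used across the package
.PACES    <- c("rest", "walk", "trot")
.RHYTHMS  <- c("AF", "SR")
.METHODS  <- c("ECG_man", "ECG_aut", "HRM")
.FLAGS    <- c("original", "outlier_8pct", "artifact", "interpolated")
.LEVELS   <- c("none", "very_low", "low", "moderate", "high", "very_high")

## Artifact-correction thresholds by level, in seconds
.LEVEL_THRESHOLDS_S <- c(very_low = 0.45, low = 0.35, moderate = 0.25,
                         high = 0.15, very_high = 0.05)

#' RRSeries: a beat-to-beat interval series
#'
#' The central container: a tachogram of strictly positive RR intervals (ms),
#' the cumulative onset time of each interval (ms, `beatTimes[1]` is the
#' window offset, usually 0), a per-interval provenance flag, and free-form
#' metadata. `beatTimes[k]` is the onset of interval `k`, so successive onset
#' differences equal the intervals.
#'
#' @slot intervals numeric, RR durations in ms, all > 0.
#' @slot beatTimes numeric, strictly increasing onset times in ms; consistent
#'   with the cumulative sum of `intervals` to within 1e-9 ms.
#' @slot flags character, one of `"original"`, `"outlier_8pct"`, `"artifact"`,
#'   `"interpolated"` per interval.
#' @slot meta list of recording metadata.
#' @seealso [RRSeries()], [computeRMSSD()], [extractWindow()]
#' @exportClass RRSeries
setClass("RRSeries",
         representation(intervals = "numeric", beatTimes = "numeric",
                        flags = "character", meta = "list"))

setValidity("RRSeries", function(object) {
  n <- length(object@intervals)
  msg <- character(0)
  if (n == 0L)
    msg <- c(msg, "RRSeries must contain at least one interval")
  if (any(!is.finite(object@intervals)) || any(object@intervals <= 0))
    msg <- c(msg, "all intervals must be finite and strictly positive")
  if (length(object@beatTimes) != n)
    msg <- c(msg, "beatTimes must have one entry per interval")
  else if (n > 1L) {
    dt <- diff(object@beatTimes)
    if (any(dt <= 0))
      msg <- c(msg, "beatTimes must be strictly increasing")
    if (max(abs(dt - object@intervals[-n])) > 1e-9)
      msg <- c(msg, "beatTimes inconsistent with cumulative sum of intervals (tolerance 1e-9 ms)")
  }
  if (length(object@flags) != n)
    msg <- c(msg, "flags must have exactly one entry per interval")
  if (!all(object@flags %in% .FLAGS))
    msg <- c(msg, sprintf("flags must be one of: %s", paste(.FLAGS, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct an RRSeries
#'
#' @param intervals numeric vector of RR intervals in ms (all > 0).
#' @param beatTimes optional onset times in ms; defaults to the cumulative
#'   sum of `intervals` starting at 0.
#' @param flags optional per-interval provenance flags; default `"original"`.
#' @param meta optional list of metadata.
#' @return an [RRSeries-class] object.
#' @examples
#' rr <- RRSeries(c(1000, 1020, 990, 1005))
#' computeRMSSD(rr)
#' @export
RRSeries <- function(intervals, beatTimes = NULL, flags = NULL, meta = list()) {
  intervals <- as.numeric(intervals)
  if (is.null(beatTimes))
    beatTimes <- cumsum(c(0, intervals))[seq_along(intervals)]
  if (is.null(flags))
    flags <- rep("original", length(intervals))
  methods::new("RRSeries", intervals = intervals, beatTimes = as.numeric(beatTimes),
               flags = flags, meta = meta)
}

#' Accessors for RRSeries
#'
#' `rrIntervals()` returns the interval vector (ms), `beatTimes()` the onset
#' times (ms), `rrFlags()` the provenance flags, `rrMeta()` the metadata list
#' and `nIntervals()` the number of intervals.
#'
#' @param x an [RRSeries-class] object.
#' @name rrIntervals
#' @aliases beatTimes rrFlags rrMeta nIntervals
NULL

#' @rdname rrIntervals
#' @export
setMethod("rrIntervals", "RRSeries", function(x) x@intervals)
#' @rdname rrIntervals
#' @export
setMethod("beatTimes", "RRSeries", function(x) x@beatTimes)
#' @rdname rrIntervals
#' @export
setMethod("rrFlags", "RRSeries", function(x) x@flags)
#' @rdname rrIntervals
#' @export
setMethod("rrMeta", "RRSeries", function(x) x@meta)
#' @rdname rrIntervals
#' @export
setMethod("nIntervals", "RRSeries", function(x) length(x@intervals))

setMethod("show", "RRSeries", function(object) {
  n <- length(object@intervals)
  cat(sprintf("RRSeries with %d intervals spanning %.1f s\n",
              n, (object@beatTimes[n] + object@intervals[n] - object@beatTimes[1]) / 1000))
  cat(sprintf("  mean RR %.1f ms; flags: %s\n",
              mean(object@intervals),
              paste(sprintf("%s=%d", names(table(object@flags)), table(object@flags)),
                    collapse = ", ")))
  if (length(object@meta))
    cat("  meta:", paste(names(object@meta), unlist(lapply(object@meta, format)),
                         sep = "=", collapse = ", "), "\n")
})

#' RecordingSegment: an RRSeries with study annotation
#'
#' A nominally 2-minute segment of one recording, annotated with subject,
#' pace (rest/walk/trot), rhythm (AF or SR) and beat-detection method
#' (`ECG_man` manually corrected gold standard, `ECG_aut` automatic ECG
#' analysis, `HRM` heart rate monitor).
#'
#' @slot series an [RRSeries-class].
#' @slot subjectId character scalar.
#' @slot pace one of `"rest"`, `"walk"`, `"trot"`.
#' @slot rhythm one of `"AF"`, `"SR"`.
#' @slot method one of `"ECG_man"`, `"ECG_aut"`, `"HRM"`.
#' @slot window numeric length-2: window start and duration in seconds.
#' @exportClass RecordingSegment
setClass("RecordingSegment",
         representation(series = "RRSeries", subjectId = "character",
                        pace = "character", rhythm = "character",
                        method = "character", window = "numeric"))

setValidity("RecordingSegment", function(object) {
  msg <- character(0)
  if (!(length(object@pace) == 1L && object@pace %in% .PACES))
    msg <- c(msg, "pace must be one of rest, walk, trot")
  if (!(length(object@rhythm) == 1L && object@rhythm %in% .RHYTHMS))
    msg <- c(msg, "rhythm must be AF or SR")
  if (!(length(object@method) == 1L && object@method %in% .METHODS))
    msg <- c(msg, "method must be one of ECG_man, ECG_aut, HRM")
  if (length(object@window) != 2L || object@window[2] <= 0)
    msg <- c(msg, "window must be (start_s, duration_s) with duration > 0")
  if (length(msg)) msg else TRUE
})

#' @rdname RecordingSegment-class
#' @param series,subjectId,pace,rhythm,method,window see slots.
#' @export
RecordingSegment <- function(series, subjectId, pace, rhythm, method,
                             window = c(0, 120)) {
  methods::new("RecordingSegment", series = series, subjectId = subjectId,
               pace = pace, rhythm = rhythm, method = method,
               window = as.numeric(window))
}

setMethod("show", "RecordingSegment", function(object) {
  cat(sprintf("RecordingSegment %s | %s | %s | %s (%d intervals, %g s window)\n",
              object@subjectId, object@pace, object@rhythm, object@method,
              length(object@series@intervals), object@window[2]))
})

#' HRVSummary: time-domain HRV metrics for one segment
#'
#' @slot rmssd,sdnn,sd1 numeric, in ms.
#' @slot nIntervals integer, intervals analysed.
#' @slot nCorrected integer, intervals replaced by interpolation.
#' @exportClass HRVSummary
setClass("HRVSummary",
         representation(rmssd = "numeric", sdnn = "numeric", sd1 = "numeric",
                        nIntervals = "integer", nCorrected = "integer"))

setValidity("HRVSummary", function(object) {
  msg <- character(0)
  if (any(c(object@rmssd, object@sdnn, object@sd1) < 0))
    msg <- c(msg, "rmssd, sdnn and sd1 must be non-negative")
  if (object@nCorrected > object@nIntervals)
    msg <- c(msg, "nCorrected cannot exceed nIntervals")
  if (length(msg)) msg else TRUE
})

setMethod("show", "HRVSummary", function(object) {
  cat(sprintf("HRVSummary: RMSSD %.2f ms | SDNN %.2f ms | SD1 %.2f ms (%d intervals, %d corrected)\n",
              object@rmssd, object@sdnn, object@sd1,
              object@nIntervals, object@nCorrected))
})

#' FilterConfig: artifact-correction and detrending settings
#'
#' The correction level fixes the deviation threshold against the
#' median-filtered local average: 0.45 s (`very_low`), 0.35 s (`low`),
#' 0.25 s (`moderate`), 0.15 s (`high`), 0.05 s (`very_high`); `none`
#' disables correction. Detrending, when enabled, applies the
#' smoothness-priors detrender with parameter `lambda` before metric
#' computation.
#'
#' @slot level character, one of the six level names.
#' @slot thresholdS numeric, threshold in seconds (NA for level `none`).
#' @slot medianWindow integer, odd beat count for the local-average median
#'   filter (default 11).
#' @slot detrend logical.
#' @slot lambda numeric, smoothness-priors regularisation parameter (>= 0).
#' @seealso [filterConfig()], [applyCorrectionLevel()]
#' @exportClass FilterConfig
setClass("FilterConfig",
         representation(level = "character", thresholdS = "numeric",
                        medianWindow = "integer", detrend = "logical",
                        lambda = "numeric"))

setValidity("FilterConfig", function(object) {
  msg <- character(0)
  if (!(length(object@level) == 1L && object@level %in% .LEVELS))
    msg <- c(msg, sprintf("level must be one of: %s", paste(.LEVELS, collapse = ", ")))
  if (object@level != "none" &&
      (!is.finite(object@thresholdS) || object@thresholdS <= 0))
    msg <- c(msg, "thresholdS must be > 0 when level is not 'none'")
  if (object@medianWindow < 3L || object@medianWindow %% 2L == 0L)
    msg <- c(msg, "medianWindow must be odd and >= 3")
  if (!is.finite(object@lambda) || object@lambda < 0)
    msg <- c(msg, "lambda must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Build a FilterConfig
#'
#' @param level correction level name; `"none"` disables correction.
#' @param medianWindow odd number of beats for the local-average median
#'   filter (default 11).
#' @param detrend logical; apply smoothness-priors detrending before metrics.
#' @param lambda detrending regularisation parameter (default 500).
#' @param thresholdS optional explicit threshold in seconds, overriding the
#'   level's standard value.
#' @return a [FilterConfig-class] object.
#' @examples
#' filterConfig("low")
#' filterConfig("moderate", detrend = TRUE)
#' @export
filterConfig <- function(level = "none", medianWindow = 11L, detrend = FALSE,
                         lambda = 500, thresholdS = NULL) {
  level <- match.arg(level, .LEVELS)
  if (is.null(thresholdS))
    thresholdS <- if (level == "none") NA_real_ else unname(.LEVEL_THRESHOLDS_S[level])
  methods::new("FilterConfig", level = level, thresholdS = as.numeric(thresholdS),
               medianWindow = as.integer(medianWindow), detrend = detrend,
               lambda = as.numeric(lambda))
}

setMethod("show", "FilterConfig", function(object) {
  cat(sprintf("FilterConfig: level=%s (threshold %s), median window %d, detrend=%s (lambda %g)\n",
              object@level,
              if (is.na(object@thresholdS)) "off" else sprintf("%.2f s", object@thresholdS),
              object@medianWindow, object@detrend, object@lambda))
})

#' CorrectionReport: bookkeeping for one artifact-correction pass
#'
#' @slot nFlagged integer, intervals flagged as artifacts.
#' @slot flaggedIndices integer positions of flagged intervals.
#' @slot nReplaced integer, intervals actually replaced (equals `nFlagged`
#'   when correction is applied).
#' @slot nExtrapolated integer, flagged intervals outside the spline support
#'   range, replaced by the nearest support value.
#' @slot baselineFallback logical, TRUE when fewer than 4 support beats
#'   remained and flagged intervals were replaced by the local-average
#'   baseline instead of a spline.
#' @exportClass CorrectionReport
setClass("CorrectionReport",
         representation(nFlagged = "integer", flaggedIndices = "integer",
                        nReplaced = "integer", nExtrapolated = "integer",
                        baselineFallback = "logical"))

setMethod("show", "CorrectionReport", function(object) {
  cat(sprintf("CorrectionReport: %d flagged, %d replaced (%d extrapolated%s)\n",
              object@nFlagged, object@nReplaced, object@nExtrapolated,
              if (object@baselineFallback) ", baseline fallback" else ""))
})

#' SynthConfig: parameters of the synthetic equine study generator
#'
#' Defaults emulate the paired-design study conditions: 14 subjects recorded
#' at rest, walk and trot in AF and, after cardioversion, in sinus rhythm,
#' each rendered under three beat-detection methods. Sinus rhythm is a
#' pace-specific mean with slow sinusoidal modulation, Gaussian jitter,
#' occasional second-degree AV blocks (rest/walk) and atrial premature
#' couplets (rest); AF is an i.i.d. lognormal tachogram with pace-specific
#' mean and coefficient of variation. Detection methods differ by per-beat
#' missed-beat (merge) and split-beat probabilities, worst at trot.
#'
#' @slot nSubjects integer.
#' @slot seed integer master seed; every segment derives a named sub-stream.
#' @slot srMeanRR,afMeanRR named numeric (rest/walk/trot), mean RR in ms.
#' @slot srJitterSd named numeric, beat-to-beat Gaussian jitter sd in ms.
#' @slot srOscillation numeric length 2: amplitude (ms) and period (s) of the
#'   slow sinus-rhythm oscillation.
#' @slot avbProb per-beat probability of a blocked beat (rest and walk).
#' @slot apdProb per-beat probability of a premature short-long couplet
#'   (rest, sinus rhythm only).
#' @slot afCv named numeric, coefficient of variation of AF intervals.
#' @slot artifactRates list: method -> pace -> c(miss, split) per-beat
#'   probabilities.
#' @slot durationS numeric, nominal segment duration in seconds (120).
#' @seealso [synthConfig()], [simulateStudy()]
#' @exportClass SynthConfig
setClass("SynthConfig",
         representation(nSubjects = "integer", seed = "integer",
                        srMeanRR = "numeric", afMeanRR = "numeric",
                        srJitterSd = "numeric", srOscillation = "numeric",
                        avbProb = "numeric", apdProb = "numeric",
                        afCv = "numeric", artifactRates = "list",
                        durationS = "numeric"))

setValidity("SynthConfig", function(object) {
  msg <- character(0)
  probs <- c(object@avbProb, object@apdProb,
             unlist(object@artifactRates, use.names = FALSE))
  if (any(probs < 0 | probs > 1))
    msg <- c(msg, "all probabilities must lie in [0, 1]")
  if (any(c(object@srMeanRR, object@afMeanRR) <= 0) ||
      any(object@srJitterSd < 0) || any(object@afCv < 0))
    msg <- c(msg, "means must be positive; jitter sd and CV non-negative")
  for (p in .PACES)
    for (r in c("srMeanRR", "afMeanRR", "srJitterSd", "afCv"))
      if (!p %in% names(methods::slot(object, r)))
        msg <- c(msg, sprintf("%s must be named with entries rest, walk, trot", r))
  for (m in c("ECG_aut", "HRM")) {
    ar <- object@artifactRates[[m]]
    if (!is.null(ar) && any(ar[["trot"]] < ar[["rest"]]))
      msg <- c(msg, sprintf("trot artifact rates must be >= rest rates for %s", m))
  }
  if (object@nSubjects < 1L) msg <- c(msg, "nSubjects must be >= 1")
  if (object@durationS <= 0) msg <- c(msg, "durationS must be > 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "SynthConfig", function(object) {
  cat(sprintf("SynthConfig: %d subjects, seed %d, %g s segments\n",
              object@nSubjects, object@seed, object@durationS))
  cat(sprintf("  SR mean RR (ms): %s | AF mean RR: %s\n",
              paste(object@srMeanRR, collapse = "/"),
              paste(object@afMeanRR, collapse = "/")))
})

#' StudyDataset: the paired AF/SR study collection
#'
#' @slot segments list of [RecordingSegment-class] covering subject x pace x
#'   rhythm x method.
#' @slot config the [SynthConfig-class] actually used (if generated).
#' @exportClass StudyDataset
setClass("StudyDataset",
         representation(segments = "list", config = "SynthConfig"))

setValidity("StudyDataset", function(object) {
  if (!all(vapply(object@segments, methods::is, logical(1), "RecordingSegment")))
    return("all segments must be RecordingSegment objects")
  ann <- segmentTable(object)
  for (s in unique(ann$subject))
    for (p in .PACES) {
      got <- ann$rhythm[ann$subject == s & ann$pace == p]
      if (!all(.RHYTHMS %in% got))
        return(sprintf("paired design broken: subject %s lacks AF or SR at %s", s, p))
    }
  TRUE
})

setMethod("show", "StudyDataset", function(object) {
  ann <- segmentTable(object)
  cat(sprintf("StudyDataset: %d segments (%d subjects x %d paces x %d rhythms x %d methods)\n",
              nrow(ann), length(unique(ann$subject)), length(unique(ann$pace)),
              length(unique(ann$rhythm)), length(unique(ann$method))))
})

#' ROCResult: ROC curve, AUC and chosen operating point
#'
#' Produced by [rocCurve()] and completed by [selectCutoff()]. AF is the
#' positive class; the classification rule is "score >= cutoff implies AF".
#'
#' @slot points data.frame with columns cutoff, sens, spec, tp, fp, tn, fn.
#' @slot auc numeric in [0, 1] (trapezoidal; equals Mann-Whitney U/(n1 n2)).
#' @slot cutoff,sens,spec chosen operating point (NA before selection).
#' @slot sensCi,specCi numeric length-2 exact Clopper-Pearson 95% intervals.
#' @slot nPos,nNeg class sizes.
#' @exportClass ROCResult
setClass("ROCResult",
         representation(points = "data.frame", auc = "numeric",
                        cutoff = "numeric", sens = "numeric", spec = "numeric",
                        sensCi = "numeric", specCi = "numeric",
                        nPos = "integer", nNeg = "integer"))

setValidity("ROCResult", function(object) {
  msg <- character(0)
  if (!is.finite(object@auc) || object@auc < 0 || object@auc > 1)
    msg <- c(msg, "auc must lie in [0, 1]")
  if (!is.na(object@sens) && length(object@sensCi) == 2L &&
      (object@sens < object@sensCi[1] - 1e-12 || object@sens > object@sensCi[2] + 1e-12))
    msg <- c(msg, "sensitivity CI must contain the point estimate")
  if (!is.na(object@spec) && length(object@specCi) == 2L &&
      (object@spec < object@specCi[1] - 1e-12 || object@spec > object@specCi[2] + 1e-12))
    msg <- c(msg, "specificity CI must contain the point estimate")
  if (length(msg)) msg else TRUE
})

setMethod("show", "ROCResult", function(object) {
  cat(sprintf("ROCResult: AUC %.3f over %d points (%d pos, %d neg)\n",
              object@auc, nrow(object@points), object@nPos, object@nNeg))
  if (!is.na(object@cutoff))
    cat(sprintf("  cutoff %.1f ms: sens %.2f (%.2f-%.2f), spec %.2f (%.2f-%.2f)\n",
                object@cutoff, object@sens, object@sensCi[1], object@sensCi[2],
                object@spec, object@specCi[1], object@specCi[2]))
})
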