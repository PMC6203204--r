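#' @include rr-core.R
NULL

#' Median-filtered local average of an RR series
#'
#' Element `k` is the median of the intervals in a centered window of
#' `medianWindow` beats (truncated at the series edges). Median filtering
#' makes the baseline robust to isolated outliers: a single aberrant beat in
#' a window of 3 or more does not move the baseline at neighbouring
#' positions.
#'
#' @param series an [RRSeries-class] or numeric vector of intervals (ms).
#' @param medianWindow odd window length in beats (>= 3).
#' @return numeric vector of per-interval baselines (ms).
#' @export
localAverage <- function(series, medianWindow = 11L) {
  x <- if (methods::is(series, "RRSeries")) series@intervals else as.numeric(series)
  if (length(x) == 0L) stop("series must be non-empty", call. = FALSE)
  medianWindow <- as.integer(medianWindow)
  if (medianWindow < 3L || medianWindow %% 2L == 0L)
    stop("medianWindow must be odd and >= 3", call. = FALSE)
  h <- medianWindow %/% 2L
  n <- length(x)
  vapply(seq_len(n), function(k) {
    stats::median(x[max(1L, k - h):min(n, k + h)])
  }, numeric(1))
}

#' Flag RR intervals deviating from the local average
#'
#' An interval is flagged as an artifact when it differs from the
#' median-filtered local average by strictly more than the threshold.
#'
#' @param series an [RRSeries-class] or numeric vector (ms).
#' @param thresholdS threshold in seconds (> 0); converted to ms internally.
#' @param medianWindow odd window length for [localAverage()].
#' @return logical mask, one entry per interval.
#' @export
flagArtifacts <- function(series, thresholdS, medianWindow = 11L) {
  x <- if (methods::is(series, "RRSeries")) series@intervals else as.numeric(series)
  if (!is.finite(thresholdS) || thresholdS <= 0)
    stop("thresholdS must be > 0", call. = FALSE)
  abs(x - localAverage(x, medianWindow)) > thresholdS * 1000
}

.emptyReport <- function() {
  methods::new("CorrectionReport", nFlagged = 0L, flaggedIndices = integer(0),
               nReplaced = 0L, nExtrapolated = 0L, baselineFallback = FALSE)
}

#' Replace flagged intervals by cubic-spline interpolation
#'
#' Fits a natural cubic spline to (onset time, interval) over the unflagged
#' beats only and evaluates it at the onset times of the flagged beats,
#' which are replaced and re-flagged `"interpolated"`. Unflagged intervals
#' are bit-identical in the output. Flagged beats outside the support range
#' are replaced by the nearest support value (counted as extrapolated in the
#' report); all replacements are clamped to the range of the support
#' intervals so sparse support cannot produce non-physiologic values. Onset
#' times are recomputed from the corrected intervals.
#'
#' @param series an [RRSeries-class].
#' @param mask logical mask from [flagArtifacts()], one entry per interval.
#' @return list with elements `series` (corrected [RRSeries-class]) and
#'   `report` (a [CorrectionReport-class]).
#' @export
correctArtifacts <- function(series, mask) {
  stopifnot(methods::is(series, "RRSeries"), is.logical(mask))
  n <- length(series@intervals)
  if (length(mask) != n)
    stop("mask length must match the number of intervals", call. = FALSE)
  if (!any(mask))
    return(list(series = series, report = .emptyReport()))
  support <- which(!mask)
  if (length(support) < 4L)
    stop(sprintf(
      "cubic-spline correction requires at least 4 unflagged support intervals, got %d",
      length(support)), call. = FALSE)
  t <- series@beatTimes
  x <- series@intervals
  flagged <- which(mask)
  fit <- stats::splinefun(t[support], x[support], method = "natural")
  repl <- fit(t[flagged])
  # nearest-support extrapolation for flagged runs touching the boundary
  lo <- t[flagged] < t[support[1]]
  hi <- t[flagged] > t[support[length(support)]]
  repl[lo] <- x[support[1]]
  repl[hi] <- x[support[length(support)]]
  rng <- range(x[support])
  repl <- pmin(pmax(repl, rng[1]), rng[2])
  newx <- x
  newx[flagged] <- repl
  flags <- series@flags
  flags[flagged] <- "interpolated"
  methods::validObject(out <- methods::new("RRSeries",
    intervals = newx,
    beatTimes = t[1] + cumsum(c(0, newx))[seq_len(n)],
    flags = flags, meta = series@meta))
  report <- methods::new("CorrectionReport",
    nFlagged = length(flagged), flaggedIndices = flagged,
    nReplaced = length(flagged), nExtrapolated = as.integer(sum(lo) + sum(hi)),
    baselineFallback = FALSE)
  list(series = out, report = report)
}

#' Apply an artifact-correction level to a series
#'
#' Composition of [flagArtifacts()] at the level's threshold and
#' [correctArtifacts()]; level `"none"` is the identity. The local average
#' is computed once from the raw series and all flagged beats are replaced
#' in a single pass. In the degenerate case where flagging leaves fewer than
#' 4 support beats (heavy flagging of a high-variability series at a tight
#' threshold), flagged intervals are replaced by the local-average baseline
#' itself and the report's `baselineFallback` is set.
#'
#' @param series an [RRSeries-class].
#' @param config a [FilterConfig-class].
#' @return list with elements `series` and `report` as for
#'   [correctArtifacts()].
#' @export
applyCorrectionLevel <- function(series, config) {
  stopifnot(methods::is(series, "RRSeries"), methods::is(config, "FilterConfig"))
  if (config@level == "none")
    return(list(series = series, report = .emptyReport()))
  mask <- flagArtifacts(series, config@thresholdS, config@medianWindow)
  if (!any(mask))
    return(list(series = series, report = .emptyReport()))
  if (sum(!mask) >= 4L)
    return(correctArtifacts(series, mask))
  ## degenerate: not enough spline support; fall back to the median baseline
  baseline <- localAverage(series@intervals, config@medianWindow)
  flagged <- which(mask)
  newx <- series@intervals
  newx[flagged] <- baseline[flagged]
  flags <- series@flags
  flags[flagged] <- "interpolated"
  out <- methods::new("RRSeries",
    intervals = newx,
    beatTimes = series@beatTimes[1] + cumsum(c(0, newx))[seq_along(newx)],
    flags = flags, meta = series@meta)
  report <- methods::new("CorrectionReport",
    nFlagged = length(flagged), flaggedIndices = flagged,
    nReplaced = length(flagged), nExtrapolated = 0L, baselineFallback = TRUE)
  list(series = out, report = report)
}

#' Flag successive-difference outliers (8% rule)
#'
#' Marks interval `k` (k >= 2) when it differs from the previous interval by
#' strictly more than `limitFraction` of that previous interval. This mirrors
#' the detection-limit convention of ambulatory ECG software: outliers are
#' flagged but remain in the analysis; the series is never modified.
#'
#' @param series an [RRSeries-class] or numeric vector (ms).
#' @param limitFraction relative detection limit (default 0.08, i.e. 8%).
#' @return logical mask; first element is always `FALSE`.
#' @export
flagSuccessiveOutliers <- function(series, limitFraction = 0.08) {
  x <- if (methods::is(series, "RRSeries")) series@intervals else as.numeric(series)
  .assertMinIntervals(x, 2L, "successive-outlier flagging")
  c(FALSE, abs(diff(x)) > limitFraction * x[-length(x)])
}

#' Annotate a series with 8% successive-difference outlier flags
#'
#' Convenience wrapper over [flagSuccessiveOutliers()] that returns a copy
#' of the series with `"outlier_8pct"` written into the flags of intervals
#' still marked `"original"`. Intervals are untouched.
#'
#' @inheritParams flagSuccessiveOutliers
#' @return an [RRSeries-class].
#' @export
annotateOutliers <- function(series, limitFraction = 0.08) {
  stopifnot(methods::is(series, "RRSeries"))
  mask <- flagSuccessiveOutliers(series, limitFraction)
  flags <- series@flags
  flags[mask & flags == "original"] <- "outlier_8pct"
  methods::initialize(series, flags = flags)
}

#' Serialise a FilterConfig to JSON
#'
#' @param config a [FilterConfig-class].
#' @return a JSON string.
#' @seealso [filterConfigFromJSON()]
#' @export
filterConfigToJSON <- function(config) {
  stopifnot(methods::is(config, "FilterConfig"))
  jsonlite::toJSON(list(level = config@level, threshold_s = config@thresholdS,
                        median_window = config@medianWindow,
                        detrend = config@detrend, lambda = config@lambda),
                   auto_unbox = TRUE, digits = NA, na = "null")
}

#' Deserialise a FilterConfig from JSON
#'
#' @param json a JSON string or file path produced by [filterConfigToJSON()].
#' @return a [FilterConfig-class].
#' @export
filterConfigFromJSON <- function(json) {
  x <- jsonlite::fromJSON(json)
  filterConfig(level = x$level, medianWindow = x$median_window,
               detrend = isTRUE(x$detrend), lambda = x$lambda,
               thresholdS = if (is.null(x$threshold_s)) NULL else x$threshold_s)
}
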