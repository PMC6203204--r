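#' @include AllClasses.R
NULL

.assertMinIntervals <- function(x, nmin = 2L, what = "metric") {
  if (length(x) < nmin)
    stop(sprintf("%s requires at least %d intervals, got %d",
                 what, nmin, length(x)), call. = FALSE)
}

#' @rdname computeRMSSD
#' @export
setMethod("computeRMSSD", "numeric", function(x) {
  .assertMinIntervals(x, 2L, "RMSSD")
  d <- diff(x)
  sqrt(sum(d * d) / (length(x) - 1L))
})

#' @rdname computeRMSSD
#' @export
setMethod("computeRMSSD", "RRSeries", function(x) computeRMSSD(x@intervals))

#' @rdname computeSDNN
#' @export
setMethod("computeSDNN", "numeric", function(x) {
  .assertMinIntervals(x, 2L, "SDNN")
  stats::sd(x)
})

#' @rdname computeSDNN
#' @export
setMethod("computeSDNN", "RRSeries", function(x) computeSDNN(x@intervals))

#' @rdname computeSD1
#' @export
setMethod("computeSD1", "numeric", function(x) {
  .assertMinIntervals(x, 2L, "SD1")
  d <- diff(x)
  # population-style sd over the N-1 differences: makes SD1 = RMSSD/sqrt(2)
  # exact when the differences have zero mean
  sqrt(sum((d - mean(d))^2) / length(d)) / sqrt(2)
})

#' @rdname computeSD1
#' @export
setMethod("computeSD1", "RRSeries", function(x) computeSD1(x@intervals))

#' Extract a time window from an RRSeries
#'
#' Returns the sub-series of intervals whose onset lies in the half-open
#' window `[start_s, start_s + duration_s)`. Onset times are re-zeroed to the
#' window start (the first retained onset keeps its offset within the
#' window); flags and metadata are carried over. Extraction is idempotent:
#' re-extracting `[0, duration_s)` from the result is the identity.
#'
#' @param series an [RRSeries-class].
#' @param startS window start in seconds (>= 0).
#' @param durationS window duration in seconds (> 0).
#' @return an [RRSeries-class].
#' @examples
#' rr <- RRSeries(rep(1000, 300))
#' w <- extractWindow(rr, 60, 120)   # 2-min window starting at 1 min
#' range(beatTimes(w))
#' @export
extractWindow <- function(series, startS, durationS) {
  stopifnot(methods::is(series, "RRSeries"))
  if (startS < 0) stop("startS must be >= 0", call. = FALSE)
  if (durationS <= 0) stop("durationS must be > 0", call. = FALSE)
  startMs <- startS * 1000
  endMs <- startMs + durationS * 1000
  onset <- series@beatTimes
  keep <- onset >= startMs & onset < endMs
  if (sum(keep) < 2L)
    stop(sprintf("window [%g s, %g s) contains %d intervals; at least 2 required",
                 startS, startS + durationS, sum(keep)), call. = FALSE)
  methods::new("RRSeries",
               intervals = series@intervals[keep],
               beatTimes = onset[keep] - startMs,
               flags = series@flags[keep],
               meta = series@meta)
}

#' Compute an HRV summary for a series under a filter configuration
#'
#' Applies the configuration's artifact-correction level (see
#' [applyCorrectionLevel()]), optionally detrends with the smoothness-priors
#' detrender, then computes RMSSD, SDNN and SD1 in ms.
#'
#' @param series an [RRSeries-class].
#' @param config a [FilterConfig-class]; default: no correction, no
#'   detrending.
#' @return an [HRVSummary-class].
#' @examples
#' rr <- RRSeries(c(rep(1000, 5), 2000, rep(1000, 5)))
#' hrvSummary(rr, filterConfig("very_low"))
#' @export
hrvSummary <- function(series, config = filterConfig("none")) {
  stopifnot(methods::is(series, "RRSeries"), methods::is(config, "FilterConfig"))
  res <- applyCorrectionLevel(series, config)
  x <- res$series@intervals
  if (config@detrend)
    x <- smoothnessPriorsDetrend(x, config@lambda)$detrended
  methods::new("HRVSummary",
               rmssd = computeRMSSD(x), sdnn = computeSDNN(x),
               sd1 = computeSD1(x), nIntervals = length(x),
               nCorrected = res$report@nReplaced)
}
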