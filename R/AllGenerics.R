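#' Root mean square of successive RR-interval differences
#'
#' RMSSD is the canonical short-term heart rate variability metric:
#' \deqn{RMSSD = \sqrt{\frac{1}{N-1}\sum_{j=1}^{N-1} (RR_{j+1} - RR_j)^2}}
#' with \eqn{N} the number of intervals. Units are those of the input
#' (milliseconds throughout this package).
#'
#' @param x an [RRSeries] or a numeric vector of RR intervals (ms).
#' @return RMSSD in ms (non-negative scalar).
#' @seealso [computeSDNN()], [computeSD1()]
#' @examples
#' computeRMSSD(c(1000, 1100, 1000, 1100, 1000))  # exactly 100
#' @export
setGeneric("computeRMSSD", function(x) standardGeneric("computeRMSSD"))

#' Standard deviation of RR intervals (SDNN)
#'
#' Sample standard deviation (divisor N - 1) of the intervals in a segment.
#'
#' @inheritParams computeRMSSD
#' @return SDNN in ms.
#' @export
setGeneric("computeSDNN", function(x) standardGeneric("computeSDNN"))

#' Poincare-plot short-axis dispersion (SD1)
#'
#' SD1 is the dispersion of the Poincare cloud \eqn{(RR_j, RR_{j+1})}
#' perpendicular to the identity line. It is computed here as
#' \eqn{SD1 = \sigma(\Delta RR)/\sqrt{2}} where \eqn{\sigma} is the
#' mean-subtracted standard deviation of the successive differences with
#' divisor equal to the number of differences, so that the identity
#' \eqn{SD1 = RMSSD/\sqrt{2}} is exact whenever the differences have zero
#' mean.
#'
#' @inheritParams computeRMSSD
#' @return SD1 in ms.
#' @export
setGeneric("computeSD1", function(x) standardGeneric("computeSD1"))

#' @rdname smoothnessPriorsDetrend
#' @export
setGeneric("smoothnessPriorsDetrend",
           function(x, lambda = 500) standardGeneric("smoothnessPriorsDetrend"))

#' @rdname rrIntervals
#' @export
setGeneric("rrIntervals", function(x) standardGeneric("rrIntervals"))

#' @rdname rrIntervals
#' @export
setGeneric("beatTimes", function(x) standardGeneric("beatTimes"))

#' @rdname rrIntervals
#' @export
setGeneric("rrFlags", function(x) standardGeneric("rrFlags"))

#' @rdname rrIntervals
#' @export
setGeneric("rrMeta", function(x) standardGeneric("rrMeta"))

#' @rdname rrIntervals
#' @export
setGeneric("nIntervals", function(x) standardGeneric("nIntervals"))
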