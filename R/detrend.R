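#' @include artifact-filter.R
NULL

#' Smoothness-priors detrending of an RR series
#'
#' Removes the slow trend of a tachogram by regularised least squares: the
#' trend \eqn{\tau} minimises \eqn{\|z - \tau\|^2 + \lambda^2 \|D_2 \tau\|^2}
#' with \eqn{D_2} the second-difference operator, i.e.
#' \eqn{\tau = (I + \lambda^2 D_2^\top D_2)^{-1} z}. `lambda = 0` returns the
#' input unchanged (all-zero detrended component); as `lambda` grows the
#' trend approaches the least-squares line (affine functions span the null
#' space of \eqn{D_2}). The default `lambda = 500` matches common HRV
#' software practice.
#'
#' The solve uses a sparse QR factorisation of the stacked banded system
#' \eqn{[I; \lambda D_2]\tau \approx [z; 0]}, which is numerically stable for
#' very large `lambda` and keeps memory linear in the series length.
#'
#' @param x an [RRSeries-class] or numeric vector of intervals (ms), length
#'   >= 3.
#' @param lambda regularisation parameter, >= 0 (dimensionless).
#' @return list with numeric elements `trend` and `detrended` (ms), each the
#'   length of the input.
#' @examples
#' z <- 1000 + seq(0, 50, length.out = 100) + rnorm(100, sd = 5)
#' d <- smoothnessPriorsDetrend(z, lambda = 500)
#' sd(d$detrended) < sd(z)
#' @rdname smoothnessPriorsDetrend
#' @export
setMethod("smoothnessPriorsDetrend", "numeric", function(x, lambda = 500) {
  if (length(x) < 3L)
    stop("smoothness-priors detrending requires at least 3 intervals", call. = FALSE)
  if (!is.finite(lambda) || lambda < 0)
    stop("lambda must be a finite value >= 0", call. = FALSE)
  n <- length(x)
  if (lambda == 0)
    return(list(trend = x, detrended = rep(0, n)))
  D2 <- Matrix::bandSparse(n - 2L, n, k = 0:2,
                           diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                            rep(1, n - 2L)))
  M <- rbind(Matrix::Diagonal(n), lambda * D2)
  rhs <- c(x, rep(0, n - 2L))
  trend <- as.numeric(Matrix::qr.coef(Matrix::qr(M), rhs))
  list(trend = trend, detrended = x - trend)
})

#' @rdname smoothnessPriorsDetrend
#' @export
setMethod("smoothnessPriorsDetrend", "RRSeries", function(x, lambda = 500) {
  smoothnessPriorsDetrend(x@intervals, lambda)
})
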