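#' @include synthetic.R
NULL

#' Exact paired Wilcoxon signed-rank test
#'
#' Two-sided exact p-value for paired samples, from the full distribution of
#' the positive-rank sum over all 2^n sign assignments of the ranked
#' absolute differences. Zero differences are dropped before ranking; tied
#' absolute differences receive mid-ranks (the distribution is computed by
#' exact convolution over the doubled ranks, equivalent to full
#' enumeration). The two-sided p is `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' @param x,y paired numeric vectors of equal length; at least 5 non-zero
#'   differences are required and at most 25 are supported in exact mode
#'   (use [wilcoxonSignedRankNormal()] beyond that).
#' @return the exact two-sided p-value.
#' @examples
#' # 14 uniformly positive differences: p = 2 / 2^14
#' wilcoxonSignedRankExact(2:15, 1:14)
#' @export
wilcoxonSignedRankExact <- function(x, y) {
  if (length(x) != length(y))
    stop("x and y must be paired vectors of equal length", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 5L)
    stop(sprintf("exact test requires at least 5 non-zero differences, got %d", n),
         call. = FALSE)
  if (n > 25L)
    stop(paste("exact enumeration is limited to 25 non-zero differences;",
               "use wilcoxonSignedRankNormal() for the normal approximation"),
         call. = FALSE)
  r2 <- as.integer(round(2 * rank(abs(d))))   # doubled mid-ranks are integers
  w2 <- sum(r2[d > 0])
  total <- sum(r2)
  ## exact distribution of the doubled positive-rank sum by convolution
  f <- numeric(total + 1L)
  f[1L] <- 1
  for (ri in r2)
    f <- f + c(numeric(ri), f[seq_len(total + 1L - ri)])
  counts <- sum(f)                            # 2^n
  ple <- sum(f[seq_len(w2 + 1L)]) / counts
  pge <- sum(f[(w2 + 1L):(total + 1L)]) / counts
  min(1, 2 * min(ple, pge))
}

#' Normal-approximation paired Wilcoxon signed-rank test
#'
#' Large-sample companion to [wilcoxonSignedRankExact()], with tie-corrected
#' variance and continuity correction.
#'
#' @inheritParams wilcoxonSignedRankExact
#' @param correct logical, apply the 0.5 continuity correction.
#' @return the approximate two-sided p-value.
#' @export
wilcoxonSignedRankNormal <- function(x, y, correct = TRUE) {
  if (length(x) != length(y))
    stop("x and y must be paired vectors of equal length", call. = FALSE)
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n < 5L)
    stop(sprintf("test requires at least 5 non-zero differences, got %d", n),
         call. = FALSE)
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tie <- table(r)
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(tie^3 - tie) / 48
  z <- w - mu
  if (correct) z <- sign(z) * max(0, abs(z) - 0.5)
  z <- z / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Bonferroni adjustment
#'
#' @param p raw p-value(s) in [0, 1].
#' @param m number of comparisons (>= 1); the study design uses 24.
#' @return `min(1, m * p)`, vectorised over `p`.
#' @export
bonferroniAdjust <- function(p, m) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]", call. = FALSE)
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  pmin(1, m * p)
}

#' ROC curve and AUC for an AF-vs-SR discriminator
#'
#' AF is the positive class and higher scores indicate AF; the
#' classification rule is "score >= cutoff implies AF". Candidate cutoffs
#' are the midpoints between adjacent distinct sorted scores plus sentinels
#' below and above all scores, so the degenerate all-positive and
#' all-negative rules are always swept. The AUC is the trapezoidal area over
#' the swept points, which equals the Mann-Whitney statistic
#' \eqn{U/(n_1 n_2)} with ties counted one half.
#'
#' @param scores numeric discriminator values (e.g. RMSSD in ms).
#' @param labels class labels, one per score; values in `{"AF", "SR"}` (or
#'   any two levels with `positive` naming the positive one).
#' @param positive the positive-class label (default `"AF"`).
#' @return an [ROCResult-class] with `points` and `auc` filled in; feed it
#'   to [selectCutoff()] to choose an operating point.
#' @export
rocCurve <- function(scores, labels, positive = "AF") {
  labels <- as.character(labels)
  if (length(scores) != length(labels))
    stop("scores and labels must have equal length", call. = FALSE)
  isPos <- labels == positive
  nPos <- sum(isPos)
  nNeg <- sum(!isPos)
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present to build a ROC curve", call. = FALSE)
  pos <- scores[isPos]
  neg <- scores[!isPos]
  s <- sort(unique(scores))
  cutoffs <- c(s[1] - 1, if (length(s) > 1) (s[-1] + s[-length(s)]) / 2,
               s[length(s)] + 1)
  pts <- do.call(rbind, lapply(cutoffs, function(ct) {
    tp <- sum(pos >= ct)
    tn <- sum(neg < ct)
    data.frame(cutoff = ct, sens = tp / nPos, spec = tn / nNeg,
               tp = tp, fp = nNeg - tn, tn = tn, fn = nPos - tp)
  }))
  ## trapezoid over (FPR, TPR), ordered by increasing FPR
  ord <- order(1 - pts$spec, pts$sens)
  fpr <- (1 - pts$spec)[ord]
  tpr <- pts$sens[ord]
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  methods::new("ROCResult", points = pts, auc = auc,
               cutoff = NA_real_, sens = NA_real_, spec = NA_real_,
               sensCi = c(NA_real_, NA_real_), specCi = c(NA_real_, NA_real_),
               nPos = as.integer(nPos), nNeg = as.integer(nNeg))
}

#' Choose a cutoff maximising sensitivity under a specificity floor
#'
#' Among swept ROC points with specificity at or above `specFloor`, the
#' point with maximal sensitivity is chosen; ties are broken by higher
#' specificity, then by lower cutoff. If no point meets the floor, the
#' fallback maximises sensitivity + specificity (same tie-breaks). The
#' chosen point's sensitivity and specificity receive exact Clopper-Pearson
#' 95% confidence intervals.
#'
#' @param roc an [ROCResult-class] from [rocCurve()].
#' @param specFloor minimum acceptable specificity (default 0.80).
#' @param conf confidence level for the exact binomial intervals.
#' @return the [ROCResult-class] with the chosen operating point filled in.
#' @export
selectCutoff <- function(roc, specFloor = 0.80, conf = 0.95) {
  stopifnot(methods::is(roc, "ROCResult"))
  pts <- roc@points
  if (nrow(pts) < 1L) stop("ROC has no points", call. = FALSE)
  elig <- pts$spec >= specFloor
  cand <- if (any(elig)) pts[elig, , drop = FALSE] else pts
  key <- if (any(elig)) cand$sens else cand$sens + cand$spec
  best <- which(key == max(key))
  if (length(best) > 1L)
    best <- best[cand$spec[best] == max(cand$spec[best])]
  if (length(best) > 1L)
    best <- best[which.min(cand$cutoff[best])]
  chosen <- cand[best, ]
  roc@cutoff <- chosen$cutoff
  roc@sens <- chosen$sens
  roc@spec <- chosen$spec
  roc@sensCi <- clopperPearson(chosen$tp, roc@nPos, conf)
  roc@specCi <- clopperPearson(chosen$tn, roc@nNeg, conf)
  methods::validObject(roc)
  roc
}

#' Exact Clopper-Pearson binomial confidence interval
#'
#' Two-sided exact interval from beta quantiles:
#' lower = `qbeta(alpha/2, x, n - x + 1)` (0 when x = 0),
#' upper = `qbeta(1 - alpha/2, x + 1, n - x)` (1 when x = n).
#'
#' @param successes number of successes (0..n).
#' @param n number of trials (>= 1).
#' @param conf confidence level (default 0.95).
#' @return numeric length-2 vector `c(lower, upper)`.
#' @examples
#' clopperPearson(14, 14)   # lower ~0.768, prints as 0.77-1
#' clopperPearson(12, 14)   # ~(0.57, 0.98)
#' @export
clopperPearson <- function(successes, n, conf = 0.95) {
  if (length(successes) != 1L || length(n) != 1L || n < 1 ||
      successes < 0 || successes > n || successes != round(successes) ||
      n != round(n))
    stop("successes must be an integer in [0, n] with n >= 1", call. = FALSE)
  alpha <- 1 - conf
  lower <- if (successes == 0) 0 else stats::qbeta(alpha / 2, successes, n - successes + 1)
  upper <- if (successes == n) 1 else stats::qbeta(1 - alpha / 2, successes + 1, n - successes)
  c(lower, upper)
}
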