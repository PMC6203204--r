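# Shared fixture builders. Everything is generated in code under fixed seeds.

# A random tachogram of n intervals, uniform on [600, 1400] ms
randomSeries <- function(n = 50, seed = 1) {
  set.seed(seed)
  RRSeries(runif(n, 600, 1400))
}

# Constant base with isolated large outliers at the given positions
outlierSeries <- function(n = 50, base = 1000, positions = c(10, 30),
                          outlier = 2400) {
  x <- rep(base, n)
  x[positions] <- outlier
  RRSeries(x)
}

# Intervals lying exactly on a line in beat time: x_k = a + b * t_k
rampSeries <- function(n = 30, a = 800, b = 0.01) {
  t <- 0
  x <- numeric(n)
  tt <- numeric(n)
  for (k in seq_len(n)) {
    tt[k] <- t
    x[k] <- a + b * t
    t <- t + x[k]
  }
  RRSeries(x, beatTimes = tt)
}

# Brute-force oracles, kept deliberately naive and independent of R/ code
oracleRMSSD <- function(x) {
  acc <- 0
  for (j in seq_len(length(x) - 1)) acc <- acc + (x[j + 1] - x[j])^2
  sqrt(acc / (length(x) - 1))
}

oracleSlidingMedian <- function(x, w) {
  h <- w %/% 2
  n <- length(x)
  out <- numeric(n)
  for (k in seq_len(n)) {
    win <- sort(x[max(1, k - h):min(n, k + h)])
    m <- length(win)
    out[k] <- if (m %% 2 == 1) win[(m + 1) / 2] else (win[m / 2] + win[m / 2 + 1]) / 2
  }
  out
}

# Exact Wilcoxon two-sided p by explicit enumeration of all sign vectors
oracleWilcoxonExact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wobs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w <- as.numeric(signs %*% r)
  ple <- mean(w <= wobs + 1e-9)
  pge <- mean(w >= wobs - 1e-9)
  min(1, 2 * min(ple, pge))
}

# Mann-Whitney U statistic with ties counted one half
oracleAUC <- function(pos, neg) {
  u <- 0
  for (p in pos) for (q in neg) u <- u + (p > q) + 0.5 * (p == q)
  u / (length(pos) * length(neg))
}
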