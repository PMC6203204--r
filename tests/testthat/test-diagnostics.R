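test_that("exact Wilcoxon p matches hand-derived boundary cases", {
  # 14 uniformly positive differences: only the all-positive sign assignment
  # attains the maximal rank sum in each tail, so p = 2 / 2^14
  expect_equal(wilcoxonSignedRankExact(2:15, 1:14), 2 / 2^14)
  # perfectly antisymmetric differences sit at the null median: p = 1
  d <- c(1, -1, 2, -2, 3, -3)
  expect_equal(wilcoxonSignedRankExact(d, rep(0, 6)), 1)
  # hand-picked n = 6 case against explicit enumeration of all 64 sign vectors
  x <- c(5, 3, 8, 1, 9, 4)
  y <- c(2, 4, 1, 0, 3, 2)
  expect_equal(wilcoxonSignedRankExact(x, y), oracleWilcoxonExact(x - y))
})

test_that("exact Wilcoxon agrees with full enumeration on random draws up to n = 12", {
  set.seed(314)
  for (i in 1:200) {
    n <- sample(5:12, 1)
    d <- round(rnorm(n, sd = 4), 1)
    d[d == 0] <- 0.5
    if (i %% 3 == 0) d[1:2] <- c(2.5, -2.5)  # force ties in |d|
    expect_equal(wilcoxonSignedRankExact(d, rep(0, n)), oracleWilcoxonExact(d))
  }
})

test_that("exact Wilcoxon matches stats::wilcox.test when the latter is exact", {
  set.seed(99)
  x <- rnorm(12, 1)
  y <- rnorm(12)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value
  expect_equal(wilcoxonSignedRankExact(x, y), ref, tolerance = 1e-12)
})

test_that("Wilcoxon input contracts: zeros dropped, size limits enforced", {
  expect_error(wilcoxonSignedRankExact(1:4, 1:4 + 1), "at least 5")
  # zero differences are dropped before the count check
  x <- c(1, 2, 3, 4, 5, 6, 10, 10)
  y <- c(0, 1, 2, 3, 4, 5, 10, 10)
  expect_equal(wilcoxonSignedRankExact(x, y), 2 / 2^6)
  expect_error(wilcoxonSignedRankExact(1:30, 1:30 + rnorm(30)),
               "wilcoxonSignedRankNormal")
  p <- wilcoxonSignedRankNormal(1:30, 1:30 - rep(1, 30) + c(rep(0, 29), 3))
  expect_true(p > 0 && p < 1)
})

test_that("Bonferroni adjustment multiplies and caps", {
  expect_equal(bonferroniAdjust(0.001, 24), 0.024)
  expect_equal(bonferroniAdjust(0.5, 24), 1)
  expect_equal(bonferroniAdjust(0.3, 1), 0.3)
  expect_equal(bonferroniAdjust(c(0.001, 0.9), 24), c(0.024, 1))
  expect_error(bonferroniAdjust(1.2, 24), "0, 1")
  expect_error(bonferroniAdjust(0.1, 0), "m must be")
})

test_that("ROC AUC equals the Mann-Whitney U statistic, including ties", {
  # perfect separation
  roc <- rocCurve(c(10, 11, 12, 1, 2, 3), c("AF", "AF", "AF", "SR", "SR", "SR"))
  expect_equal(roc@auc, 1)
  # interleaved identical distributions: U = n1 n2 / 2 by construction
  sc <- c(1, 3, 5, 7, 2, 4, 6, 8)
  lb <- rep(c("AF", "SR"), each = 4)
  expect_equal(rocCurve(sc, lb)@auc, oracleAUC(sc[1:4], sc[5:8]))
  # random instances with and without ties
  set.seed(2718)
  for (i in 1:50) {
    pos <- round(rnorm(14, 1), if (i %% 2) 1 else 0)
    neg <- round(rnorm(14), if (i %% 2) 1 else 0)
    roc <- rocCurve(c(pos, neg), rep(c("AF", "SR"), each = 14))
    expect_equal(roc@auc, oracleAUC(pos, neg), tolerance = 1e-12)
  }
  expect_error(rocCurve(1:5, rep("AF", 5)), "both classes")
})

test_that("ROC AUC agrees with an independent implementation (pROC)", {
  skip_if_not_installed("pROC")
  set.seed(161)
  pos <- rlnorm(14, log(300), 0.5)
  neg <- rlnorm(14, log(60), 0.6)
  ours <- rocCurve(c(pos, neg), rep(c("AF", "SR"), each = 14))@auc
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = rep(c(1, 0), each = 14), predictor = c(pos, neg),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})

test_that("cutoff selection maximises sensitivity under the specificity floor", {
  # perfectly separating ROC: sens = spec = 1 at the separating cutoff
  roc <- selectCutoff(rocCurve(c(100, 110, 5, 8), c("AF", "AF", "SR", "SR")))
  expect_equal(roc@sens, 1)
  expect_equal(roc@spec, 1)
  expect_true(roc@cutoff > 8 && roc@cutoff <= 100)

  # constructed 3-point rule check: the floor excludes the most sensitive
  # point and sensitivity then beats specificity
  pts <- data.frame(cutoff = c(10, 20, 30),
                    sens = c(1.0, 0.9, 0.7), spec = c(0.6, 0.85, 1.0),
                    tp = c(10, 9, 7), fp = c(4, 2, 0),
                    tn = c(6, 8, 10), fn = c(0, 1, 3))
  roc3 <- methods::new("ROCResult", points = pts, auc = 0.9,
                       cutoff = NA_real_, sens = NA_real_, spec = NA_real_,
                       sensCi = c(NA_real_, NA_real_), specCi = c(NA_real_, NA_real_),
                       nPos = 10L, nNeg = 10L)
  chosen <- selectCutoff(roc3, specFloor = 0.80)
  expect_equal(chosen@cutoff, 20)

  # all points below the floor: fall back to max(sens + spec)
  pts2 <- transform(pts, spec = c(0.10, 0.40, 0.50), tn = c(1, 4, 5))
  roc4 <- methods::new("ROCResult", points = pts2, auc = 0.6,
                       cutoff = NA_real_, sens = NA_real_, spec = NA_real_,
                       sensCi = c(NA_real_, NA_real_), specCi = c(NA_real_, NA_real_),
                       nPos = 10L, nNeg = 10L)
  fb <- selectCutoff(roc4, specFloor = 0.80)
  expect_equal(fb@cutoff, pts2$cutoff[which.max(pts2$sens + pts2$spec)])

  # the chosen point satisfies its own rule on re-check
  set.seed(59)
  roc5 <- selectCutoff(rocCurve(c(rnorm(14, 2), rnorm(14)),
                                rep(c("AF", "SR"), each = 14)))
  better <- roc5@points$spec >= 0.80 & roc5@points$sens > roc5@sens
  expect_false(any(better))
})

test_that("Clopper-Pearson intervals are exact, monotone and match binom.test", {
  expect_equal(round(clopperPearson(14, 14), 2), c(0.77, 1.00))
  expect_equal(round(clopperPearson(13, 14)[1], 2), 0.66)
  expect_equal(round(clopperPearson(12, 14), 2), c(0.57, 0.98))
  expect_equal(clopperPearson(0, 10)[1], 0)
  expect_equal(clopperPearson(10, 10)[2], 1)
  # independent oracle: stats::binom.test conf.int is the exact interval
  for (x in c(0, 3, 7, 14)) {
    ref <- as.numeric(stats::binom.test(x, 14)$conf.int)
    expect_equal(clopperPearson(x, 14), ref, tolerance = 1e-12)
  }
  lowers <- vapply(0:14, function(x) clopperPearson(x, 14)[1], numeric(1))
  expect_true(all(diff(lowers) > 0 | (lowers[-1] == 0 & lowers[-15] == 0)))
  # interval shrinks with n at fixed proportion
  wide <- clopperPearson(7, 10)
  narrow <- clopperPearson(70, 100)
  expect_lt(diff(narrow), diff(wide))
  expect_error(clopperPearson(15, 14), "in \\[0, n\\]")
})

test_that("summarizeStudy produces the fixed 24-cell layout with invariant statistics", {
  res <- defaultStudySummary()
  expect_equal(nrow(res$table1), 24L)
  expect_equal(nrow(res$table2), 24L)
  expect_equal(unique(res$table1$pace), c("rest", "walk", "trot"))
  expect_equal(res$table1$p_bonferroni,
               pmin(1, 24 * res$table1$p_raw))
  expect_true(all(res$table2$auc >= 0 & res$table2$auc <= 1))
  expect_true(all(res$table2$sens_lo <= res$table2$sens + 1e-12))
  expect_true(all(res$table2$spec_hi >= res$table2$spec - 1e-12))

  # any cell where all AF values exceed all SR values has AUC 1 and a
  # perfect operating point
  sep <- res$table1$min_af > res$table1$max_sr
  expect_true(any(sep))
  expect_true(all(res$table2$auc[sep] == 1))
  expect_true(all(res$table2$sens[sep] == 1 & res$table2$spec[sep] == 1))
})

test_that("paired statistics are invariant under consistent subject reordering", {
  ds <- simulateStudy(synthConfig(nSubjects = 8, seed = 21))
  cfg <- filterConfig("none")
  af <- vapply(sprintf("H%02d", 1:8), function(s)
    hrvSummary(studySegment(ds, s, "walk", "AF", "ECG_man")@series, cfg)@rmssd,
    numeric(1))
  sr <- vapply(sprintf("H%02d", 1:8), function(s)
    hrvSummary(studySegment(ds, s, "walk", "SR", "ECG_man")@series, cfg)@rmssd,
    numeric(1))
  perm <- c(5, 2, 8, 1, 7, 3, 6, 4)
  expect_equal(wilcoxonSignedRankExact(af, sr),
               wilcoxonSignedRankExact(af[perm], sr[perm]))
  expect_equal(rocCurve(c(af, sr), rep(c("AF", "SR"), each = 8))@auc,
               rocCurve(c(af[perm], sr[perm]), rep(c("AF", "SR"), each = 8))@auc)
})
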