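#' @include detrend.R
NULL

#' Build a SynthConfig
#'
#' All defaults were calibrated once so that, under the gold-standard
#' detection method without filtering, the per-pace median RMSSD of the
#' synthetic cohort falls inside the observed equine AF and sinus-rhythm
#' ranges (rest AF 248-1409 / SR 26-378 ms; walk 84-495 / 11-185; trot
#' 53-144 / 5-18). Jitter and AF coefficients of variation are per-pace:
#' vagal tone, and with it sinus variability, collapses with exercise, and
#' the relative irregularity of the AF ventricular response shrinks as rate
#' rises.
#'
#' @param nSubjects number of subjects (default 14).
#' @param seed master seed; every segment derives a named, reproducible
#'   sub-stream from it.
#' @param srMeanRR,afMeanRR named per-pace mean RR in ms.
#' @param srJitterSd named per-pace beat-to-beat Gaussian jitter sd (ms).
#' @param srOscillation amplitude (ms) and period (s) of the slow SR
#'   oscillation.
#' @param avbProb per-beat probability of a second-degree AV block (rest and
#'   walk; blocked beats roughly double the RR interval).
#' @param apdProb per-beat probability of an atrial premature short-long
#'   couplet (rest SR only).
#' @param afCv named per-pace coefficient of variation of AF intervals.
#' @param artifactRates list method -> pace -> c(miss, split) per-beat
#'   detection-error probabilities; the gold standard has none and rates are
#'   worst at trot.
#' @param durationS segment duration in seconds.
#' @return a [SynthConfig-class].
#' @export
synthConfig <- function(nSubjects = 14L, seed = 1L,
                        srMeanRR = c(rest = 1600, walk = 950, trot = 620),
                        afMeanRR = c(rest = 1350, walk = 850, trot = 520),
                        srJitterSd = c(rest = 40, walk = 28, trot = 6.5),
                        srOscillation = c(amplitude = 30, period = 40),
                        avbProb = 0.006, apdProb = 0.004,
                        afCv = c(rest = 0.35, walk = 0.19, trot = 0.12),
                        artifactRates = list(
                          ECG_man = list(rest = c(miss = 0, split = 0),
                                         walk = c(miss = 0, split = 0),
                                         trot = c(miss = 0, split = 0)),
                          ECG_aut = list(rest = c(miss = 0.002, split = 0.002),
                                         walk = c(miss = 0.006, split = 0.004),
                                         trot = c(miss = 0.02, split = 0.008)),
                          HRM = list(rest = c(miss = 0.005, split = 0.003),
                                     walk = c(miss = 0.010, split = 0.005),
                                     trot = c(miss = 0.030, split = 0.010))),
                        durationS = 120) {
  methods::new("SynthConfig", nSubjects = as.integer(nSubjects),
               seed = as.integer(seed),
               srMeanRR = srMeanRR, afMeanRR = afMeanRR,
               srJitterSd = srJitterSd, srOscillation = srOscillation,
               avbProb = avbProb, apdProb = apdProb, afCv = afCv,
               artifactRates = artifactRates, durationS = durationS)
}

#' Derive a reproducible sub-stream seed from a master seed and a key
#'
#' Deterministic polynomial string hash combined with the master seed,
#' reduced modulo 2^31 - 1, so any single segment of a simulated study can
#' be regenerated in isolation.
#'
#' @param masterSeed integer master seed.
#' @param key character key, e.g. `"H03_trot_AF"`.
#' @return an integer seed in [0, 2^31 - 2].
#' @export
streamSeed <- function(masterSeed, key) {
  h <- 0
  for (ch in utf8ToInt(key))
    h <- (h * 31 + ch) %% 2147483647
  as.integer((h + as.numeric(masterSeed) %% 2147483647) %% 2147483647)
}

#' Simulate one sinus-rhythm segment
#'
#' Intervals are the pace mean plus a slow sinusoidal modulation plus
#' Gaussian jitter. At rest and walk, a beat is replaced with probability
#' `avbProb` by a blocked beat of roughly twice the local base interval
#' (second-degree AV block); at rest, with probability `apdProb`, a
#' premature short-long couplet is inserted. The series is truncated at the
#' configured duration (intervals whose onset falls before the end are
#' kept).
#'
#' @param pace `"rest"`, `"walk"` or `"trot"`.
#' @param config a [SynthConfig-class].
#' @param streamSeed optional integer seed for this segment's RNG stream.
#' @return an [RRSeries-class].
#' @export
simulateSRSegment <- function(pace, config = synthConfig(), streamSeed = NULL) {
  pace <- match.arg(pace, .PACES)
  if (!is.null(streamSeed)) set.seed(streamSeed)
  m <- config@srMeanRR[[pace]]
  jit <- config@srJitterSd[[pace]]
  A <- config@srOscillation[[1]]
  periodMs <- config@srOscillation[[2]] * 1000
  durMs <- config@durationS * 1000
  avb <- if (pace %in% c("rest", "walk")) config@avbProb else 0
  apd <- if (pace == "rest") config@apdProb else 0
  intervals <- numeric(0)
  t <- 0
  while (t < durMs) {
    base <- m + A * sin(2 * pi * t / periodMs)
    u <- stats::runif(1)
    if (u < avb) {
      x <- 2 * base + stats::rnorm(1, 0, jit)
      intervals <- c(intervals, max(x, 0.2 * m))
      t <- t + x
    } else if (u < avb + apd) {
      short <- 0.65 * base + stats::rnorm(1, 0, jit)
      long <- 1.35 * base + stats::rnorm(1, 0, jit)
      intervals <- c(intervals, max(short, 0.2 * m))
      t <- t + short
      if (t < durMs) {
        intervals <- c(intervals, max(long, 0.2 * m))
        t <- t + long
      }
    } else {
      x <- base + stats::rnorm(1, 0, jit)
      intervals <- c(intervals, max(x, 0.2 * m))
      t <- t + x
    }
  }
  RRSeries(intervals, meta = list(pace = pace, rhythm = "SR"))
}

#' Simulate one atrial-fibrillation segment
#'
#' AF intervals are drawn i.i.d. from a lognormal distribution with the
#' pace's AF mean RR and coefficient of variation, reflecting the
#' irregularly irregular ventricular response; for i.i.d. draws the expected
#' RMSSD is \eqn{\sqrt{2}\,\sigma} of the interval distribution.
#'
#' @inheritParams simulateSRSegment
#' @return an [RRSeries-class].
#' @export
simulateAFSegment <- function(pace, config = synthConfig(), streamSeed = NULL) {
  pace <- match.arg(pace, .PACES)
  if (!is.null(streamSeed)) set.seed(streamSeed)
  m <- config@afMeanRR[[pace]]
  cv <- config@afCv[[pace]]
  durMs <- config@durationS * 1000
  if (cv == 0) {
    n <- ceiling(durMs / m)
    return(RRSeries(rep(m, n), meta = list(pace = pace, rhythm = "AF")))
  }
  sdlog <- sqrt(log(1 + cv^2))
  meanlog <- log(m) - sdlog^2 / 2
  intervals <- numeric(0)
  repeat {
    intervals <- c(intervals, stats::rlnorm(64, meanlog, sdlog))
    if (sum(intervals) >= durMs) break
  }
  onset <- cumsum(c(0, intervals))[seq_along(intervals)]
  RRSeries(intervals[onset < durMs], meta = list(pace = pace, rhythm = "AF"))
}

#' Corrupt a series with beat-detection errors
#'
#' Emulates QRS-detection error of a given detection method: with the
#' method's per-pace per-beat probabilities, two adjacent intervals are
#' merged (missed beat) or one interval is split into two unequal parts with
#' a uniform(0.3, 0.7) fraction (spurious detection). The gold-standard
#' `ECG_man` preset applies no corruption. Total duration is conserved
#' exactly.
#'
#' @param series an [RRSeries-class].
#' @param method `"ECG_man"`, `"ECG_aut"` or `"HRM"`.
#' @param pace `"rest"`, `"walk"` or `"trot"`.
#' @param config a [SynthConfig-class].
#' @param streamSeed optional integer seed for this corruption's RNG stream.
#' @return an [RRSeries-class] with the same total duration.
#' @export
corruptDetection <- function(series, method, pace, config = synthConfig(),
                             streamSeed = NULL) {
  stopifnot(methods::is(series, "RRSeries"))
  method <- match.arg(method, .METHODS)
  pace <- match.arg(pace, .PACES)
  rates <- config@artifactRates[[method]][[pace]]
  miss <- unname(rates[["miss"]])
  split <- unname(rates[["split"]])
  if (miss == 0 && split == 0) {
    out <- series
    out@meta$method <- method
    return(out)
  }
  if (!is.null(streamSeed)) set.seed(streamSeed)
  x <- series@intervals
  n <- length(x)
  ## missed beats: merge with the following interval, no overlapping merges
  merged <- numeric(0)
  i <- 1L
  while (i <= n) {
    if (i < n && stats::runif(1) < miss) {
      merged <- c(merged, x[i] + x[i + 1L])
      i <- i + 2L
    } else {
      merged <- c(merged, x[i])
      i <- i + 1L
    }
  }
  ## spurious detections: split one interval into two unequal parts
  out <- numeric(0)
  for (y in merged) {
    if (stats::runif(1) < split) {
      u <- stats::runif(1, 0.3, 0.7)
      out <- c(out, u * y, (1 - u) * y)
    } else {
      out <- c(out, y)
    }
  }
  meta <- series@meta
  meta$method <- method
  RRSeries(out,
           beatTimes = series@beatTimes[1] + cumsum(c(0, out))[seq_along(out)],
           meta = meta)
}

#' Simulate a full paired AF/SR study
#'
#' For each subject and pace, one AF and one SR truth series are generated
#' and rendered under all three detection-method presets, yielding
#' `nSubjects x 3 paces x 2 rhythms x 3 methods` segments. Each truth series
#' and each corruption uses a named RNG sub-stream derived from the master
#' seed, so the dataset is bit-reproducible and any single segment can be
#' regenerated in isolation.
#'
#' @param config a [SynthConfig-class].
#' @return a [StudyDataset-class].
#' @examples
#' ds <- simulateStudy(synthConfig(nSubjects = 2, seed = 7))
#' ds
#' @export
simulateStudy <- function(config = synthConfig()) {
  segments <- list()
  for (i in seq_len(config@nSubjects)) {
    id <- sprintf("H%02d", i)
    for (pace in .PACES) {
      for (rhythm in .RHYTHMS) {
        key <- paste(id, pace, rhythm, sep = "_")
        truth <- if (rhythm == "AF")
          simulateAFSegment(pace, config, streamSeed(config@seed, key))
        else
          simulateSRSegment(pace, config, streamSeed(config@seed, key))
        truth@meta$subject <- id
        for (method in .METHODS) {
          corrupted <- corruptDetection(
            truth, method, pace, config,
            streamSeed(config@seed, paste(key, method, sep = "_")))
          segments[[paste(key, method, sep = "_")]] <-
            RecordingSegment(corrupted, id, pace, rhythm, method,
                             window = c(0, config@durationS))
        }
      }
    }
  }
  methods::new("StudyDataset", segments = segments, config = config)
}

#' Tabulate the segments of a StudyDataset
#'
#' @param dataset a [StudyDataset-class].
#' @return data.frame with columns subject, pace, rhythm, method, nIntervals.
#' @export
segmentTable <- function(dataset) {
  stopifnot(methods::is(dataset, "StudyDataset"))
  do.call(rbind, lapply(unname(dataset@segments), function(s) {
    data.frame(subject = s@subjectId, pace = s@pace, rhythm = s@rhythm,
               method = s@method, nIntervals = length(s@series@intervals),
               stringsAsFactors = FALSE)
  }))
}

#' Retrieve one segment of a StudyDataset
#'
#' @param dataset a [StudyDataset-class].
#' @param subject,pace,rhythm,method segment coordinates.
#' @return a [RecordingSegment-class].
#' @export
studySegment <- function(dataset, subject, pace, rhythm, method) {
  key <- paste(subject, pace, rhythm, method, sep = "_")
  seg <- dataset@segments[[key]]
  if (is.null(seg)) {
    hit <- vapply(dataset@segments, function(s)
      s@subjectId == subject && s@pace == pace && s@rhythm == rhythm &&
        s@method == method, logical(1))
    if (!any(hit))
      stop(sprintf("no segment for %s/%s/%s/%s", subject, pace, rhythm, method),
           call. = FALSE)
    seg <- dataset@segments[[which(hit)[1]]]
  }
  seg
}
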