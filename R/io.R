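#' @include study.R
NULL

.inferFormat <- function(path, format = c("auto", "rr_text", "rr_csv")) {
  format <- match.arg(format)
  if (format != "auto") return(format)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "rr_csv" else "rr_text"
}

#' Read an RR-interval file
#'
#' Two plain-text dialects, both in milliseconds. `rr_text`: one positive
#' interval per line, `#`-prefixed comment lines and blank lines skipped.
#' `rr_csv`: header `time_ms,rr_ms,flag`; onset times are taken from
#' `time_ms` when present and reconstructed by cumulative sum otherwise;
#' missing flags default to `"original"`. The format is inferred from the
#' file extension (`.csv` is `rr_csv`) unless given explicitly — content is
#' never silently guessed.
#'
#' @param path file path.
#' @param format `"auto"`, `"rr_text"` or `"rr_csv"`.
#' @param meta optional metadata list attached to the series.
#' @return an [RRSeries-class].
#' @export
readRRFile <- function(path, format = "auto", meta = list()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  format <- .inferFormat(path, format)
  if (format == "rr_text") {
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", lines)
    idx <- which(keep)
    if (!length(idx)) stop(sprintf("%s: no RR intervals found", path), call. = FALSE)
    vals <- suppressWarnings(as.numeric(trimws(lines[idx])))
    bad <- which(!is.finite(vals) | vals <= 0)
    if (length(bad))
      stop(sprintf("%s: line %d: invalid RR interval '%s' (positive number required)",
                   path, idx[bad[1]], trimws(lines[idx[bad[1]]])), call. = FALSE)
    return(RRSeries(vals, meta = meta))
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_ms", "rr_ms", "flag")
  if (!all(need %in% names(df)))
    stop(sprintf("%s: rr_csv requires header columns %s", path,
                 paste(need, collapse = ",")), call. = FALSE)
  if (!nrow(df)) stop(sprintf("%s: no RR intervals found", path), call. = FALSE)
  bad <- which(!is.finite(df$rr_ms) | df$rr_ms <= 0)
  if (length(bad))
    stop(sprintf("%s: line %d: invalid RR interval '%s' (positive number required)",
                 path, bad[1] + 1L, df$rr_ms[bad[1]]), call. = FALSE)
  flags <- ifelse(is.na(df$flag) | df$flag == "", "original", df$flag)
  bt <- if (all(is.finite(df$time_ms))) df$time_ms else NULL
  RRSeries(df$rr_ms, beatTimes = bt, flags = flags, meta = meta)
}

#' Write an RR-interval file
#'
#' Inverse of [readRRFile()] within the declared precision: intervals are
#' written at 3 decimals (0.001 ms). Flags are preserved only by the
#' `rr_csv` format.
#'
#' @param series an [RRSeries-class].
#' @param path output path.
#' @param format `"rr_text"` or `"rr_csv"`.
#' @return invisibly, `path`.
#' @export
writeRRFile <- function(series, path, format = c("rr_text", "rr_csv")) {
  stopifnot(methods::is(series, "RRSeries"))
  format <- match.arg(format)
  if (format == "rr_text") {
    writeLines(sprintf("%.3f", series@intervals), path)
  } else {
    ## times are rewritten as the cumulative sum of the rounded intervals so
    ## the file is self-consistent at the declared 0.001 ms precision
    r <- round(series@intervals, 3)
    t0 <- round(series@beatTimes[1], 3)
    df <- data.frame(time_ms = sprintf("%.3f", t0 + cumsum(c(0, r))[seq_along(r)]),
                     rr_ms = sprintf("%.3f", r),
                     flag = series@flags)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read and write run configurations
#'
#' A run configuration bundles the seed, synthetic-generator settings,
#' analysis options and output directory, serialised as JSON with a stable
#' write-read round trip.
#'
#' @param config named list with any of: `seed`, `n_subjects`, `spec_floor`,
#'   `m`, `median_window`, `out_dir`, `verbose`, plus a `synth` sub-list of
#'   [synthConfig()] overrides.
#' @param path JSON file path.
#' @return `readRunConfig()` returns the configuration list;
#'   `writeRunConfig()` returns `path` invisibly.
#' @export
writeRunConfig <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeRunConfig
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  jsonlite::fromJSON(path, simplifyVector = TRUE)
}

.resolveSynthConfig <- function(runCfg) {
  args <- list()
  if (!is.null(runCfg$seed)) args$seed <- runCfg$seed
  if (!is.null(runCfg$n_subjects)) args$nSubjects <- runCfg$n_subjects
  synth <- runCfg$synth
  if (!is.null(synth)) {
    for (nm in intersect(names(synth),
                         c("srMeanRR", "afMeanRR", "srJitterSd", "afCv"))) {
      v <- unlist(synth[[nm]])
      args[[nm]] <- v
    }
    for (nm in intersect(names(synth),
                         c("avbProb", "apdProb", "durationS", "srOscillation")))
      args[[nm]] <- unlist(synth[[nm]])
  }
  do.call(synthConfig, args)
}
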