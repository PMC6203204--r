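#' @include diagnostics.R
NULL

#' Default method x filter grid of the study design
#'
#' Eight analysis cells per pace: the manually corrected ECG gold standard
#' without filtering; the automatically analysed ECG at all six correction
#' levels with smoothness-priors detrending (lambda 500), matching common
#' HRV-software defaults; and the heart rate monitor, whose proprietary
#' correction is emulated by the `low` (0.35 s) preset. Across three paces
#' this yields the study's 24 comparisons.
#'
#' @return data.frame with columns method, level, detrend, lambda.
#' @export
defaultFilterGrid <- function() {
  rbind(
    data.frame(method = "ECG_man", level = "none", detrend = FALSE, lambda = 500),
    data.frame(method = "ECG_aut", level = .LEVELS, detrend = TRUE, lambda = 500),
    data.frame(method = "HRM", level = "low", detrend = FALSE, lambda = 500))
}

.cellConfig <- function(row, medianWindow = 11L) {
  filterConfig(row$level, medianWindow = medianWindow,
               detrend = row$detrend, lambda = row$lambda)
}

#' Run the full diagnostic evaluation over a study dataset
#'
#' For every pace x method x filter-level cell of the grid: computes the
#' per-subject RMSSD under the cell's filter configuration, the AF and SR
#' medians and min-max ranges, the exact two-sided Wilcoxon signed-rank
#' p-value with its Bonferroni adjustment, and the ROC analysis (AUC,
#' operating point chosen to maximise sensitivity at >= `specFloor`
#' specificity, exact binomial CIs). Row order is fixed: rest, walk, trot;
#' within a pace, grid order.
#'
#' @param dataset a paired [StudyDataset-class].
#' @param grid analysis grid as from [defaultFilterGrid()].
#' @param specFloor specificity floor for cutoff selection (default 0.80).
#' @param m number of comparisons for the Bonferroni adjustment; defaults to
#'   the number of cells (24 for the default grid).
#' @param medianWindow median-filter window for all cells.
#' @return list with `table1` (paired-comparison data.frame), `table2`
#'   (ROC/cutoff data.frame) and `roc` (named list of [ROCResult-class]).
#' @examples
#' ds <- simulateStudy(synthConfig(nSubjects = 6, seed = 11))
#' res <- summarizeStudy(ds)
#' head(res$table1)
#' @export
summarizeStudy <- function(dataset, grid = defaultFilterGrid(),
                           specFloor = 0.80, m = NULL, medianWindow = 11L) {
  stopifnot(methods::is(dataset, "StudyDataset"))
  subjects <- sort(unique(segmentTable(dataset)$subject))
  if (is.null(m)) m <- 3L * nrow(grid)
  t1 <- list(); t2 <- list(); rocs <- list()
  for (pace in .PACES) {
    for (g in seq_len(nrow(grid))) {
      row <- grid[g, ]
      cfg <- .cellConfig(row, medianWindow)
      vals <- lapply(.RHYTHMS, function(rhythm) {
        vapply(subjects, function(s) {
          seg <- studySegment(dataset, s, pace, rhythm, row$method)
          hrv <- hrvSummary(seg@series, cfg)
          hrv@rmssd
        }, numeric(1))
      })
      names(vals) <- .RHYTHMS
      af <- vals$AF; sr <- vals$SR
      p <- wilcoxonSignedRankExact(af, sr)
      cell <- sprintf("%s.%s.%s", pace, row$method, row$level)
      t1[[cell]] <- data.frame(
        pace = pace, method = row$method, level = row$level,
        median_af = stats::median(af), min_af = min(af), max_af = max(af),
        median_sr = stats::median(sr), min_sr = min(sr), max_sr = max(sr),
        p_raw = p, p_bonferroni = bonferroniAdjust(p, m),
        stringsAsFactors = FALSE)
      roc <- selectCutoff(
        rocCurve(c(af, sr), rep(.RHYTHMS, times = c(length(af), length(sr)))),
        specFloor = specFloor)
      rocs[[cell]] <- roc
      t2[[cell]] <- data.frame(
        pace = pace, method = row$method, level = row$level,
        auc = roc@auc, cutoff = roc@cutoff,
        sens = roc@sens, sens_lo = roc@sensCi[1], sens_hi = roc@sensCi[2],
        spec = roc@spec, spec_lo = roc@specCi[1], spec_hi = roc@specCi[2],
        stringsAsFactors = FALSE)
    }
  }
  list(table1 = do.call(rbind, c(t1, list(make.row.names = FALSE))),
       table2 = do.call(rbind, c(t2, list(make.row.names = FALSE))),
       roc = rocs)
}

#' Write study results as TSV tables
#'
#' Writes `table1.tsv` (paired comparisons) and `table2.tsv` (ROC/cutoffs)
#' mirroring the two summary tables, and optionally one `roc_<cell>.csv` per
#' analysis cell with the swept ROC points. Output is deterministic for a
#' given result object.
#'
#' @param results list from [summarizeStudy()].
#' @param dir output directory (created if needed).
#' @param rocDumps logical, write per-cell ROC point CSVs.
#' @return invisibly, the paths written.
#' @export
writeStudyResults <- function(results, dir, rocDumps = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in c("table1", "table2")) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    utils::write.table(results[[nm]], p, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    paths <- c(paths, p)
  }
  if (rocDumps) {
    for (cell in names(results$roc)) {
      p <- file.path(dir, sprintf("roc_%s.csv", gsub("[^A-Za-z0-9_.]", "_", cell)))
      utils::write.csv(results$roc[[cell]]@points, p, row.names = FALSE)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
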