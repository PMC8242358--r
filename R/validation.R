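## Base-level precision/recall/FPR of scored peak calls against histone
## truth sets, swept over score cutoffs, and threshold selection at the
## precision-recall intercept.
##
## For peaks retained at a cutoff (score >= cutoff, merged):
##   TP        = bases of retained peaks overlapping RP
##   FP        = bases of retained peaks overlapping RN
##   precision = TP / (TP + FP)     (undefined, not 0, when TP + FP = 0)
##   recall    = TP / RP bases
##   FPR       = FP / RN bases

.check_scored <- function(peaks) {
  if (nrow(peaks) && anyNA(peaks$score))
    stop("every peak must carry a score (found ", sum(is.na(peaks$score)),
         " unscored)")
}

.check_truth <- function(truth) {
  if (!inherits(truth, "TruthSets")) stop("truth must be a TruthSets object")
  if (truth$rp_bases <= 0 || truth$rn_bases <= 0)
    stop("unusable truth set: RP and RN must both be non-empty")
}

#' Validation metrics of a peak set at one score cutoff
#'
#' Peaks with `score >= cutoff` are retained and merged; true-positive bases
#' are those overlapping the real-positive set and false-positive bases
#' those overlapping the real-negative set.
#'
#' @param peaks A scored [peak_set()] (every peak must have a score).
#' @param truth A [build_truth_sets()] result with non-empty RP and RN.
#' @param cutoff Score threshold; peaks scoring at least this are retained.
#' @return A one-row data.frame: cutoff, n_peaks, tp_bases, fp_bases,
#'   precision (NA when no retained base touches RP or RN), recall, fpr.
#' @export
validation_point <- function(peaks, truth, cutoff) {
  .check_scored(peaks)
  .check_truth(truth)
  kept <- peaks[peaks$score >= cutoff, , drop = FALSE]
  tp <- intersect_bases(kept, truth$rp)
  fp <- intersect_bases(kept, truth$rn)
  .metrics_row(cutoff, nrow(kept), tp, fp, truth)
}

.metrics_row <- function(cutoff, n_peaks, tp, fp, truth) {
  data.frame(cutoff = cutoff, n_peaks = n_peaks,
             tp_bases = tp, fp_bases = fp,
             precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
             recall = tp / truth$rp_bases,
             fpr = fp / truth$rn_bases)
}

#' Sweep validation metrics over an increasing grid of score cutoffs
#'
#' @inheritParams validation_point
#' @param cutoffs Explicit numeric vector of cutoffs, or `NULL` to use the
#'   default grid: all distinct observed scores when there are at most
#'   `max_grid` of them, otherwise `max_grid` evenly spaced score quantiles.
#' @param max_grid Grid size cap for the default grid (default 200 distinct
#'   scores, thinned to 50 quantiles above the cap).
#' @return A `ValidationCurve` data.frame, one [validation_point()] row per
#'   cutoff in increasing cutoff order, with attributes `label` and `truth`.
#' @export
sweep_cutoffs <- function(peaks, truth, cutoffs = NULL, max_grid = 200) {
  .check_scored(peaks)
  .check_truth(truth)
  if (is.null(cutoffs)) {
    s <- sort(unique(peaks$score))
    cutoffs <- if (length(s) <= max_grid) s else
      unique(quantile(peaks$score, probs = seq(0, 1, length.out = 50),
                      names = FALSE, type = 1))
  }
  cutoffs <- sort(unique(as.numeric(cutoffs)))
  if (length(cutoffs) < 2) stop("need at least 2 cutoffs")
  ## per-chromosome ranges built once and filtered per cutoff
  chroms <- sort(unique(peaks$chrom))
  rp_irl <- as_irl(truth$rp); rn_irl <- as_irl(truth$rn)
  by_chrom <- lapply(setNames(nm = chroms), function(ch) {
    i <- peaks$chrom == ch
    list(ir = IRanges::IRanges(peaks$start[i] + 1, peaks$end[i]),
         score = peaks$score[i],
         rp = rp_irl[[ch]], rn = rn_irl[[ch]])
  })
  curve <- do.call(rbind, lapply(cutoffs, function(ct) {
    tp <- fp <- 0
    for (x in by_chrom) {
      kept <- IRanges::reduce(x$ir[x$score >= ct])
      if (!is.null(x$rp))
        tp <- tp + sum(IRanges::width(IRanges::intersect(kept, x$rp)))
      if (!is.null(x$rn))
        fp <- fp + sum(IRanges::width(IRanges::intersect(kept, x$rn)))
    }
    .metrics_row(ct, sum(peaks$score >= ct), tp, fp, truth)
  }))
  structure(curve, class = c("ValidationCurve", "data.frame"),
            label = peak_label(peaks))
}

#' Select the peak-filtering cutoff at the precision-recall intercept
#'
#' Returns the smallest evaluated cutoff at which precision is at least
#' recall (the point where the rising precision curve crosses the falling
#' recall curve on the evaluated grid; no interpolation).  Degenerate
#' curves are flagged via the `"note"` attribute: `"no-crossing-at-start"`
#' when precision >= recall already at the first cutoff, and
#' `"no-crossing"` when the curves never cross (the last cutoff is
#' returned).
#'
#' @param curve A [sweep_cutoffs()] result.
#' @return The selected cutoff (with attribute `note` when degenerate).
#' @export
select_cutoff <- function(curve) {
  if (nrow(curve) < 2) stop("curve must have at least 2 points")
  if (all(is.na(curve$precision)))
    stop("precision is undefined at every cutoff")
  cross <- which(!is.na(curve$precision) & curve$precision >= curve$recall)
  if (!length(cross)) {
    ct <- curve$cutoff[nrow(curve)]
    attr(ct, "note") <- "no-crossing"
  } else {
    ct <- curve$cutoff[cross[1]]
    if (cross[1] == 1L) attr(ct, "note") <- "no-crossing-at-start"
  }
  ct
}

#' Filter a peak set at a score cutoff
#'
#' Retains peaks with `score >= cutoff`; original records are preserved
#' unmerged.
#'
#' @inheritParams validation_point
#' @return A [peak_set()] with the retained peaks.
#' @export
filter_peaks <- function(peaks, cutoff) {
  .check_scored(peaks)
  kept <- peaks[!is.na(peaks$score) & peaks$score >= cutoff, , drop = FALSE]
  rownames(kept) <- NULL
  structure(kept, class = c("PeakSet", "data.frame"),
            label = peak_label(peaks))
}

#' Precision of a peak subset against the truth sets
#'
#' Precision of the given peaks as they stand (no additional score cutoff):
#' TP / (TP + FP) over the subset's merged bases.  Used e.g. to assess peaks
#' unique to a single library.
#'
#' @param peaks A [peak_set()] (scores not required).
#' @param truth A [build_truth_sets()] result.
#' @return Precision in \[0, 1\], or `NA` (with a warning) when the subset
#'   touches neither RP nor RN.
#' @export
subset_precision <- function(peaks, truth) {
  .check_truth(truth)
  validate_intervals(peaks)
  if (nrow(peaks) == 0L) stop("peak subset is empty")
  tp <- intersect_bases(peaks, truth$rp)
  fp <- intersect_bases(peaks, truth$rn)
  if (tp + fp == 0) {
    warning("subset overlaps neither RP nor RN: precision undefined")
    return(NA_real_)
  }
  tp / (tp + fp)
}
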