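## Histone-mark truth sets for peak validation.
##
## Active regulatory regions carry H3K4me1 (enhancers) or H3K4me3
## (promoters) together with H3K27ac (activity); Polycomb-repressed
## chromatin carries H3K27me3.  ATAC-seq peaks are therefore validated
## against a real-positive set (K4 peaks confirmed by K27ac) and a
## real-negative set (K27me3 peaks).

#' Build real-positive and real-negative truth sets from histone marks
#'
#' The real-positive set (RP) is the union of those H3K4me1 and H3K4me3
#' peaks that each overlap an H3K27ac peak by at least `min_overlap` bases;
#' by default the entire qualifying peak is retained (peak-level selection),
#' not just the overlapping portion.  The real-negative set (RN) is the
#' H3K27me3 peaks.  Both sets are stored merged and sorted.
#'
#' RP and RN are not forced to be disjoint: bases falling in both count
#' toward both true and false positives exactly as the validation formulas
#' dictate.  Their shared base count is reported in `rp_rn_shared_bases`
#' so truth-set coherence can be judged.
#'
#' @param h3k4me1,h3k4me3,h3k27ac,h3k27me3 Interval data.frames
#'   ([peak_set()]s) for the four marks.
#' @param min_overlap Minimum shared bases for a K4 peak to qualify
#'   (default 1 bp).
#' @param clip_to_k27ac If `TRUE`, RP is clipped to the base-level
#'   intersection of the K4 peaks with H3K27ac rather than retaining whole
#'   qualifying peaks.
#' @return A `TruthSets` list: `rp`, `rn` (merged interval data.frames),
#'   `rp_bases`, `rn_bases`, `rp_rn_shared_bases`, `provenance`.
#' @examples
#' k4me3 <- peak_set("chr1", 0, 500)
#' k27ac <- peak_set("chr1", 400, 600)
#' k27me3 <- peak_set("chr1", 1000, 2000)
#' ts <- build_truth_sets(peak_set(character(), numeric(), numeric()),
#'                        k4me3, k27ac, k27me3)
#' ts$rp   # chr1:[0,500)
#' @export
build_truth_sets <- function(h3k4me1, h3k4me3, h3k27ac, h3k27me3,
                             min_overlap = 1, clip_to_k27ac = FALSE) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  for (s in list(h3k4me1, h3k4me3, h3k27ac, h3k27me3)) validate_intervals(s)
  if (nrow(h3k4me1) + nrow(h3k4me3) + nrow(h3k27ac) + nrow(h3k27me3) == 0L)
    stop("all four histone peak sets are empty")

  k4 <- rbind(h3k4me1[, c("chrom", "start", "end")],
              h3k4me3[, c("chrom", "start", "end")])
  if (nrow(h3k27ac) == 0L && nrow(k4) > 0L) {
    warning("H3K27ac set is empty: real-positive set is empty")
    rp <- k4[0, , drop = FALSE]
  } else if (nrow(k4) == 0L) {
    rp <- k4
  } else {
    hit <- overlap_flags(k4, h3k27ac, min_overlap)
    rp <- k4[hit, , drop = FALSE]
    if (clip_to_k27ac && nrow(rp)) {
      ir <- as_irl(rp); ac <- as_irl(h3k27ac)
      rp <- irl_to_df(lapply(setNames(nm = intersect(names(ir), names(ac))),
                             function(ch)
                               IRanges::intersect(ir[[ch]], ac[[ch]])))
    }
  }
  rp <- sort_and_merge(rp)
  rn <- sort_and_merge(h3k27me3[, c("chrom", "start", "end")])

  structure(list(rp = rp, rn = rn,
                 rp_bases = total_bases(rp), rn_bases = total_bases(rn),
                 rp_rn_shared_bases = intersect_bases(rp, rn),
                 provenance = c(h3k4me1 = peak_label(h3k4me1),
                                h3k4me3 = peak_label(h3k4me3),
                                h3k27ac = peak_label(h3k27ac),
                                h3k27me3 = peak_label(h3k27me3))),
            class = "TruthSets")
}

#' @export
print.TruthSets <- function(x, ...) {
  cat(sprintf("TruthSets: RP %d regions (%s bp), RN %d regions (%s bp), %s bp shared\n",
              nrow(x$rp), format(x$rp_bases, big.mark = ","),
              nrow(x$rn), format(x$rn_bases, big.mark = ","),
              format(x$rp_rn_shared_bases, big.mark = ",")))
  invisible(x)
}
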