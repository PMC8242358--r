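## Core interval model and base-level set arithmetic.
##
## Intervals live in plain data.frames (columns chrom, start, end, and for
## peak sets name, score, strand) using the BED convention: 0-based start,
## exclusive end.  Set arithmetic is delegated to IRanges/GenomicRanges,
## converting to 1-based closed coordinates at the boundary.

#' Construct a genome (chromosome sizes)
#'
#' @param chrom Character vector of chromosome names (unique, non-empty).
#' @param length Integer vector of chromosome lengths in bp (all > 0).
#' @return A `Genome` data.frame with columns `chrom` and `length`.
#' @examples
#' genome(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) != length(length))
    stop("chrom and length must have equal lengths")
  if (anyDuplicated(chrom) || any(!nzchar(chrom)) || anyNA(chrom))
    stop("chromosome names must be unique and non-empty")
  if (anyNA(length) || any(length <= 0) || any(length != floor(length)))
    stop("chromosome lengths must be positive integers")
  structure(data.frame(chrom = chrom, length = length,
                       stringsAsFactors = FALSE),
            class = c("Genome", "data.frame"))
}

#' Read chromosome sizes from a 2-column TSV
#'
#' @param path Path to a tab-separated file with columns name, length.
#' @return A [genome()] object.
#' @export
read_chrom_sizes <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = FALSE,
                   colClasses = c("character", "numeric"),
                   col.names = c("chrom", "length"))
  genome(df$chrom, df$length)
}

#' Construct a scored peak set
#'
#' A `PeakSet` is a data.frame of 0-based half-open genomic intervals with
#' optional name, score and strand, carrying a library label.  Intervals
#' within a set may overlap: merging is always explicit
#' (see [sort_and_merge()]).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Numeric vectors, 0-based half-open (`0 <= start < end`).
#' @param name Optional record names.
#' @param score Optional numeric peak quality scores (as emitted by MACS2 or
#'   HMMRATAC; unitless).
#' @param strand Optional strand, one of `"+"`, `"-"`, `"."` (unstranded).
#'   Strand is preserved but ignored by all overlap arithmetic.
#' @param label Library label (e.g. a tissue/replicate/prep identifier).
#' @param genome Optional [genome()]; when given, `end` must not exceed the
#'   chromosome length.
#' @return A `PeakSet` data.frame (columns chrom, start, end, name, score,
#'   strand) sorted by (chrom, start, end).
#' @examples
#' peak_set("chr1", c(0, 500), c(100, 900), score = c(8, 3))
#' @export
peak_set <- function(chrom, start, end, name = NA_character_,
                     score = NA_real_, strand = ".",
                     label = "peaks", genome = NULL) {
  n <- max(length(chrom), length(start), length(end))
  df <- data.frame(chrom = rep_len(as.character(chrom), n),
                   start = as.numeric(start),
                   end = as.numeric(end),
                   name = rep_len(as.character(name), n),
                   score = rep_len(as.numeric(score), n),
                   strand = rep_len(as.character(strand), n),
                   stringsAsFactors = FALSE)
  validate_intervals(df, genome = genome)
  if (!all(df$strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("PeakSet", "data.frame"), label = label)
}

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s': %d intervals on %d chromosome(s)\n",
              attr(x, "label"), nrow(x), length(unique(x$chrom))))
  if (nrow(x)) print(head(as.data.frame(x), 6L))
  invisible(x)
}

#' Label of a peak set
#' @param x A `PeakSet`.
#' @return The label string.
#' @export
peak_label <- function(x) attr(x, "label") %||% "peaks"

`%||%` <- function(a, b) if (is.null(a)) b else a

## Validates the interval contract shared by every module: parseable
## coordinates, 0 <= start < end, and (when a genome is attached) end within
## the chromosome.  Used by constructors and generators alike.
validate_intervals <- function(df, genome = NULL, what = "interval") {
  if (nrow(df) == 0L) return(invisible(df))
  if (anyNA(df$chrom) || any(!nzchar(df$chrom)))
    stop(what, "s must have non-empty chromosome names")
  if (anyNA(df$start) || anyNA(df$end))
    stop(what, " coordinates must be non-missing")
  if (any(df$start < 0) || any(df$start >= df$end))
    stop(what, "s must satisfy 0 <= start < end")
  if (!is.null(genome)) {
    len <- setNames(genome$length, genome$chrom)
    unknown <- setdiff(df$chrom, genome$chrom)
    if (length(unknown))
      stop("chromosome(s) not in genome: ", paste(unknown, collapse = ", "))
    if (any(df$end > len[df$chrom]))
      stop(what, "s extend beyond chromosome end")
  }
  invisible(df)
}

## data.frame (0-based half-open) -> GRanges (1-based closed)
as_granges <- function(df) {
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start + 1, df$end))
}

## data.frame -> named list of IRanges keyed by chromosome (1-based closed).
## Per-chromosome IRanges keeps the hot set-arithmetic paths free of the
## seqinfo bookkeeping that whole-genome containers carry.
as_irl <- function(df) {
  idx <- split(seq_len(nrow(df)), df$chrom)
  lapply(idx, function(i) IRanges::IRanges(df$start[i] + 1, df$end[i]))
}

irl_to_df <- function(irl) {
  n <- vapply(irl, length, integer(1))
  data.frame(chrom = rep(names(irl), n),
             start = as.numeric(unlist(lapply(irl, IRanges::start),
                                       use.names = FALSE)) - 1,
             end = as.numeric(unlist(lapply(irl, IRanges::end),
                                     use.names = FALSE)),
             stringsAsFactors = FALSE)
}

## Per-row flags: does each interval of `a` share >= min_overlap bases with
## the merged footprint of `b`?
overlap_flags <- function(a, b, min_overlap = 1) {
  out <- logical(nrow(a))
  if (nrow(a) == 0L || nrow(b) == 0L) return(out)
  bm <- lapply(as_irl(b), IRanges::reduce)
  idx <- split(seq_len(nrow(a)), a$chrom)
  for (ch in names(idx)) {
    if (is.null(bm[[ch]])) next
    i <- idx[[ch]]
    out[i] <- IRanges::countOverlaps(
      IRanges::IRanges(a$start[i] + 1, a$end[i]), bm[[ch]],
      minoverlap = min_overlap) > 0
  }
  out
}

## Warn when two interval sets share no chromosome names (likely a naming
## mismatch such as "chr1" vs "1"); exact string matching is used throughout.
check_shared_chroms <- function(a, b) {
  if (nrow(a) && nrow(b) && !length(intersect(unique(a$chrom), unique(b$chrom))))
    warning("interval sets share no chromosome names; ",
            "check naming conventions (no 'chr' aliasing is performed)")
  invisible(NULL)
}

#' Sort and merge intervals
#'
#' Merges intervals that overlap or abut within `min_gap` bases, returning a
#' sorted, pairwise-disjoint set.  The total number of distinct covered bases
#' is preserved (and with `min_gap > 0`, gap bases are added).
#'
#' @param intervals A data.frame with columns chrom, start, end (0-based
#'   half-open), e.g. a [peak_set()].
#' @param min_gap Two intervals separated by at most this many bases are
#'   merged (default 0: only overlapping or abutting intervals merge).
#' @return data.frame of disjoint intervals sorted by (chrom, start).
#' @examples
#' sort_and_merge(data.frame(chrom = "chr1", start = c(0, 5, 30),
#'                           end = c(10, 20, 40)))
#' @export
sort_and_merge <- function(intervals, min_gap = 0) {
  if (min_gap < 0) stop("min_gap must be non-negative")
  validate_intervals(intervals)
  if (nrow(intervals) == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  irl_to_df(lapply(as_irl(intervals), IRanges::reduce,
                   min.gapwidth = min_gap + 1))
}

#' Total distinct bases covered by a set of intervals
#'
#' Intervals are merged first, so overlapping peaks never count a base twice
#' (the "Bases covered" summary of a peak set).
#'
#' @inheritParams sort_and_merge
#' @return Number of distinct covered bases.
#' @export
total_bases <- function(intervals) {
  validate_intervals(intervals)
  sum(vapply(as_irl(intervals), function(ir)
    sum(IRanges::width(IRanges::reduce(ir))), numeric(1)))
}

#' Bases covered by both of two interval sets
#'
#' Both sets are merged before intersecting, so the result is the size of
#' the base-level intersection of their footprints; symmetric in A and B.
#'
#' @param a,b Interval data.frames (chrom, start, end).
#' @return Number of bases covered by both sets.
#' @export
intersect_bases <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(0)
  ia <- as_irl(a); ib <- as_irl(b)
  sum(vapply(intersect(names(ia), names(ib)), function(ch)
    sum(IRanges::width(IRanges::intersect(ia[[ch]], ib[[ch]]))),
    numeric(1)))
}

#' Does an interval overlap a set by at least `min_overlap` bases?
#'
#' @param x A single-row interval data.frame (or list with chrom/start/end).
#' @param s An interval data.frame.
#' @param min_overlap Minimum shared bases (>= 1); intervals are half-open,
#'   so `[a,b)` and `[b,c)` never overlap.
#' @return Logical.
#' @export
overlaps_any <- function(x, s, min_overlap = 1) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  x <- as.data.frame(x)[, c("chrom", "start", "end")]
  validate_intervals(x); validate_intervals(s)
  if (nrow(s) == 0L) return(FALSE)
  any(overlap_flags(x, s, min_overlap))
}

#' Base-level Jaccard index of two interval sets
#'
#' `intersect / union` of covered bases after merging each set; the
#' statistic bedtools/pybedtools `jaccard` reports, used as a replicate
#' concordance metric.
#'
#' @param a,b Interval data.frames.
#' @return Jaccard index in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  validate_intervals(a); validate_intervals(b)
  ta <- total_bases(a); tb <- total_bases(b)
  if (ta + tb == 0) stop("jaccard undefined: both interval sets are empty")
  check_shared_chroms(a, b)
  i <- intersect_bases(a, b)
  i / (ta + tb - i)
}
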