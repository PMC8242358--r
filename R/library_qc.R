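## Library enrichment and concordance metrics: FRiP, peak summaries,
## replicate-confirmed counts, UpSet-style intersection patterns, binned
## RPKM coverage, correlation, PCA, fingerprint (Lorenz) curves and the
## synthetic Jensen-Shannon distance.

#' Construct a fragment set
#'
#' Paired-end fragment spans (one interval per sequenced fragment) for one
#' library.
#'
#' @param chrom,start,end Fragment coordinates, 0-based half-open.
#' @param label Library identifier.
#' @param genome Optional [genome()] for coordinate validation.
#' @return A `FragmentSet` data.frame with attributes `label` and `n_total`.
#' @export
fragment_set <- function(chrom, start, end, label = "fragments",
                         genome = NULL) {
  df <- data.frame(chrom = as.character(chrom), start = as.numeric(start),
                   end = as.numeric(end), stringsAsFactors = FALSE)
  validate_intervals(df, genome = genome, what = "fragment")
  structure(df, class = c("FragmentSet", "data.frame"),
            label = label, n_total = nrow(df))
}

#' Fraction of fragments in peaks (FRiP)
#'
#' The classic ATAC/ChIP enrichment metric: the fraction of sequenced
#' fragments overlapping the (merged) peak set by at least `min_overlap`
#' bases.  Fragments are paired-end units, so values are not directly
#' comparable to read-mate-based FRiP (each fragment corresponds to two
#' read mates).
#'
#' @param fragments A [fragment_set()] (must be non-empty).
#' @param peaks A [peak_set()] (an empty set gives FRiP 0).
#' @param min_overlap Minimum shared bases (default 1).
#' @return FRiP in \[0, 1\].
#' @export
frip <- function(fragments, peaks, min_overlap = 1) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  validate_intervals(fragments, what = "fragment")
  if (nrow(fragments) == 0L) stop("fragment set is empty")
  validate_intervals(peaks)
  if (nrow(peaks) == 0L) return(0)
  check_shared_chroms(fragments, peaks)
  sum(overlap_flags(fragments, peaks, min_overlap)) / nrow(fragments)
}

#' Summary statistics of a peak set
#'
#' Count, mean/median raw peak length and merged covered bases — the
#' per-library summary columns of a filtered-peak report.
#'
#' @param peaks A non-empty [peak_set()].
#' @return A one-row data.frame: count, mean_length, median_length,
#'   bases_covered.
#' @export
peak_summary <- function(peaks) {
  validate_intervals(peaks)
  if (nrow(peaks) == 0L) stop("cannot summarise an empty peak set")
  len <- peaks$end - peaks$start
  data.frame(count = nrow(peaks), mean_length = mean(len),
             median_length = median(len), bases_covered = total_bases(peaks))
}

#' Peaks of one set confirmed by another
#'
#' Number of peaks in `a` overlapping the merged peaks of `b` by at least
#' `min_overlap` bases.  Directional: it counts peaks of the first set.
#'
#' @param a,b [peak_set()]s.
#' @param min_overlap Minimum shared bases (default 1).
#' @return Count of confirmed peaks in `a` (0 when either set is empty).
#' @export
confirmed_count <- function(a, b, min_overlap = 1) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  validate_intervals(a); validate_intervals(b)
  if (nrow(a) == 0L || nrow(b) == 0L) return(0L)
  sum(overlap_flags(a, b, min_overlap))
}

#' UpSet-style exclusive intersection patterns of several peak sets
#'
#' The union of all peaks is merged into disjoint regions; each region is
#' assigned the exact set of libraries whose peaks overlap it by at least
#' `min_overlap` bases, and regions are counted per membership pattern
#' (region-centric counting, so patterns are disjoint and counts sum to the
#' number of merged union regions).
#'
#' @param peaksets A list of [peak_set()]s with distinct labels (>= 2).
#' @param min_overlap Minimum shared bases (default 1).
#' @return A data.frame with one row per observed pattern: one logical
#'   column per library label, plus `pattern` (labels joined by `&`) and
#'   `count`.
#' @export
intersection_patterns <- function(peaksets, min_overlap = 1) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  if (length(peaksets) < 2) stop("need at least 2 peak sets")
  labels <- vapply(peaksets, peak_label, character(1))
  if (anyDuplicated(labels))
    stop("duplicate peak set labels: ",
         paste(labels[duplicated(labels)], collapse = ", "))
  for (p in peaksets) validate_intervals(p)

  union_df <- do.call(rbind, lapply(peaksets, function(p)
    as.data.frame(p)[, c("chrom", "start", "end")]))
  regions <- sort_and_merge(union_df)
  if (nrow(regions) == 0L)
    return(data.frame(pattern = character(), count = integer()))
  member <- vapply(peaksets, function(p)
    overlap_flags(regions, p, min_overlap), logical(nrow(regions)))
  member <- matrix(member, nrow = nrow(regions),
                   dimnames = list(NULL, labels))
  pattern <- apply(member, 1L, function(row)
    paste(labels[row], collapse = "&"))
  tab <- table(pattern)
  out <- data.frame(pattern = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  flags <- vapply(labels, function(l)
    vapply(strsplit(out$pattern, "&", fixed = TRUE),
           function(p) l %in% p, logical(1)), logical(nrow(out)))
  cbind(as.data.frame(matrix(flags, nrow = nrow(out),
                             dimnames = list(NULL, labels))), out)
}

#' Tile a genome into fixed-size bins
#'
#' @param genome A [genome()].
#' @param bin_size Bin width in bp (>= 1); the last bin of each chromosome
#'   may be short.
#' @return A data.frame of bins (chrom, start, end) tiling each chromosome
#'   in order.
#' @export
genome_bins <- function(genome, bin_size = 1000) {
  if (!inherits(genome, "Genome")) stop("genome must be a Genome object")
  if (nrow(genome) == 0L) stop("genome is empty")
  if (bin_size < 1) stop("bin_size must be >= 1")
  do.call(rbind, lapply(seq_len(nrow(genome)), function(i) {
    starts <- seq(0, genome$length[i] - 1, by = bin_size)
    data.frame(chrom = genome$chrom[i], start = starts,
               end = pmin(starts + bin_size, genome$length[i]),
               stringsAsFactors = FALSE)
  }))
}

#' Binned fragment coverage, RPKM-normalized
#'
#' Counts fragments overlapping each fixed-size genome bin (a fragment
#' straddling a bin boundary is counted once per overlapped bin) and
#' normalizes to RPKM: `count * 1e9 / (n_total * bin_width)`.
#'
#' @param fragments A [fragment_set()].
#' @param genome A [genome()].
#' @param bin_size Bin width in bp (default 1000).
#' @return A data.frame of bins with raw `count` and `rpkm` columns.
#' @export
binned_coverage <- function(fragments, genome, bin_size = 1000) {
  bins <- genome_bins(genome, bin_size)
  validate_intervals(fragments, genome = genome, what = "fragment")
  n_total <- nrow(fragments)
  counts <- if (n_total == 0L) integer(nrow(bins)) else
    GenomicRanges::countOverlaps(as_granges(bins), as_granges(fragments))
  bins$count <- counts
  bins$rpkm <- if (n_total > 0)
    counts * 1e9 / (n_total * (bins$end - bins$start)) else 0
  bins
}

#' Assemble a coverage matrix across libraries
#'
#' @param fragment_sets List of [fragment_set()]s (distinct labels).
#' @param genome A [genome()].
#' @param bin_size Bin width in bp.
#' @return A `CoverageMatrix` list: `bins` (data.frame), `rpkm` and `count`
#'   (bins x libraries matrices), `bin_size`.
#' @export
coverage_matrix <- function(fragment_sets, genome, bin_size = 1000) {
  labels <- vapply(fragment_sets, function(f) attr(f, "label"), character(1))
  if (anyDuplicated(labels)) stop("duplicate library labels")
  covs <- lapply(fragment_sets, binned_coverage, genome = genome,
                 bin_size = bin_size)
  bins <- covs[[1]][, c("chrom", "start", "end")]
  structure(list(
    bins = bins,
    rpkm = matrix(unlist(lapply(covs, `[[`, "rpkm")), ncol = length(covs),
                  dimnames = list(NULL, labels)),
    count = matrix(unlist(lapply(covs, `[[`, "count")), ncol = length(covs),
                   dimnames = list(NULL, labels)),
    bin_size = bin_size), class = "CoverageMatrix")
}

#' Pearson correlation of library coverage profiles
#'
#' @param cov A [coverage_matrix()] (>= 2 libraries, >= 3 bins).
#' @param order_rows Reorder rows/columns by complete-linkage ("farthest
#'   point") clustering of `1 - r` for display (default `FALSE`).
#' @return Symmetric libraries x libraries correlation matrix with unit
#'   diagonal; pairs involving a zero-variance library are `NA` (flagged
#'   with a warning).
#' @export
correlation_matrix <- function(cov, order_rows = FALSE) {
  v <- cov$rpkm
  if (ncol(v) < 2) stop("need at least 2 libraries")
  if (nrow(v) < 3) stop("need at least 3 bins")
  zero_var <- apply(v, 2, sd) == 0
  if (any(zero_var))
    warning("zero-variance librar(ies): ",
            paste(colnames(v)[zero_var], collapse = ", "),
            "; correlations involving them are NA")
  r <- suppressWarnings(cor(v))
  diag(r) <- 1
  if (order_rows && !any(zero_var) && ncol(r) > 2) {
    ord <- stats::hclust(stats::as.dist(1 - r), method = "complete")$order
    r <- r[ord, ord]
  }
  r
}

#' Principal components of library coverage
#'
#' PCA of the libraries-by-bins RPKM matrix using all genomic bins (no
#' top-variance bin selection), centered per bin.
#'
#' @param cov A [coverage_matrix()].
#' @param n_components Number of components to return (at most the number
#'   of libraries).
#' @return List with `coordinates` (libraries x components) and
#'   `explained_variance` (fractions, non-increasing, summing to <= 1).
#' @export
coverage_pca <- function(cov, n_components = 2) {
  x <- t(cov$rpkm)                      # libraries x bins
  if (n_components > nrow(x))
    stop("more components than libraries")
  p <- prcomp(x, center = TRUE, scale. = FALSE)
  ev <- p$sdev^2 / sum(p$sdev^2)
  k <- min(n_components, ncol(p$x))
  coords <- p$x[, seq_len(k), drop = FALSE]
  if (k < n_components) {               # pad degenerate trailing components
    pad <- matrix(0, nrow(coords), n_components - k)
    coords <- cbind(coords, pad)
    ev <- c(ev, rep(0, n_components - k))
  }
  list(coordinates = coords,
       explained_variance = ev[seq_len(n_components)])
}

#' Fingerprint (Lorenz) curve and area under it
#'
#' Bins are sorted by ascending fragment count; the curve plots the
#' cumulative fraction of bins (x) against the cumulative fraction of
#' fragments (y), anchored at (0, 0).  A flat, unenriched library gives a
#' diagonal (AUC 0.5); concentrating coverage in few bins bows the curve
#' down (AUC approaches 0).  AUC is computed by the trapezoid rule, so a
#' single-bin spike among B bins has AUC exactly 1/(2B).
#'
#' @param counts Per-bin raw fragment counts (>= 2 bins, total > 0).
#' @return List with `x`, `y` (curve coordinates including the (0,0)
#'   anchor) and `auc` in (0, 0.5].
#' @export
fingerprint <- function(counts) {
  counts <- as.numeric(counts)
  if (length(counts) < 2) stop("need at least 2 bins")
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("all-zero count vector")
  s <- sort(counts)
  b <- length(s)
  x <- c(0, seq_len(b) / b)
  y <- c(0, cumsum(s) / sum(s))
  auc <- sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  list(x = x, y = y, auc = auc)
}

#' Synthetic Jensen-Shannon distance of a coverage profile
#'
#' Compares the observed per-bin count histogram with the histogram of an
#' equal-length synthetic sample drawn from a Poisson law with the observed
#' mean (the no-enrichment reference for a library sequenced to the same
#' depth).  The distance is the square root of the Jensen-Shannon
#' divergence with base-2 logarithms, so it lies in \[0, 1\]; larger means
#' more enrichment.
#'
#' @param counts Per-bin raw fragment counts (total > 0).
#' @param seed Integer seed for the synthetic Poisson draw (mandatory for
#'   reproducibility).
#' @return SJSD in \[0, 1\].
#' @export
sjsd <- function(counts, seed) {
  counts <- as.numeric(counts)
  if (anyNA(counts) || any(counts < 0)) stop("counts must be non-negative")
  if (sum(counts) == 0) stop("total count must be > 0")
  if (missing(seed)) stop("seed is required")
  synth <- withr_seed(seed, rpois(length(counts), mean(counts)))
  breaks <- 0:(max(counts, synth) + 1)   # integer count bins
  p <- tabulate(findInterval(counts, breaks), length(breaks) - 1)
  q <- tabulate(findInterval(synth, breaks), length(breaks) - 1)
  js_distance(p / sum(p), q / sum(q))
}

## Jensen-Shannon distance between two discrete distributions (base-2 logs).
js_distance <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    i <- a > 0
    sum(a[i] * log2(a[i] / b[i]))
  }
  sqrt(pmax(0, (kl(p, m) + kl(q, m)) / 2))
}

## Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}
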