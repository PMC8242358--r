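# Per-base boolean-array oracles for toy genomes (a few kb): every
# base-counting operation in the package must agree with these brute-force
# reimplementations.  The oracles deliberately share no code with the
# package's interval arithmetic.

# Logical membership vector per chromosome: position i (1-based) is TRUE
# when base [i-1, i) is covered.
oracle_mask <- function(df, chrom_len) {
  masks <- lapply(chrom_len, function(L) logical(L))
  for (k in seq_len(nrow(df))) {
    ch <- df$chrom[k]
    idx <- seq.int(df$start[k] + 1, df$end[k])
    masks[[ch]][idx] <- TRUE
  }
  masks
}

oracle_total_bases <- function(df, chrom_len) {
  sum(vapply(oracle_mask(df, chrom_len), sum, numeric(1)))
}

oracle_intersect_bases <- function(a, b, chrom_len) {
  ma <- oracle_mask(a, chrom_len)
  mb <- oracle_mask(b, chrom_len)
  sum(vapply(names(chrom_len), function(ch) sum(ma[[ch]] & mb[[ch]]),
             numeric(1)))
}

oracle_jaccard <- function(a, b, chrom_len) {
  i <- oracle_intersect_bases(a, b, chrom_len)
  u <- oracle_total_bases(a, chrom_len) + oracle_total_bases(b, chrom_len) - i
  i / u
}

oracle_overlaps_any <- function(x, s, chrom_len, min_overlap = 1) {
  oracle_intersect_bases(as.data.frame(x), s, chrom_len) >= min_overlap
}

# One interval of `a` at a time against the union of `b`.
oracle_confirmed_count <- function(a, b, chrom_len, min_overlap = 1) {
  sum(vapply(seq_len(nrow(a)), function(k)
    oracle_intersect_bases(a[k, , drop = FALSE], b, chrom_len) >=
      min_overlap, logical(1)))
}

# Region-centric membership patterns: runs of the union mask are the merged
# regions; each run's labels are the sets overlapping it by >= min_overlap.
oracle_patterns <- function(sets, chrom_len, min_overlap = 1) {
  union_df <- do.call(rbind, lapply(sets, function(s)
    as.data.frame(s)[, c("chrom", "start", "end")]))
  union_mask <- oracle_mask(union_df, chrom_len)
  set_masks <- lapply(sets, oracle_mask, chrom_len = chrom_len)
  patterns <- character(0)
  for (ch in names(chrom_len)) {
    r <- rle(union_mask[[ch]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1
    for (j in which(r$values)) {
      run <- starts[j]:ends[j]
      labs <- names(sets)[vapply(set_masks, function(m)
        sum(m[[ch]][run]) >= min_overlap, logical(1))]
      patterns <- c(patterns, paste(labs, collapse = "&"))
    }
  }
  table(patterns)
}

oracle_classify <- function(promoters, peaks, chrom_len, min_overlap = 1) {
  vapply(seq_len(nrow(promoters)), function(k)
    oracle_intersect_bases(promoters[k, c("chrom", "start", "end")],
                           peaks, chrom_len) >= min_overlap, logical(1))
}

# Random toy interval set on chromosomes "a" (and optionally "b").
random_intervals <- function(n, chrom_len, scored = FALSE) {
  chrom <- sample(names(chrom_len), n, replace = TRUE)
  L <- unname(unlist(chrom_len[chrom]))
  start <- floor(runif(n) * (L - 1))
  end <- start + 1 + floor(runif(n) * pmin(L - start - 1, 500))
  peak_set(chrom, start, end,
           score = if (scored) round(runif(n, 0, 10), 2) else NA_real_,
           label = paste0("rand", sample.int(1e6, 1)))
}

toy_chroms <- function(len_a = 5000, len_b = 3000) {
  c(a = len_a, b = len_b)
}
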