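## Fully in-silico chromatin-accessibility datasets with known ground truth.
##
## A synthetic genome carries disjoint planted "active" regulatory regions
## (marked by H3K4me1/H3K4me3 + H3K27ac, so the truth-set builder recovers
## them exactly) and "repressed" regions (H3K27me3).  Peak calls are a
## mixture of true peaks inside active regions (high scores) and decoys
## inside repressed regions (low scores).  Fragments hit true peaks with a
## configured FRiP and show the nucleosome fragment-length ladder
## (nucleosome-free / mono- / di-nucleosomal).  Genes are planted so that a
## configured fraction have a true peak over their promoter, and expression
## is shifted upward for those open-promoter genes.  Every random draw is
## governed by one seed via per-stage derived seeds, so the generator is
## byte-reproducible.

#' Configuration for the synthetic dataset generator
#'
#' Defaults describe a small two-chromosome genome with well-separated true
#' and decoy score distributions and a target FRiP of 0.5.
#'
#' @param seed Integer master seed; every stage derives its own stream from
#'   it.
#' @param n_chroms,chrom_length Genome shape (chromosomes x bp).
#' @param n_active_regions,n_repressed_regions Planted truth regions.
#' @param region_length Length range (min, max) of planted regions, bp.
#' @param n_true_peaks,n_decoy_peaks Peak calls planted inside active /
#'   repressed regions.
#' @param mu_true,mu_decoy,sigma_score Normal score model for true and
#'   decoy calls.
#' @param n_fragments Sequenced fragments to simulate.
#' @param target_frip Probability that a fragment lands inside a true peak
#'   (background fragments are placed outside all calls).
#' @param frag_mix Mixture weights (summing to 1) for the fragment-length
#'   ladder: nucleosome-free ~ Uniform(50, 120) bp, mono-nucleosomal ~
#'   Normal(200, 20), di-nucleosomal ~ Normal(400, 30).
#' @param n_genes Genes to plant.
#' @param open_fraction Fraction of genes whose promoter overlaps a true
#'   peak.
#' @param expression_effect Mean expression shift added to open-promoter
#'   genes (variance-stabilized scale).
#' @param baseline_expression,sigma_expr Expression baseline and noise SD.
#' @param n_samples Expression samples (replicates).
#' @param decoy_mode `"repressed"` plants decoys inside repressed regions
#'   (they accrue false-positive bases); `"neutral"` plants them outside
#'   both truth sets (they contribute neither TP nor FP, exercising the
#'   undefined-precision path).
#' @return A `SyntheticConfig` list.
#' @export
synthetic_config <- function(seed = 1,
                             n_chroms = 2, chrom_length = 5e6,
                             n_active_regions = 300,
                             n_repressed_regions = 100,
                             region_length = c(1000, 5000),
                             n_true_peaks = 300, n_decoy_peaks = 100,
                             mu_true = 10, mu_decoy = 3, sigma_score = 1,
                             n_fragments = 1e5, target_frip = 0.5,
                             frag_mix = c(nfr = 0.45, mono = 0.40, di = 0.15),
                             n_genes = 500, open_fraction = 0.5,
                             expression_effect = 2,
                             baseline_expression = 5, sigma_expr = 1,
                             n_samples = 2,
                             decoy_mode = c("repressed", "neutral")) {
  decoy_mode <- match.arg(decoy_mode)
  cfg <- list(seed = as.integer(seed), n_chroms = n_chroms,
              chrom_length = chrom_length,
              n_active_regions = n_active_regions,
              n_repressed_regions = n_repressed_regions,
              region_length = region_length,
              n_true_peaks = n_true_peaks, n_decoy_peaks = n_decoy_peaks,
              mu_true = mu_true, mu_decoy = mu_decoy,
              sigma_score = sigma_score,
              n_fragments = n_fragments, target_frip = target_frip,
              frag_mix = frag_mix, n_genes = n_genes,
              open_fraction = open_fraction,
              expression_effect = expression_effect,
              baseline_expression = baseline_expression,
              sigma_expr = sigma_expr, n_samples = n_samples,
              decoy_mode = decoy_mode)
  counts <- c(cfg$n_chroms, cfg$n_active_regions, cfg$n_repressed_regions,
              cfg$n_true_peaks, cfg$n_decoy_peaks, cfg$n_fragments,
              cfg$n_genes, cfg$n_samples)
  if (any(counts < 0)) stop("counts must be non-negative")
  if (cfg$n_chroms < 1 || cfg$chrom_length < 1) stop("empty genome")
  if (abs(sum(cfg$frag_mix) - 1) > 1e-8)
    stop("frag_mix weights must sum to 1")
  if (cfg$target_frip <= 0 || cfg$target_frip >= 1)
    stop("target_frip must be in (0, 1)")
  if (length(cfg$region_length) != 2 ||
      cfg$region_length[1] < 100 ||
      cfg$region_length[1] > cfg$region_length[2])
    stop("region_length must be (min, max) with min >= 100")
  structure(cfg, class = "SyntheticConfig")
}

## Per-stage seed derivation: one master seed, independent streams per
## generation stage so modules can be regenerated independently.
.stage_seed <- function(seed, stage) {
  (as.numeric(seed) * 7919 + stage * 104729) %% 2147483647
}

## Place disjoint regions of the given lengths on a genome, each assigned
## to a uniformly random chromosome, separated by at least `min_gap` bases.
.place_disjoint <- function(lengths, genome, min_gap = 1) {
  n <- length(lengths)
  if (n == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  ci <- sample.int(nrow(genome), n, replace = TRUE)
  out <- vector("list", nrow(genome))
  for (i in seq_len(nrow(genome))) {
    li <- lengths[ci == i]
    k <- length(li)
    if (!k) next
    G <- genome$length[i]
    free <- G - sum(li) - (k - 1) * min_gap
    if (free < 0)
      stop("cannot place regions without overlap on ", genome$chrom[i],
           "; use a larger genome or fewer/shorter regions")
    extra <- sort(floor(runif(k) * (free + 1)))
    starts <- extra + (seq_len(k) - 1) * min_gap + cumsum(c(0, li[-k]))
    out[[i]] <- data.frame(chrom = genome$chrom[i], start = starts,
                           end = starts + li, stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, out)
  df[order(df$chrom, df$start), , drop = FALSE]
}

## Sample n intervals of the given lengths uniformly on the genome,
## rejecting any that overlap `avoid` (a merged interval data.frame).
.sample_avoiding <- function(n, lens, genome, avoid, max_iter = 200) {
  if (n == 0L)
    return(data.frame(chrom = character(), start = numeric(),
                      end = numeric(), stringsAsFactors = FALSE))
  avoid_gr <- if (nrow(avoid)) as_granges(avoid) else NULL
  chrom <- character(n); start <- numeric(n)
  need <- seq_len(n); lens_need <- lens
  for (iter in seq_len(max_iter)) {
    m <- length(need)
    ci <- sample.int(nrow(genome), m, replace = TRUE,
                     prob = genome$length)
    maxs <- genome$length[ci] - lens_need
    st <- floor(runif(m) * pmax(0, maxs + 1))
    bad <- maxs < 0
    if (!is.null(avoid_gr)) {
      cand <- GenomicRanges::GRanges(
        genome$chrom[ci], IRanges::IRanges(st + 1, st + lens_need))
      bad <- bad | GenomicRanges::countOverlaps(cand, avoid_gr) > 0
    }
    keep <- need[!bad]
    chrom[keep] <- genome$chrom[ci[!bad]]
    start[keep] <- st[!bad]
    need <- need[bad]; lens_need <- lens_need[bad]
    if (!length(need)) break
  }
  if (length(need))
    stop("could not place ", length(need),
         " interval(s) outside existing features; genome too crowded")
  data.frame(chrom = chrom, start = start, end = start + lens,
             stringsAsFactors = FALSE)
}

## Draw fragment lengths from the nucleosome ladder mixture.
.fragment_lengths <- function(n, weights) {
  comp <- sample.int(3, n, replace = TRUE, prob = weights)
  len <- numeric(n)
  len[comp == 1] <- runif(sum(comp == 1), 50, 120)
  len[comp == 2] <- rnorm(sum(comp == 2), 200, 20)
  len[comp == 3] <- rnorm(sum(comp == 3), 400, 30)
  pmax(30, round(len))
}

#' Generate a synthetic chromatin-accessibility dataset
#'
#' Deterministic for a fixed `config$seed`.  See [synthetic_config()] for
#' the planted structure.  The returned ground-truth ledger records, for
#' every peak call, whether it is a planted true peak, for every gene
#' whether its promoter was planted over a true peak, and the exact
#' expected values of downstream metrics (precision of the unfiltered call
#' set, realized in-peak fragment fraction).
#'
#' @param config A [synthetic_config()].
#' @return A `SyntheticDataset` list: `genome`, `active_regions`,
#'   `repressed_regions`, `histone` (named list of four [peak_set()]s),
#'   `calls` (scored [peak_set()]), `fragments` ([fragment_set()]),
#'   `annotation` ([gene_annotation()]), `expression` (data.frame),
#'   `ledger` (list).
#' @export
generate_dataset <- function(config = synthetic_config()) {
  if (!inherits(config, "SyntheticConfig"))
    stop("config must come from synthetic_config()")
  gnm <- genome(paste0("chr", seq_len(config$n_chroms)),
                rep(config$chrom_length, config$n_chroms))

  ## -- planted truth regions ------------------------------------------
  set.seed(.stage_seed(config$seed, 1))
  n_reg <- config$n_active_regions + config$n_repressed_regions
  reg_len <- round(runif(n_reg, config$region_length[1],
                         config$region_length[2]))
  regions <- .place_disjoint(reg_len, gnm, min_gap = 1000)
  is_active <- rep(FALSE, n_reg)
  if (config$n_active_regions > 0)
    is_active[sample.int(n_reg, config$n_active_regions)] <- TRUE
  active <- regions[is_active, , drop = FALSE]
  repressed <- regions[!is_active, , drop = FALSE]
  rownames(active) <- rownames(repressed) <- NULL

  ## -- histone peaks: marks sit exactly on the planted regions --------
  set.seed(.stage_seed(config$seed, 2))
  k4me1_idx <- if (nrow(active)) sort(sample.int(
    nrow(active), ceiling(nrow(active) / 2))) else integer()
  histone <- list(
    h3k4me1 = peak_set(active$chrom[k4me1_idx], active$start[k4me1_idx],
                       active$end[k4me1_idx], label = "H3K4me1",
                       genome = gnm),
    h3k4me3 = peak_set(active$chrom, active$start, active$end,
                       label = "H3K4me3", genome = gnm),
    h3k27ac = peak_set(active$chrom, active$start, active$end,
                       label = "H3K27ac", genome = gnm),
    h3k27me3 = peak_set(repressed$chrom, repressed$start, repressed$end,
                        label = "H3K27me3", genome = gnm))

  ## -- peak calls: true peaks in active regions, decoys per decoy_mode -
  set.seed(.stage_seed(config$seed, 3))
  place_in <- function(n, regions) {
    if (n == 0L || nrow(regions) == 0L)
      return(data.frame(chrom = character(), start = numeric(),
                        end = numeric(), stringsAsFactors = FALSE))
    ri <- if (n <= nrow(regions)) sample.int(nrow(regions), n) else
      sample.int(nrow(regions), n, replace = TRUE)
    rl <- regions$end[ri] - regions$start[ri]
    ## calls recover most of their region, as peak callers approximately
    ## recover regulatory elements; keeps recall high at low cutoffs
    pl <- pmin(rl, pmax(200, round(runif(n, 0.9, 1) * rl)))
    off <- floor(runif(n) * (rl - pl + 1))
    data.frame(chrom = regions$chrom[ri],
               start = regions$start[ri] + off,
               end = regions$start[ri] + off + pl,
               stringsAsFactors = FALSE)
  }
  true_df <- place_in(config$n_true_peaks, active)
  decoy_df <- if (config$decoy_mode == "repressed")
    place_in(config$n_decoy_peaks, repressed)
  else
    .sample_avoiding(config$n_decoy_peaks,
                     round(runif(config$n_decoy_peaks, 500, 2000)),
                     gnm, sort_and_merge(regions))
  n_calls <- nrow(true_df) + nrow(decoy_df)
  calls_df <- rbind(true_df, decoy_df)
  scores <- round(c(rnorm(nrow(true_df), config$mu_true, config$sigma_score),
                    rnorm(nrow(decoy_df), config$mu_decoy,
                          config$sigma_score)), 4)
  names_ <- sprintf("peak_%05d", seq_len(n_calls))
  is_true <- c(rep(TRUE, nrow(true_df)), rep(FALSE, nrow(decoy_df)))
  calls <- peak_set(calls_df$chrom, calls_df$start, calls_df$end,
                    name = names_, score = scores, strand = ".",
                    label = "synthetic_calls", genome = gnm)
  truth_by_name <- setNames(is_true, names_)

  ## -- fragments: in-peak with probability target_frip ----------------
  set.seed(.stage_seed(config$seed, 4))
  nf <- config$n_fragments
  frag <- data.frame(chrom = character(), start = numeric(),
                     end = numeric(), stringsAsFactors = FALSE)
  n_in <- 0L
  if (nf > 0) {
    if (nrow(true_df) == 0L)
      stop("cannot target a positive FRiP with no true peaks")
    lens <- .fragment_lengths(nf, config$frag_mix)
    in_peak <- runif(nf) < config$target_frip
    n_in <- sum(in_peak)
    pi <- sample.int(nrow(true_df), n_in, replace = TRUE)
    pw <- true_df$end[pi] - true_df$start[pi]
    li <- pmin(lens[in_peak], pw)          # clip to fit inside the peak
    off <- floor(runif(n_in) * (pw - li + 1))
    inside <- data.frame(chrom = true_df$chrom[pi],
                         start = true_df$start[pi] + off,
                         end = true_df$start[pi] + off + li,
                         stringsAsFactors = FALSE)
    outside <- .sample_avoiding(nf - n_in, lens[!in_peak], gnm,
                                sort_and_merge(calls_df))
    frag <- rbind(inside, outside)[order(c(which(in_peak),
                                           which(!in_peak))), ]
  }
  fragments <- fragment_set(frag$chrom, frag$start, frag$end,
                            label = "synthetic_fragments", genome = gnm)

  ## -- genes: a configured fraction get a true peak over the promoter -
  set.seed(.stage_seed(config$seed, 5))
  upstream <- 1000
  ng <- config$n_genes
  gene_open <- logical(0)
  annotation <- gene_annotation(character(), character(), numeric(),
                                numeric(), character())
  if (ng > 0) {
    if (nrow(true_df) == 0L && config$open_fraction > 0)
      stop("cannot plant open promoters with no true peaks")
    n_open <- round(config$open_fraction * ng)
    gene_len <- round(runif(ng, 2000, 10000))
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    chrom <- character(ng); gstart <- numeric(ng); gend <- numeric(ng)
    if (n_open > 0) {
      pi <- sample.int(nrow(true_df), n_open, replace = TRUE)
      ts <- true_df$start[pi]; te <- true_df$end[pi]
      anchor <- ts + 1 + floor(runif(n_open) * (te - ts - 1))
      plus <- strand[seq_len(n_open)] == "+"
      glen <- gene_len[seq_len(n_open)]
      clen <- setNames(gnm$length, gnm$chrom)[true_df$chrom[pi]]
      chrom[seq_len(n_open)] <- true_df$chrom[pi]
      gstart[seq_len(n_open)] <- ifelse(plus, anchor,
                                        pmax(0, anchor - glen))
      gend[seq_len(n_open)] <- ifelse(plus, pmin(clen, anchor + glen),
                                      anchor)
    }
    if (ng > n_open) {
      idx <- (n_open + 1):ng
      glen <- gene_len[idx]
      ## one buffered interval = promoter + gene body, placed clear of all
      ## calls so the promoter cannot overlap any peak
      buf <- .sample_avoiding(length(idx), glen + upstream, gnm,
                              sort_and_merge(calls_df))
      plus <- strand[idx] == "+"
      chrom[idx] <- buf$chrom
      gstart[idx] <- ifelse(plus, buf$start + upstream, buf$start)
      gend[idx] <- ifelse(plus, buf$end, buf$end - upstream)
    }
    gene_open <- c(rep(TRUE, n_open), rep(FALSE, ng - n_open))
    ord <- sample.int(ng)                 # shuffle so ids carry no signal
    annotation <- gene_annotation(sprintf("gene_%05d", seq_len(ng)),
                                  chrom[ord], gstart[ord], gend[ord],
                                  strand[ord])
    gene_open <- gene_open[ord]
  }

  ## -- expression: baseline + effect for open promoters + noise -------
  set.seed(.stage_seed(config$seed, 6))
  expression <- data.frame(gene_id = annotation$gene_id,
                           stringsAsFactors = FALSE)
  for (s in seq_len(config$n_samples))
    expression[[sprintf("sample_%d", s)]] <-
      round(config$baseline_expression +
              config$expression_effect * as.numeric(gene_open) +
              rnorm(ng, 0, config$sigma_expr), 6)

  ## -- ground-truth ledger --------------------------------------------
  tp0 <- intersect_bases(calls, active)
  fp0 <- intersect_bases(calls, repressed)
  ledger <- list(
    config = unclass(config),
    active_bases = total_bases(active),
    repressed_bases = total_bases(repressed),
    n_true_calls = sum(is_true), n_decoy_calls = sum(!is_true),
    call_is_true = as.list(truth_by_name),
    gene_promoter_open = if (ng > 0)
      as.list(setNames(gene_open, annotation$gene_id)) else list(),
    expected_precision_all_calls =
      if (tp0 + fp0 > 0) tp0 / (tp0 + fp0) else NA,
    realized_frip = if (nf > 0) n_in / nf else NA,
    expression_effect = config$expression_effect)

  structure(list(genome = gnm, active_regions = active,
                 repressed_regions = repressed, histone = histone,
                 calls = calls, fragments = fragments,
                 annotation = annotation, expression = expression,
                 ledger = ledger),
            class = "SyntheticDataset")
}

#' @export
print.SyntheticDataset <- function(x, ...) {
  cat(sprintf(paste0(
    "SyntheticDataset: %d chrom(s), %d active + %d repressed regions,\n",
    "  %d calls (%d true), %d fragments, %d genes\n"),
    nrow(x$genome), nrow(x$active_regions), nrow(x$repressed_regions),
    nrow(x$calls), x$ledger$n_true_calls, nrow(x$fragments),
    nrow(x$annotation)))
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits the dataset in the formats the rest of the package reads: BED6
#' histone peaks, gappedPeak scored calls (the real-valued score in the
#' signalValue column, 13), BED6 fragments, a chromosome-sizes TSV, GTF
#' gene records, an expression TSV, and the ground-truth ledger as JSON.
#'
#' @param ds A [generate_dataset()] result.
#' @param dir Output directory (created if missing).
#' @return Named character vector of written paths (the file manifest).
#' @export
write_dataset <- function(ds, dir) {
  if (!inherits(ds, "SyntheticDataset")) stop("ds must be a SyntheticDataset")
  if (!dir.exists(dir) &&
      !dir.create(dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create directory ", dir)
  paths <- c(chrom_sizes = file.path(dir, "chrom.sizes"),
             h3k4me1 = file.path(dir, "h3k4me1.bed"),
             h3k4me3 = file.path(dir, "h3k4me3.bed"),
             h3k27ac = file.path(dir, "h3k27ac.bed"),
             h3k27me3 = file.path(dir, "h3k27me3.bed"),
             calls = file.path(dir, "calls.gappedPeak"),
             fragments = file.path(dir, "fragments.bed"),
             annotation = file.path(dir, "genes.gtf"),
             expression = file.path(dir, "expression.tsv"),
             ledger = file.path(dir, "ledger.json"))

  write.table(ds$genome, paths["chrom_sizes"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  for (mark in names(ds$histone))
    write_bed(ds$histone[[mark]], paths[[mark]])

  cl <- as.data.frame(ds$calls)
  gp <- data.frame(cl$chrom, .fmt(cl$start), .fmt(cl$end), cl$name,
                   pmin(1000L, pmax(0L, round(cl$score * 10))),
                   cl$strand, .fmt(cl$start), .fmt(cl$end), "0", 1L,
                   paste0(.fmt(cl$end - cl$start), ","), "0,",
                   .fmt(cl$score), -1L, -1L)
  write.table(gp, paths["calls"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  fr <- as.data.frame(ds$fragments)
  frag_bed <- peak_set(fr$chrom, fr$start, fr$end,
                       name = sprintf("frag_%07d", seq_len(nrow(fr))),
                       label = "fragments")
  write_bed(frag_bed, paths["fragments"])

  an <- as.data.frame(ds$annotation)
  gtf <- data.frame(an$chrom, "peakproof", "gene", .fmt(an$start + 1),
                    .fmt(an$end), ".", an$strand, ".",
                    sprintf('gene_id "%s";', an$gene_id))
  write.table(gtf, paths["annotation"], sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)

  write.table(ds$expression, paths["expression"], sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = TRUE)
  jsonlite::write_json(ds$ledger, paths["ledger"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}

.fmt <- function(x) format(x, scientific = FALSE, trim = TRUE)

#' Read back a written synthetic dataset
#'
#' Inverse of [write_dataset()] built on the package's own readers; used to
#' verify round-trip consistency between emitted files and the in-memory
#' dataset.
#'
#' @param dir Directory written by [write_dataset()].
#' @return List with the same components as [generate_dataset()] (the
#'   ledger is the parsed JSON).
#' @export
read_dataset <- function(dir) {
  gnm <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  histone <- list(
    h3k4me1 = read_peaks(file.path(dir, "h3k4me1.bed"), label = "H3K4me1"),
    h3k4me3 = read_peaks(file.path(dir, "h3k4me3.bed"), label = "H3K4me3"),
    h3k27ac = read_peaks(file.path(dir, "h3k27ac.bed"), label = "H3K27ac"),
    h3k27me3 = read_peaks(file.path(dir, "h3k27me3.bed"),
                          label = "H3K27me3"))
  calls <- read_peaks(file.path(dir, "calls.gappedPeak"),
                      format = "gappedPeak", score_column = 13,
                      label = "synthetic_calls", genome = gnm)
  fr <- read_peaks(file.path(dir, "fragments.bed"))
  list(genome = gnm, histone = histone, calls = calls,
       fragments = fragment_set(fr$chrom, fr$start, fr$end,
                                label = "synthetic_fragments",
                                genome = gnm),
       annotation = read_gene_annotation(file.path(dir, "genes.gtf")),
       expression = read_expression_table(file.path(dir, "expression.tsv")),
       ledger = jsonlite::read_json(file.path(dir, "ledger.json"),
                                    simplifyVector = FALSE))
}
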