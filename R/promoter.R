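## Promoter accessibility versus gene expression.
##
## A gene's presumed promoter is the 1 kb immediately upstream of its
## annotated start (strand-aware: upstream of `start` for + genes, of `end`
## for - genes).  A promoter is "open" under a peak set when it overlaps
## the merged peaks by at least 1 bp; genes are then grouped by their
## open/closed pattern across peak sets and each group's expression is
## summarised.

#' Construct a gene annotation
#'
#' @param gene_id Unique gene identifiers.
#' @param chrom,start,end Gene body coordinates, 0-based half-open.
#' @param strand `"+"` or `"-"` per gene.
#' @return A `GeneAnnotation` data.frame.
#' @export
gene_annotation <- function(gene_id, chrom, start, end, strand) {
  df <- data.frame(gene_id = as.character(gene_id),
                   chrom = as.character(chrom),
                   start = as.numeric(start), end = as.numeric(end),
                   strand = as.character(strand), stringsAsFactors = FALSE)
  if (anyDuplicated(df$gene_id)) stop("gene_id values must be unique")
  if (!all(df$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  validate_intervals(df, what = "gene")
  structure(df, class = c("GeneAnnotation", "data.frame"))
}

#' Read gene records from a GTF or BED6 file
#'
#' GTF: rows with feature type `"gene"` are kept and `gene_id` is taken
#' from the attributes column (GTF coordinates are 1-based closed and are
#' converted to 0-based half-open).  BED6: `gene_id` is the name field.
#'
#' @param path File path.
#' @param format `"gtf"`, `"bed6"` or `"auto"` (by file extension).
#' @return A [gene_annotation()].
#' @export
read_gene_annotation <- function(path, format = "auto") {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format, c("auto", "gtf", "bed6"))
  if (format == "auto")
    format <- if (grepl("\\.gtf(\\.gz)?$", path, ignore.case = TRUE))
      "gtf" else "bed6"
  if (format == "gtf") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (!length(lines))
      return(gene_annotation(character(), character(), numeric(),
                             numeric(), character()))
    f <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(f) != 9L)
    if (length(bad))
      stop("malformed GTF line ", bad[1], ": expected 9 fields")
    m <- matrix(unlist(f), ncol = 9, byrow = TRUE)
    keep <- m[, 3] == "gene"
    m <- m[keep, , drop = FALSE]
    ids <- sub('.*gene_id[ =]+"?([^";]+)"?.*', "\\1", m[, 9])
    gene_annotation(ids, m[, 1], as.numeric(m[, 4]) - 1, as.numeric(m[, 5]),
                    m[, 7])
  } else {
    p <- read_peaks(path, format = "bed6")
    if (anyNA(p$name)) stop("BED6 gene annotation requires gene ids in the name field")
    if (!all(p$strand %in% c("+", "-")))
      stop("BED6 gene annotation requires stranded records")
    gene_annotation(p$name, p$chrom, p$start, p$end, p$strand)
  }
}

#' Read a gene expression table
#'
#' Tab-separated with a header line: first column `gene_id`, remaining
#' columns one normalized abundance value per sample (e.g. on a
#' variance-stabilized scale).
#'
#' @param path File path.
#' @return Data.frame with `gene_id` plus one numeric column per sample.
#' @export
read_expression_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- "gene_id"
  df$gene_id <- as.character(df$gene_id)
  for (j in seq_along(df)[-1]) {
    df[[j]] <- as.numeric(df[[j]])
    if (anyNA(df[[j]])) stop("non-finite expression values in column ",
                             names(df)[j])
  }
  df
}

#' Derive promoter regions from a gene annotation
#'
#' The promoter of a + strand gene is `[start - upstream, start)`; of a
#' - strand gene, `[end, end + upstream)`.  Promoters are clamped to the
#' chromosome; genes whose clamped promoter is empty (a gene starting at
#' the chromosome edge) are dropped with a warning.  With
#' `ignore_strand = TRUE` every gene is treated as + strand (the literal
#' "upstream of the annotated start" reading).
#'
#' @param annotation A [gene_annotation()].
#' @param genome A [genome()] covering every gene's chromosome.
#' @param upstream Promoter width in bp (default 1000).
#' @param ignore_strand Treat all genes as + strand (default `FALSE`).
#' @return Data.frame of promoter intervals keyed by `gene_id`.
#' @export
promoter_regions <- function(annotation, genome, upstream = 1000,
                             ignore_strand = FALSE) {
  if (upstream < 1) stop("upstream must be >= 1")
  if (!inherits(genome, "Genome")) stop("genome must be a Genome object")
  len <- setNames(genome$length, genome$chrom)
  unknown <- setdiff(annotation$chrom, genome$chrom)
  if (length(unknown))
    stop("gene chromosome(s) not in genome: ",
         paste(unknown, collapse = ", "))
  plus <- ignore_strand | annotation$strand == "+"
  start <- ifelse(plus, pmax(0, annotation$start - upstream),
                  annotation$end)
  end <- ifelse(plus, annotation$start,
                pmin(len[annotation$chrom], annotation$end + upstream))
  out <- data.frame(gene_id = annotation$gene_id,
                    chrom = annotation$chrom,
                    start = start, end = end,
                    strand = annotation$strand, stringsAsFactors = FALSE)
  empty <- out$start >= out$end
  if (any(empty)) {
    warning(sum(empty), " gene(s) dropped: empty promoter after clamping (",
            paste(head(out$gene_id[empty], 5), collapse = ", "), ")")
    out <- out[!empty, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Classify promoters as open or closed under a peak set
#'
#' A promoter is open when it overlaps the merged peaks by at least
#' `min_overlap` bases.
#'
#' @param promoters A [promoter_regions()] result.
#' @param peaks A [peak_set()].
#' @param min_overlap Minimum shared bases (default 1).
#' @return Data.frame of gene_id, promoter coordinates and logical `open`.
#' @export
classify_promoters <- function(promoters, peaks, min_overlap = 1) {
  if (min_overlap < 1) stop("min_overlap must be >= 1")
  validate_intervals(promoters, what = "promoter")
  validate_intervals(peaks)
  open <- overlap_flags(promoters, peaks, min_overlap)
  cbind(promoters[, c("gene_id", "chrom", "start", "end")], open = open)
}

#' Expression summary by promoter accessibility pattern
#'
#' Genes are grouped by their open/closed pattern across several peak sets
#' and each group's expression is summarised per sample.
#'
#' @param calls Named list of [classify_promoters()] results, one per peak
#'   set (names are the peak-set labels).
#' @param expr An expression table (`gene_id` plus one numeric column per
#'   sample, see [read_expression_table()]).
#' @return List with `summary` (one row per pattern x sample: pattern,
#'   sample, n, mean, median), `patterns` (per-gene pattern table) and
#'   `n_missing_expression` (genes with calls but no expression value).
#' @export
accessibility_expression_summary <- function(calls, expr) {
  if (!length(calls)) stop("no promoter calls given")
  if (is.null(names(calls)) || any(!nzchar(names(calls))))
    stop("calls must be a named list (one name per peak set)")
  ids <- calls[[1]]$gene_id
  for (cl in calls)
    if (!identical(cl$gene_id, ids))
      stop("all call sets must cover the same genes in the same order")
  status <- vapply(calls, `[[`, logical(length(ids)), "open")
  status <- matrix(status, nrow = length(ids),
                   dimnames = list(NULL, names(calls)))
  pattern <- apply(status, 1L, function(row)
    paste(ifelse(row, "open", "closed"), collapse = "/"))
  genes <- data.frame(gene_id = ids, pattern = pattern,
                      stringsAsFactors = FALSE)

  shared <- intersect(ids, expr$gene_id)
  if (!length(shared))
    stop("no genes shared between promoter calls and expression table")
  n_missing <- length(setdiff(ids, expr$gene_id))
  e <- expr[match(shared, expr$gene_id), , drop = FALSE]
  pat <- genes$pattern[match(shared, genes$gene_id)]
  samples <- names(expr)[-1]
  rows <- lapply(samples, function(s) {
    agg_n <- tapply(e[[s]], pat, length)
    data.frame(pattern = names(agg_n), sample = s,
               n = as.integer(agg_n),
               mean = as.numeric(tapply(e[[s]], pat, mean)),
               median = as.numeric(tapply(e[[s]], pat, median)),
               stringsAsFactors = FALSE)
  })
  list(summary = do.call(rbind, rows), patterns = genes,
       n_missing_expression = n_missing)
}
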