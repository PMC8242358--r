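## BED-family readers and writer.
##
## Supported dialects (all tab-separated, 0-based half-open):
##   bed3        chrom start end
##   bed6        chrom start end [name [score [strand]]]
##   broadPeak   9 columns  (ENCODE; col 7 signalValue, 8 pValue, 9 qValue)
##   narrowPeak  10 columns (broadPeak + summit offset)
##   gappedPeak  15 columns (BED12 + signalValue, pValue, qValue)
## The score defaults to BED column 5; callers with other score semantics
## (e.g. HMMRATAC's fold-change in gappedPeak column 13) are handled via
## `score_column`.

.format_ncols <- c(bed3 = 3L, bed6 = 6L, narrowPeak = 10L,
                   broadPeak = 9L, gappedPeak = 15L)

#' Read a BED-family peak file
#'
#' @param path Path to a tab-separated peak file.
#' @param format One of `"bed3"`, `"bed6"`, `"narrowPeak"`, `"broadPeak"`,
#'   `"gappedPeak"` or `"auto"` (sniff by column count).
#' @param score_column Optional 1-based column index to read scores from
#'   (default: column 5 when present).
#' @param label Library label for the returned set (default: file name).
#' @param genome Optional [genome()] used to validate coordinates.
#' @return A [peak_set()].
#' @export
read_peaks <- function(path, format = "auto", score_column = NULL,
                       label = basename(path), genome = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- match.arg(format,
                      c("auto", "bed3", "bed6", names(.format_ncols)))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L)
    return(peak_set(character(), numeric(), numeric(), label = label,
                    genome = genome))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)

  if (format == "auto") {
    format <- switch(as.character(nf[1]),
                     "3" = "bed3", "4" = "bed6", "5" = "bed6", "6" = "bed6",
                     "9" = "broadPeak", "10" = "narrowPeak",
                     "15" = "gappedPeak",
                     stop("cannot sniff format: line 1 has ", nf[1],
                          " columns"))
  }
  expected <- switch(format, bed3 = 3L, bed6 = nf[1], .format_ncols[[format]])
  if (format == "bed6" && !(expected %in% 3:6))
    stop("bed6 lines must have 3-6 columns, line 1 has ", expected)
  bad <- which(nf != expected)
  if (length(bad))
    stop("malformed line ", bad[1], " in ", path, ": expected ", expected,
         " tab-separated fields, found ", nf[bad[1]])

  mat <- matrix(unlist(fields), ncol = expected, byrow = TRUE)
  start <- suppressWarnings(as.numeric(mat[, 2]))
  end <- suppressWarnings(as.numeric(mat[, 3]))
  bad <- which(is.na(start) | is.na(end) | start < 0 | start != floor(start))
  if (length(bad))
    stop("malformed line ", bad[1], " in ", path,
         ": coordinates must be non-negative integers")
  bad <- which(start >= end)
  if (length(bad))
    stop("malformed line ", bad[1], " in ", path, ": start >= end")

  sc <- if (is.null(score_column)) 5L else as.integer(score_column)
  score <- if (sc <= expected) {
    s <- suppressWarnings(as.numeric(mat[, sc]))
    s[mat[, sc] == "."] <- NA_real_
    s
  } else NA_real_
  if (!is.null(score_column) && sc > expected)
    stop("score_column ", sc, " exceeds the ", expected, " columns of ", path)

  name <- if (expected >= 4) mat[, 4] else NA_character_
  name[name == "."] <- NA_character_
  strand <- if (expected >= 6) mat[, 6] else "."
  strand[!strand %in% c("+", "-")] <- "."
  peak_set(mat[, 1], start, end, name = name, score = score,
           strand = strand, label = label, genome = genome)
}

#' Write a peak set as BED6
#'
#' Output is sorted in canonical (chrom, start, end) order.  Missing names
#' and scores are written as `"."` and `0`; `read_peaks(write_bed(x))`
#' round-trips chrom/start/end/name/score/strand.
#'
#' @param peaks A [peak_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  validate_intervals(peaks)
  ord <- order(peaks$chrom, peaks$start, peaks$end)
  df <- as.data.frame(peaks)[ord, , drop = FALSE]
  out <- data.frame(df$chrom, format(df$start, scientific = FALSE, trim = TRUE),
                    format(df$end, scientific = FALSE, trim = TRUE),
                    ifelse(is.na(df$name), ".", df$name),
                    ifelse(is.na(df$score), ".",
                           format(df$score, scientific = FALSE, trim = TRUE)),
                    df$strand)
  ok <- tryCatch({
    write.table(out, path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    TRUE
  }, error = function(e) stop("cannot write ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}
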