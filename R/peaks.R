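# ChIP-seq peak sets and BED input/output. BED is 0-based half-open, which is
# also the internal convention, so coordinates pass through unchanged. Peaks
# are unstranded; overlapping peaks are retained as-is (no merging).

#' Construct a peak set
#'
#' @param chrom,start,end vectors of peak coordinates (0-based half-open).
#' @param score non-negative numeric score per peak (default 0).
#' @param source_label free-text provenance label (e.g. cell line).
#' @return An object of class `peak_set`: a data frame with columns `chrom`,
#'   `start`, `end`, `score`, sorted by (chrom, start).
#' @export
peak_set <- function(chrom, start, end, score = 0, source_label = "") {
  if (length(chrom) == 1L && length(start) > 1L)
    chrom <- rep(chrom, length(start))
  if (length(score) == 1L) score <- rep(score, length(start))
  stopifnot(length(chrom) == length(start), length(start) == length(end),
            length(score) == length(chrom))
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) && (any(start < 0) || any(end <= start)))
    stopf("peak intervals must satisfy 0 <= start < end")
  if (length(score) && (any(!is.finite(score)) || any(score < 0)))
    stopf("peak scores must be finite and non-negative")
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   score = as.numeric(score), stringsAsFactors = FALSE)
  df <- df[order(df$chrom, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("peak_set", "data.frame"),
            source_label = source_label)
}

#' Read a BED3+ peak file
#'
#' Columns beyond the third are optional; if a 5th column is present it is
#' taken as the score (BED5 convention), otherwise scores are 0.
#'
#' @param path BED file path.
#' @param source_label provenance label attached to the result.
#' @return A [peak_set].
#' @export
read_bed <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) stopf("BED file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  if (!any(keep)) return(peak_set(character(0), integer(0), integer(0),
                                  source_label = source_label))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3L))
    stopf("BED parse error at line %d: fewer than 3 fields", which(keep)[which(nf < 3L)[1L]])
  chrom <- vapply(fields, `[`, character(1), 1L)
  start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2L)))
  end   <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3L)))
  if (anyNA(start) || anyNA(end))
    stopf("BED parse error: non-numeric coordinate at line %d",
          which(keep)[which(is.na(start) | is.na(end))[1L]])
  score <- rep(0, length(chrom))
  has5 <- nf >= 5L
  if (any(has5)) {
    s5 <- suppressWarnings(as.numeric(vapply(fields[has5], `[`, character(1), 5L)))
    if (anyNA(s5)) stopf("BED parse error: non-numeric score")
    score[has5] <- s5
  }
  peak_set(chrom, start, end, score, source_label = source_label)
}

#' Write a peak set as BED5
#'
#' @param peaks a [peak_set].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "peak_set"))
  lines <- sprintf("%s\t%d\t%d\tpeak_%d\t%s", peaks$chrom, peaks$start,
                   peaks$end, seq_len(nrow(peaks)),
                   format(peaks$score, trim = TRUE, scientific = FALSE))
  writeLines(lines, path)
  invisible(path)
}
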