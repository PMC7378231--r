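# Expression matrices, sample sheets, and RPKM normalization.
#
# An expression matrix is a plain numeric matrix (genes x samples) with
# rownames = gene_ids, colnames = sample_ids and an attribute `unit` of
# "count" or "rpkm". RPKM = count * 1e9 / (exonic length in bp * library
# size), i.e. reads per kilobase of exon per million mapped reads.

#' Read a sample sheet
#'
#' @param path TSV with header columns `sample_id`, `group`, `library_size`.
#' @param groups optional character vector of allowed group labels; any other
#'   label is an error.
#' @return Data frame with columns `sample_id`, `group`, `library_size`.
#' @export
read_sample_sheet <- function(path, groups = NULL) {
  if (!file.exists(path)) stopf("sample sheet not found: %s", path)
  sheet <- read_tsv(path)
  need <- c("sample_id", "group", "library_size")
  if (!all(need %in% names(sheet)))
    stopf("sample sheet must have columns: %s", paste(need, collapse = ", "))
  sample_sheet(sheet$sample_id, sheet$group, sheet$library_size, groups)
}

#' Construct a sample sheet
#'
#' @param sample_id,group character vectors; `group` assigns each sample to a
#'   tissue group or cell-line condition.
#' @param library_size positive integer total mapped reads per sample.
#' @param groups optional declared set of allowed group labels.
#' @return Data frame with one row per sample.
#' @export
sample_sheet <- function(sample_id, group, library_size, groups = NULL) {
  if (anyDuplicated(sample_id))
    stopf("duplicated sample_id in sample sheet")
  library_size <- as.numeric(library_size)
  if (any(!is.finite(library_size)) || any(library_size <= 0))
    stopf("library sizes must be positive")
  if (!is.null(groups)) {
    bad <- setdiff(unique(group), groups)
    if (length(bad)) stopf("unknown group label(s): %s", paste(bad, collapse = ", "))
  }
  data.frame(sample_id = as.character(sample_id), group = as.character(group),
             library_size = library_size, stringsAsFactors = FALSE)
}

expr_unit <- function(m) attr(m, "unit")

expr_matrix <- function(values, unit = c("count", "rpkm")) {
  unit <- match.arg(unit)
  if (any(!is.finite(values)) || any(values < 0))
    stopf("expression values must be finite and non-negative")
  attr(values, "unit") <- unit
  values
}

#' Read a count (or RPKM) matrix aligned to a sample sheet
#'
#' @param path TSV whose first column is `gene_id` and whose remaining header
#'   names are sample ids. Every file sample must appear in the sheet and
#'   vice versa; columns are reordered to the sheet order.
#' @param sheet a [sample_sheet] data frame.
#' @param unit `"count"` (default) or `"rpkm"`.
#' @return Numeric matrix (genes x samples) with attribute `unit`.
#' @export
read_matrix <- function(path, sheet, unit = "count") {
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  tab <- read_tsv(path)
  if (names(tab)[1L] != "gene_id")
    stopf("matrix first column must be 'gene_id', found '%s'", names(tab)[1L])
  gene_id <- as.character(tab$gene_id)
  if (anyDuplicated(gene_id))
    stopf("duplicated gene_id in matrix: %s",
          paste(unique(gene_id[duplicated(gene_id)]), collapse = ", "))
  samples_in_file <- names(tab)[-1L]
  extra <- setdiff(samples_in_file, sheet$sample_id)
  if (length(extra))
    stopf("sample(s) in matrix absent from sample sheet: %s",
          paste(extra, collapse = ", "))
  missing <- setdiff(sheet$sample_id, samples_in_file)
  if (length(missing))
    stopf("sample(s) in sheet missing from matrix: %s",
          paste(missing, collapse = ", "))
  m <- as.matrix(tab[, sheet$sample_id, drop = FALSE])
  if (!is.numeric(m) || anyNA(m) || any(!is.finite(m)) || any(m < 0))
    stopf("matrix cells must be finite non-negative numbers")
  rownames(m) <- gene_id
  expr_matrix(m, unit)
}

#' Write an expression matrix as TSV
#'
#' @param m matrix with rownames (gene ids) and colnames (sample ids).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv(df, path)
}

#' Normalize counts to RPKM
#'
#' RPKM\[g, s\] = count\[g, s\] * 1e9 / (exonic length of g in bp *
#' library size of s). Exonic length is the sum of exon widths from the gene
#' model; library sizes come from the sample sheet.
#'
#' @param counts count matrix from [read_matrix()] (unit `"count"`).
#' @param models a [gene_models] object covering every matrix gene.
#' @param sheet a [sample_sheet] covering every matrix sample.
#' @return Matrix of the same shape with attribute `unit = "rpkm"`.
#' @examples
#' # count 50 on a 2 kb gene in a 10 M-read library -> RPKM 2.5
#' @export
compute_rpkm <- function(counts, models, sheet) {
  if (!identical(expr_unit(counts), "count"))
    stopf("compute_rpkm expects a matrix with unit 'count'")
  missing <- setdiff(rownames(counts), models$genes$gene_id)
  if (length(missing))
    stopf("gene(s) without a model: %s", paste(missing, collapse = ", "))
  ls <- sheet$library_size[match(colnames(counts), sheet$sample_id)]
  if (anyNA(ls)) stopf("sample(s) missing from sheet: %s",
                       paste(colnames(counts)[is.na(ls)], collapse = ", "))
  if (any(ls <= 0)) stopf("library sizes must be positive")
  len <- models$genes$exon_bp[match(rownames(counts), models$genes$gene_id)]
  if (any(len <= 0)) stopf("gene exonic length must be positive")
  rpkm <- counts * 1e9 / (len %o% ls)
  expr_matrix(unclass_matrix(rpkm), "rpkm")
}

unclass_matrix <- function(m) {
  attributes(m) <- attributes(m)[c("dim", "dimnames")]
  m
}

group_means <- function(m, sheet, group) {
  cols <- sheet$sample_id[sheet$group == group]
  if (!length(cols)) stopf("no samples in group '%s'", group)
  rowMeans(m[, cols, drop = FALSE])
}
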