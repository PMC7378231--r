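# Gene models and GTF input/output.
#
# Internal coordinates are 0-based half-open everywhere in the package; GTF
# (1-based inclusive) is converted on read and write. The transcription start
# site (TSS) is strand-aware: `start` on "+", `end - 1` on "-".

#' Construct a set of gene models
#'
#' @param genes data frame with columns `gene_id`, `name`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand` (`+` or `-`), `biotype`
#'   (`coding`/`noncoding`), `database` (`RefSeq`/`GENCODE`/`NONCODE`).
#' @param exons data frame with columns `gene_id`, `start`, `end`; every exon
#'   must lie within its gene, exons of one gene must be non-overlapping.
#' @return An object of class `gene_models`: a list with validated, sorted
#'   `genes` (with derived `tss` and `exon_bp` columns) and `exons` tables.
#' @export
gene_models <- function(genes, exons) {
  need_g <- c("gene_id", "name", "chrom", "start", "end", "strand",
              "biotype", "database")
  if (!all(need_g %in% names(genes)))
    stopf("genes is missing columns: %s",
          paste(setdiff(need_g, names(genes)), collapse = ", "))
  need_e <- c("gene_id", "start", "end")
  if (!all(need_e %in% names(exons)))
    stopf("exons is missing columns: %s",
          paste(setdiff(need_e, names(exons)), collapse = ", "))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  exons <- as.data.frame(exons, stringsAsFactors = FALSE)

  if (anyDuplicated(genes$gene_id))
    stopf("duplicated gene_id: %s",
          paste(unique(genes$gene_id[duplicated(genes$gene_id)]), collapse = ", "))
  if (!all(genes$strand %in% c("+", "-")))
    stopf("gene strand must be '+' or '-'")
  bad_bt <- setdiff(unique(genes$biotype), GENE_BIOTYPES)
  if (length(bad_bt)) stopf("unknown biotype: %s", paste(bad_bt, collapse = ", "))
  bad_db <- setdiff(unique(genes$database), GENE_DATABASES)
  if (length(bad_db)) stopf("unknown database: %s", paste(bad_db, collapse = ", "))
  if (any(genes$start < 0) || any(genes$end <= genes$start))
    stopf("gene intervals must satisfy 0 <= start < end")
  if (any(exons$start < 0) || any(exons$end <= exons$start))
    stopf("exon intervals must satisfy 0 <= start < end")
  orphan <- setdiff(exons$gene_id, genes$gene_id)
  if (length(orphan)) stopf("exons reference unknown genes: %s",
                            paste(unique(orphan), collapse = ", "))
  if (!all(genes$gene_id %in% exons$gene_id))
    stopf("genes without exons: %s",
          paste(setdiff(genes$gene_id, exons$gene_id), collapse = ", "))

  # sort exons within gene; check containment and non-overlap
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ,
                 drop = FALSE]
  g_start <- genes$start[match(exons$gene_id, genes$gene_id)]
  g_end   <- genes$end[match(exons$gene_id, genes$gene_id)]
  out_of_gene <- exons$start < g_start | exons$end > g_end
  if (any(out_of_gene))
    stopf("exon outside its gene: %s",
          paste(unique(exons$gene_id[out_of_gene]), collapse = ", "))
  by_gene <- split(seq_len(nrow(exons)), exons$gene_id)
  for (ix in by_gene) {
    if (length(ix) > 1L) {
      s <- exons$start[ix]; e <- exons$end[ix]
      if (any(s[-1L] < e[-length(e)]))
        stopf("overlapping exons in gene %s", exons$gene_id[ix[1L]])
    }
  }

  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  bp <- tapply(exons$end - exons$start, exons$gene_id, sum)
  genes$exon_bp <- as.integer(bp[genes$gene_id])

  ord <- order(genes$chrom, genes$start, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  exons <- exons[order(match(exons$gene_id, genes$gene_id), exons$start), ,
                 drop = FALSE]
  rownames(genes) <- NULL
  rownames(exons) <- NULL
  exons$chrom  <- genes$chrom[match(exons$gene_id, genes$gene_id)]
  exons$strand <- genes$strand[match(exons$gene_id, genes$gene_id)]
  exons <- exons[, c("gene_id", "chrom", "start", "end", "strand")]
  structure(list(genes = genes, exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes (%d coding, %d noncoding), %d exons\n",
              nrow(x$genes), sum(x$genes$biotype == "coding"),
              sum(x$genes$biotype == "noncoding"), nrow(x$exons)))
  invisible(x)
}

parse_gtf_attr <- function(attr, key, lineno, required = TRUE) {
  m <- regmatches(attr, regexec(paste0(key, ' "([^"]*)"'), attr))
  val <- vapply(m, function(z) if (length(z) == 2L) z[2L] else NA_character_,
                character(1))
  if (required && anyNA(val))
    stopf("GTF parse error at line %d: missing attribute '%s'",
          lineno[which(is.na(val))[1L]], key)
  val
}

#' Read gene models from GTF
#'
#' Expects `gene` and `exon` features (other feature types are ignored) with
#' attributes `gene_id`, `gene_name`, `biotype` (`coding`/`noncoding`) and
#' `database` (`RefSeq`/`GENCODE`/`NONCODE`). GTF 1-based inclusive
#' coordinates are converted to the internal 0-based half-open convention.
#'
#' @param path GTF file path.
#' @return A [gene_models] object, sorted by (chrom, start, gene_id).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stopf("GTF file not found: %s", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  lineno <- which(keep)
  if (!length(lineno)) stopf("GTF file %s has no feature lines", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stopf("GTF parse error at line %d: expected 9 tab-separated fields, got %d",
          lineno[which(nf != 9L)[1L]], nf[which(nf != 9L)[1L]])
  tab <- do.call(rbind, fields)
  feature <- tab[, 3L]
  sel <- feature %in% c("gene", "exon")
  tab <- tab[sel, , drop = FALSE]
  lineno <- lineno[sel]
  start1 <- suppressWarnings(as.integer(tab[, 4L]))
  end1   <- suppressWarnings(as.integer(tab[, 5L]))
  bad <- is.na(start1) | is.na(end1) | start1 < 1L | end1 < start1
  if (any(bad))
    stopf("GTF parse error at line %d: invalid coordinates '%s'-'%s'",
          lineno[which(bad)[1L]], tab[which(bad)[1L], 4L], tab[which(bad)[1L], 5L])
  gene_id <- parse_gtf_attr(tab[, 9L], "gene_id", lineno)

  is_gene <- tab[, 3L] == "gene"
  gl <- which(is_gene)
  genes <- data.frame(
    gene_id = gene_id[gl],
    name = parse_gtf_attr(tab[gl, 9L], "gene_name", lineno[gl]),
    chrom = tab[gl, 1L],
    start = start1[gl] - 1L,
    end = end1[gl],
    strand = tab[gl, 7L],
    biotype = parse_gtf_attr(tab[gl, 9L], "biotype", lineno[gl]),
    database = parse_gtf_attr(tab[gl, 9L], "database", lineno[gl]),
    stringsAsFactors = FALSE)
  exons <- data.frame(
    gene_id = gene_id[!is_gene],
    start = start1[!is_gene] - 1L,
    end = end1[!is_gene],
    stringsAsFactors = FALSE)
  gene_models(genes, exons)
}

#' Write gene models to GTF
#'
#' Inverse of [read_gtf()]: emits one `gene` line followed by its `exon`
#' lines, converting internal 0-based half-open coordinates back to GTF
#' 1-based inclusive. `write_gtf` then `read_gtf` round-trips to an
#' identical object, and re-writing reproduces the file byte for byte.
#'
#' @param models a [gene_models] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(models, path) {
  stopifnot(inherits(models, "gene_models"))
  g <- models$genes
  e <- models$exons
  attr_str <- sprintf('gene_id "%s"; gene_name "%s"; biotype "%s"; database "%s";',
                      g$gene_id, g$name, g$biotype, g$database)
  gene_lines <- sprintf("%s\tcrpclnc\tgene\t%d\t%d\t.\t%s\t.\t%s",
                        g$chrom, g$start + 1L, g$end, g$strand, attr_str)
  ix <- match(e$gene_id, g$gene_id)
  exon_lines <- sprintf("%s\tcrpclnc\texon\t%d\t%d\t.\t%s\t.\t%s",
                        e$chrom, e$start + 1L, e$end, e$strand, attr_str[ix])
  # interleave: gene line, then its exons, in stored order
  out <- character(0)
  exon_by_gene <- split(exon_lines, factor(e$gene_id, levels = g$gene_id))
  out <- unlist(mapply(function(gl, el) c(gl, el), gene_lines, exon_by_gene,
                       SIMPLIFY = FALSE, USE.NAMES = FALSE))
  writeLines(out, path)
  invisible(path)
}

# GRanges views used by the interval machinery --------------------------------

gene_body_granges <- function(models, subset = NULL) {
  g <- models$genes
  if (!is.null(subset)) g <- g[match(subset, g$gene_id), , drop = FALSE]
  GenomicRanges::GRanges(
    seqnames = g$chrom,
    ranges = IRanges::IRanges(start = g$start + 1L, end = g$end),
    strand = g$strand, gene_id = g$gene_id, biotype = g$biotype)
}

exon_granges <- function(models, subset = NULL) {
  e <- models$exons
  if (!is.null(subset)) e <- e[e$gene_id %in% subset, , drop = FALSE]
  GenomicRanges::GRanges(
    seqnames = e$chrom,
    ranges = IRanges::IRanges(start = e$start + 1L, end = e$end),
    strand = e$strand, gene_id = e$gene_id)
}
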