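# Curation of bona fide lncRNAs and genomic-context classification.
#
# Many database lncRNAs are composed of exons of protein-coding genes; with
# (even directional) RNA-seq those reads cannot be told apart from the coding
# transcript, so such candidates are excluded. Exclusion requires SAME-strand
# exonic overlap: with directional libraries an opposite-strand exon overlap
# is distinguishable and must not exclude. Kept candidates are classified by
# gene-body overlap with coding genes: antisense (opposite strand),
# intergenic (no overlap on either strand), or other (same-strand overlap
# without shared exons, i.e. sense/intronic/overlapping).

#' Curate lncRNA candidates and classify their genomic context
#'
#' @param candidates character vector of candidate gene ids; all must be
#'   `noncoding` in `models`.
#' @param models [gene_models] containing both the candidates and the
#'   protein-coding genes to compare against.
#' @param classes optional named vector (gene_id -> e.g. Type_A/Type_B) used
#'   only to break down the summary.
#' @param min_overlap_frac minimum fraction of a candidate exon that must be
#'   covered by a same-strand coding exon to trigger exclusion; the default 0
#'   excludes on any overlap of at least 1 bp.
#' @return List with `calls` (data frame: `gene_id`, `verdict`
#'   (`kept`/`excluded_exonic`), `context` (`antisense`/`intergenic`/`other`,
#'   `NA` when excluded), `evidence`) and `summary` (counts per verdict and
#'   context, split by `classes` when given).
#' @export
curate_all <- function(candidates, models, classes = NULL,
                       min_overlap_frac = 0) {
  g <- models$genes
  unknown <- setdiff(candidates, g$gene_id)
  if (length(unknown))
    stopf("unknown candidate gene(s): %s", paste(unknown, collapse = ", "))
  bt <- g$biotype[match(candidates, g$gene_id)]
  if (any(bt != "noncoding"))
    stopf("candidate(s) with coding biotype: %s",
          paste(candidates[bt != "noncoding"], collapse = ", "))

  coding_ids <- g$gene_id[g$biotype == "coding"]
  calls <- data.frame(gene_id = candidates,
                      verdict = rep("kept", length(candidates)),
                      context = rep("intergenic", length(candidates)),
                      evidence = rep("", length(candidates)),
                      stringsAsFactors = FALSE)
  if (!length(candidates)) {
    calls$context <- character(0)
    return(list(calls = calls, summary = curation_summary(calls, classes)))
  }

  if (length(coding_ids)) {
    cand_body <- gene_body_granges(models, candidates)
    cod_body <- gene_body_granges(models, coding_ids)

    # exclusion: same-strand exonic overlap
    cand_ex <- exon_granges(models, candidates)
    cod_ex <- exon_granges(models, coding_ids)
    exo <- GenomicRanges::findOverlaps(cand_ex, cod_ex, ignore.strand = FALSE)
    if (length(exo)) {
      ow <- GenomicRanges::width(GenomicRanges::pintersect(
        cand_ex[S4Vectors::queryHits(exo)], cod_ex[S4Vectors::subjectHits(exo)]))
      frac <- ow / GenomicRanges::width(cand_ex[S4Vectors::queryHits(exo)])
      hit <- ow >= 1L & frac >= min_overlap_frac
      excluded <- unique(cand_ex$gene_id[S4Vectors::queryHits(exo)[hit]])
      calls$verdict[calls$gene_id %in% excluded] <- "excluded_exonic"
    }

    # context from gene-body overlap, any strand
    bo <- GenomicRanges::findOverlaps(cand_body, cod_body, ignore.strand = TRUE)
    if (length(bo)) {
      qs <- S4Vectors::queryHits(bo); ss <- S4Vectors::subjectHits(bo)
      same <- as.character(GenomicRanges::strand(cand_body))[qs] ==
        as.character(GenomicRanges::strand(cod_body))[ss]
      ow <- GenomicRanges::width(GenomicRanges::pintersect(
        cand_body[qs], cod_body[ss], ignore.strand = TRUE))
      for (i in seq_along(candidates)) {
        mine <- which(qs == i)
        if (!length(mine)) next
        ctx <- if (any(!same[mine])) "antisense" else "other"
        calls$context[i] <- ctx
        rel <- ifelse(same[mine], "sense", "antisense")
        calls$evidence[i] <- paste(sprintf("%s(%s:%dbp)",
                                           cod_body$gene_id[ss[mine]],
                                           rel, ow[mine]), collapse = ";")
      }
    }
  }
  calls$context[calls$verdict == "excluded_exonic"] <- NA_character_
  list(calls = calls, summary = curation_summary(calls, classes))
}

curation_summary <- function(calls, classes = NULL) {
  out <- calls
  out$outcome <- ifelse(out$verdict == "excluded_exonic", "excluded_exonic",
                        out$context)
  if (!is.null(classes)) {
    out$class <- unname(classes[out$gene_id])
    agg <- as.data.frame(table(class = out$class, outcome = out$outcome),
                         stringsAsFactors = FALSE)
  } else {
    agg <- as.data.frame(table(outcome = out$outcome),
                         stringsAsFactors = FALSE)
  }
  names(agg)[names(agg) == "Freq"] <- "n"
  agg[agg$n > 0 | TRUE, , drop = FALSE]
}

#' Curate a single lncRNA candidate
#'
#' Convenience wrapper around [curate_all()] for one gene.
#'
#' @inheritParams curate_all
#' @param gene_id a single candidate gene id (must be `noncoding`).
#' @return One-row calls data frame (see [curate_all()]).
#' @export
curate_lnc <- function(gene_id, models, min_overlap_frac = 0) {
  stopifnot(length(gene_id) == 1L)
  curate_all(gene_id, models, min_overlap_frac = min_overlap_frac)$calls
}
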