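# Set-overlap chi-square tests, relative-expression (heatmap) tables, and
# the assembled pipeline summary.

#' Pearson chi-square test on a 2x2 contingency table
#'
#' @param tab 2x2 matrix of non-negative counts (rows: in/out of set 1,
#'   columns: in/out of set 2). All four marginals must be positive.
#' @param yates apply the Yates continuity correction (default `FALSE`; the
#'   uncorrected Pearson statistic is the package default).
#' @return List with `statistic`, `p_value`, `df` (always 1) and `expected`.
#' @examples
#' chisq_2x2(matrix(c(20, 10, 80, 90), 2))  # statistic ~ 3.9216
#' @export
chisq_2x2 <- function(tab, yates = FALSE) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L))) stopf("tab must be 2x2")
  if (any(tab < 0) || any(tab != round(tab)))
    stopf("cell counts must be non-negative integers")
  if (sum(tab) == 0) stopf("table total must be positive")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stopf("zero marginal: chi-square statistic undefined")
  res <- suppressWarnings(stats::chisq.test(tab, correct = yates))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value),
       df = 1L, expected = res$expected)
}

#' Chi-square enrichment test for the overlap of two gene sets
#'
#' Builds the 2x2 membership table of `set1` x `set2` over `universe` and
#' forwards it to [chisq_2x2()]. This is the generic operation behind
#' comparisons of, e.g., CRPC-upregulated genes against externally defined
#' up/down gene sets or AR-induced gene sets.
#'
#' @param universe character vector: the full gene universe.
#' @param set1,set2 character vectors, both subsets of `universe`.
#' @param yates passed to [chisq_2x2()].
#' @return List with `table` (2x2 matrix) plus the [chisq_2x2()] fields.
#' @export
overlap_test <- function(universe, set1, set2, yates = FALSE) {
  universe <- unique(universe)
  set1 <- unique(set1); set2 <- unique(set2)
  if (length(setdiff(set1, universe)) || length(setdiff(set2, universe)))
    stopf("set1 and set2 must be subsets of the universe")
  in1 <- universe %in% set1
  in2 <- universe %in% set2
  tab <- matrix(c(sum(in1 & in2), sum(!in1 & in2),
                  sum(in1 & !in2), sum(!in1 & !in2)),
                nrow = 2L,
                dimnames = list(set1 = c("in", "out"), set2 = c("in", "out")))
  c(list(table = tab), chisq_2x2(tab, yates = yates))
}

#' Per-sample log2 expression relative to the benign-group mean
#'
#' Entry (g, s) = log2((rpkm\[g, s\] + eps) / (mean benign RPKM of g + eps)).
#' Columns are ordered benign, then the remaining groups in sheet order; a
#' gene at its benign mean maps to 0 and an all-zero gene to 0 everywhere.
#' This is the presentation-layer table behind relative-expression heatmaps.
#'
#' @param rpkm RPKM matrix.
#' @param sheet [sample_sheet]; must contain the benign group.
#' @param pseudocount symmetric pseudocount `eps`.
#' @param benign_label group label of the reference (benign) samples.
#' @return Numeric matrix with an attribute `groups` giving each column's
#'   group label.
#' @export
heatmap_table <- function(rpkm, sheet, pseudocount = 0.01,
                          benign_label = "benign") {
  if (!any(sheet$group == benign_label))
    stopf("benign group '%s' missing from sample sheet", benign_label)
  bmean <- group_means(rpkm, sheet, benign_label)
  ord <- order(sheet$group != benign_label,
               match(sheet$group, unique(sheet$group)))
  samples <- sheet$sample_id[ord]
  m <- log2((rpkm[, samples, drop = FALSE] + pseudocount) /
              (bmean + pseudocount))
  attr(m, "groups") <- sheet$group[ord]
  m
}

#' Assemble the pipeline summary
#'
#' Collects the stage counts of the discovery funnel into one table:
#' genes passing the expression filter, Type_A, Type_B, curated lncRNAs,
#' regulated lncRNAs, and candidates bound within the lncRNA window. Counts
#' along the funnel are non-increasing by construction.
#'
#' @param classification [classify_genes()] output.
#' @param curation `calls` data frame from [curate_all()].
#' @param funnel [crpc_lnc_funnel()] output.
#' @return Data frame with columns `stage` and `n`.
#' @export
assemble_report <- function(classification, curation, funnel) {
  if (length(setdiff(curation$gene_id, classification$gene_id)))
    stopf("curation covers genes absent from the classification")
  data.frame(
    stage = c("genes_tested", "passed_expression_filter", "Type_A", "Type_B",
              "lnc_candidates", "curated_lnc", "regulated_lnc",
              "bound_within_window"),
    n = c(nrow(classification),
          sum(classification$passed_filter),
          sum(classification$class == "Type_A"),
          sum(classification$class == "Type_B"),
          nrow(curation),
          funnel$stages$n[funnel$stages$stage == "curated"],
          funnel$stages$n[funnel$stages$stage == "regulated"],
          funnel$stages$n[funnel$stages$stage == "bound_within_window"]),
    stringsAsFactors = FALSE)
}
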