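# Type_A / Type_B classification of CRPC-upregulated genes.
#
# A gene first has to pass the "highly expressed in CRPC" filter: mean RPKM
# over CRPC samples above the per-database cutoff (RefSeq 5, GENCODE 1,
# NONCODE 1). Among filtered genes,
#   Type_A: significantly up in CRPC vs localized prostate cancer AND vs
#           benign prostate (both Mann-Whitney p < alpha, direction up);
#   Type_B: significantly up in CRPC vs benign only, with Type_A removed.
# Everything else is unclassified. p-values are nominal by default (no
# multiple-testing correction), reproducing the published criterion; a
# Benjamini-Hochberg option is available behind `adjust = "BH"`.

#' Classify genes as Type_A / Type_B by CRPC up-regulation
#'
#' @param rpkm RPKM matrix (genes x samples, unit `"rpkm"`).
#' @param sheet [sample_sheet] assigning each sample to one of the three
#'   tissue groups; each group needs at least 2 samples.
#' @param models [gene_models] supplying each gene's source database.
#' @param thresholds a [crpc_thresholds] object.
#' @param groups named character vector mapping the canonical roles
#'   `benign`, `pca`, `crpc` to the labels used in `sheet`.
#' @param adjust `"none"` (default, the published criterion) or `"BH"` to
#'   Benjamini-Hochberg-adjust each comparison's p-values across genes
#'   before thresholding.
#' @return Data frame with one row per gene: `gene_id`, `class`
#'   (`Type_A`/`Type_B`/`unclassified`), `passed_filter`, per-group mean
#'   RPKM, and p-value + direction for CRPC vs Pca and CRPC vs benign.
#' @export
classify_genes <- function(rpkm, sheet, models, thresholds = crpc_thresholds(),
                           groups = c(benign = "benign", pca = "pca",
                                      crpc = "crpc"),
                           adjust = c("none", "BH")) {
  adjust <- match.arg(adjust)
  if (!identical(expr_unit(rpkm), "rpkm"))
    stopf("classify_genes expects a matrix with unit 'rpkm'")
  for (role in c("benign", "pca", "crpc")) {
    nsamp <- sum(sheet$group == groups[[role]])
    if (nsamp < 2L)
      stopf("group '%s' has %d samples; need at least 2", groups[[role]], nsamp)
  }
  gid <- rownames(rpkm)
  db <- models$genes$database[match(gid, models$genes$gene_id)]
  if (anyNA(db))
    stopf("gene(s) without a model: %s", paste(gid[is.na(db)], collapse = ", "))

  cols <- lapply(groups, function(gl) sheet$sample_id[sheet$group == gl])
  m_ben  <- rowMeans(rpkm[, cols$benign, drop = FALSE])
  m_pca  <- rowMeans(rpkm[, cols$pca, drop = FALSE])
  m_crpc <- rowMeans(rpkm[, cols$crpc, drop = FALSE])
  passed <- m_crpc > thresholds$rpkm_min[db]

  test_vs <- function(other_cols) {
    res <- lapply(seq_along(gid), function(i)
      mann_whitney(rpkm[i, cols$crpc], rpkm[i, other_cols]))
    list(p = vapply(res, `[[`, numeric(1), "p_value"),
         dir = vapply(res, `[[`, character(1), "direction"))
  }
  vs_pca <- test_vs(cols$pca)
  vs_ben <- test_vs(cols$benign)
  p_pca <- vs_pca$p; p_ben <- vs_ben$p
  if (adjust == "BH") {
    p_pca <- stats::p.adjust(p_pca, method = "BH")
    p_ben <- stats::p.adjust(p_ben, method = "BH")
  }

  alpha <- thresholds$alpha
  sig_pca <- p_pca < alpha & vs_pca$dir == "up"
  sig_ben <- p_ben < alpha & vs_ben$dir == "up"
  klass <- rep("unclassified", length(gid))
  klass[passed & sig_pca & sig_ben] <- "Type_A"
  klass[passed & sig_ben & klass != "Type_A"] <- "Type_B"

  data.frame(gene_id = gid, class = klass, passed_filter = passed,
             mean_rpkm_benign = m_ben, mean_rpkm_pca = m_pca,
             mean_rpkm_crpc = m_crpc,
             p_crpc_vs_pca = p_pca, dir_crpc_vs_pca = vs_pca$dir,
             p_crpc_vs_benign = p_ben, dir_crpc_vs_benign = vs_ben$dir,
             row.names = NULL, stringsAsFactors = FALSE)
}
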