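#' Analysis thresholds
#'
#' Bundles every cutoff used across the pipeline. The defaults reproduce the
#' study design: highly-expressed filters of RPKM > 5 for RefSeq genes and
#' RPKM > 1 for GENCODE/NONCODE genes (evaluated on the CRPC group mean),
#' nominal significance at alpha = 0.05 with no multiple-testing correction,
#' a 50 kb peak-to-TSS window for AR-target calling in protein-coding genes,
#' a 10 kb window for lncRNA candidate selection, and fold-change cutoffs of
#' > 1.5 (induced) and < 0.8 (repressed), applied strictly.
#'
#' @param rpkm_min named numeric vector of per-database expression filters
#'   (mean RPKM over CRPC samples must exceed the value for the gene's
#'   source database).
#' @param alpha significance level for the Mann-Whitney tests.
#' @param window_target_bp peak-to-TSS window (bp) for AR-target calling.
#' @param window_lnc_bp peak-to-TSS window (bp) for lncRNA candidates.
#' @param fold_induced fold-change above which a gene is called induced.
#' @param fold_repressed fold-change below which a gene is called repressed.
#' @param pseudocount added to both numerator and denominator of fold
#'   changes so that fold(0, 0) = 1.
#' @return An object of class `crpc_thresholds` (a validated list).
#' @examples
#' th <- crpc_thresholds()
#' th$rpkm_min[["RefSeq"]]
#' @export
crpc_thresholds <- function(rpkm_min = c(RefSeq = 5, GENCODE = 1, NONCODE = 1),
                            alpha = 0.05,
                            window_target_bp = 50000L,
                            window_lnc_bp = 10000L,
                            fold_induced = 1.5,
                            fold_repressed = 0.8,
                            pseudocount = 0.01) {
  if (!all(c("RefSeq", "GENCODE", "NONCODE") %in% names(rpkm_min)))
    stopf("rpkm_min must be named for RefSeq, GENCODE and NONCODE")
  if (any(!is.finite(rpkm_min)) || any(rpkm_min <= 0))
    stopf("rpkm_min values must be positive and finite")
  if (!(alpha > 0 && alpha < 1)) stopf("alpha must lie in (0, 1)")
  if (window_target_bp <= 0 || window_lnc_bp <= 0)
    stopf("windows must be positive")
  if (!(fold_repressed < 1 && 1 < fold_induced))
    stopf("fold thresholds must satisfy fold_repressed < 1 < fold_induced")
  if (pseudocount <= 0) stopf("pseudocount must be positive")
  structure(list(rpkm_min = rpkm_min, alpha = alpha,
                 window_target_bp = as.integer(window_target_bp),
                 window_lnc_bp = as.integer(window_lnc_bp),
                 fold_induced = fold_induced, fold_repressed = fold_repressed,
                 pseudocount = pseudocount),
            class = "crpc_thresholds")
}

GENE_DATABASES <- c("RefSeq", "GENCODE", "NONCODE")
GENE_BIOTYPES  <- c("coding", "noncoding")
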