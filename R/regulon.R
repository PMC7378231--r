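# AR regulon integration: peak-to-TSS assignment, androgen/siAR regulation
# calls, AR-target gene sets, and the CRPC lncRNA candidate funnel.
#
# Peak-to-gene distance is interval-to-point: 0 when the TSS lies inside the
# peak, otherwise the distance from the TSS to the nearer peak edge. By
# default a peak is assigned only to its closest-TSS gene(s) (ties keep all),
# and a gene is "bound" when an assigned peak lies within the window; set
# `closest_only = FALSE` for a plain within-window criterion.

peak_tss_distance <- function(p_start, p_end, tss) {
  pmax(p_start - tss, tss - (p_end - 1L), 0L)
}

#' Assign ChIP-seq peaks to genes by TSS proximity
#'
#' @param peaks a [peak_set].
#' @param models a [gene_models] object (at least one gene).
#' @param window_bp maximum peak-to-TSS distance (bp) for a binding call.
#' @param closest_only if `TRUE` (default) each peak counts only for its
#'   closest-TSS gene(s); if `FALSE` every gene with a peak within the
#'   window is bound.
#' @return Data frame with one row per gene: `gene_id`, `bound`,
#'   `nearest_peak_distance` (bp; `NA` when no peak is assigned),
#'   `n_supporting` and `supporting_peaks` (list column of row indices into
#'   `peaks`), plus the `window_bp` used.
#' @export
assign_peaks <- function(peaks, models, window_bp, closest_only = TRUE) {
  stopifnot(inherits(peaks, "peak_set"))
  g <- models$genes
  if (!nrow(g)) stopf("assign_peaks needs at least one gene")
  if (window_bp <= 0) stopf("window_bp must be positive")

  nearest <- rep(NA_integer_, nrow(g))
  support <- vector("list", nrow(g))
  for (i in seq_along(support)) support[[i]] <- integer(0)

  if (nrow(peaks)) {
    for (chrom in unique(peaks$chrom)) {
      gi <- which(g$chrom == chrom)
      if (!length(gi)) next
      pi <- which(peaks$chrom == chrom)
      # D[p, g]: interval-to-TSS distance
      D <- pmax(outer(peaks$start[pi], g$tss[gi], `-`),
                outer(-(peaks$end[pi] - 1L), g$tss[gi], `+`))
      D[D < 0L] <- 0L
      if (closest_only) {
        pmin_d <- apply(D, 1L, min)
        for (k in seq_along(pi)) {
          hit <- gi[D[k, ] == pmin_d[k]]
          for (h in hit) {
            d <- pmin_d[k]
            if (is.na(nearest[h]) || d < nearest[h]) nearest[h] <- d
            if (d <= window_bp) support[[h]] <- c(support[[h]], pi[k])
          }
        }
      } else {
        gmin <- apply(D, 2L, min)
        nearest[gi] <- ifelse(is.na(nearest[gi]), gmin, pmin(nearest[gi], gmin))
        for (j in seq_along(gi)) {
          within <- pi[D[, j] <= window_bp]
          support[[gi[j]]] <- c(support[[gi[j]]], within)
        }
      }
    }
  }
  n_sup <- lengths(support)
  out <- data.frame(gene_id = g$gene_id,
                    bound = n_sup > 0L,
                    nearest_peak_distance = nearest,
                    n_supporting = n_sup,
                    window_bp = as.integer(window_bp),
                    stringsAsFactors = FALSE)
  out$supporting_peaks <- support
  out
}

#' Call androgen/AR regulation from a two-condition experiment
#'
#' Fold change is `(mean(treated) + eps) / (mean(control) + eps)` on RPKM,
#' with the pseudocount `eps` keeping fold(0, 0) = 1. For the DHT contrast
#' (treated = DHT, control = vehicle), fold > `fold_induced` means
#' androgen-induced and fold < `fold_repressed` androgen-repressed. For the
#' siAR contrast (treated = siAR, control = siControl) the reading inverts:
#' fold < `fold_repressed` marks an AR-induced gene (knockdown lowers it) and
#' fold > `fold_induced` an AR-repressed gene. In both cases the reported
#' `call` states the gene's relation to androgen/AR activity: `"induced"`
#' (positively regulated), `"repressed"`, or `"unchanged"`. Thresholds are
#' strict inequalities.
#'
#' @param rpkm RPKM matrix for the cell-line experiment.
#' @param sheet [sample_sheet] whose groups are exactly the two condition
#'   labels of the contrast (`vehicle`/`DHT` or `siControl`/`siAR`).
#' @param contrast `"DHT_vs_vehicle"` or `"siAR_vs_siControl"`.
#' @param thresholds a [crpc_thresholds] object.
#' @param cell_line label recorded in the output.
#' @return Data frame: `gene_id`, `cell_line`, `contrast`, `fold`, `call`.
#' @export
call_regulation <- function(rpkm, sheet,
                            contrast = c("DHT_vs_vehicle", "siAR_vs_siControl"),
                            thresholds = crpc_thresholds(), cell_line = "") {
  contrast <- match.arg(contrast)
  if (!identical(expr_unit(rpkm), "rpkm"))
    stopf("call_regulation expects a matrix with unit 'rpkm'")
  labels <- if (contrast == "DHT_vs_vehicle") c("vehicle", "DHT")
            else c("siControl", "siAR")
  for (lab in labels)
    if (!any(sheet$group == lab))
      stopf("condition '%s' missing from sample sheet", lab)
  eps <- thresholds$pseudocount
  ctrl  <- group_means(rpkm, sheet, labels[1L])
  treat <- group_means(rpkm, sheet, labels[2L])
  fold <- (treat + eps) / (ctrl + eps)
  call <- rep("unchanged", length(fold))
  if (contrast == "DHT_vs_vehicle") {
    call[fold > thresholds$fold_induced]  <- "induced"
    call[fold < thresholds$fold_repressed] <- "repressed"
  } else {
    call[fold < thresholds$fold_repressed] <- "induced"
    call[fold > thresholds$fold_induced]  <- "repressed"
  }
  data.frame(gene_id = rownames(rpkm), cell_line = cell_line,
             contrast = contrast, fold = fold, call = call,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' AR-target gene sets per cell line
#'
#' A gene is an AR target in a cell line when it is AR-bound (peak within the
#' target window of its TSS) and its expression responds to the line's
#' contrast (call other than `"unchanged"`). Following the study's grouping,
#' the intersection of the two androgen-dependent lines (LNCaP, VCaP) is
#' reported alongside the CRPC-model line (22Rv1).
#'
#' @param binding named list of [assign_peaks()] results, one per cell line.
#' @param regulation named list of [call_regulation()] results with the same
#'   names and the same gene universe.
#' @return List with `per_line` (named list of gene-id vectors), and, when
#'   the respective lines are present, `LNCaP_VCaP` (intersection) and
#'   `R22Rv1` (the 22Rv1 set).
#' @export
ar_target_genes <- function(binding, regulation) {
  if (!identical(sort(names(binding)), sort(names(regulation))))
    stopf("binding and regulation must cover the same cell lines")
  universe <- sort(binding[[1L]]$gene_id)
  per_line <- lapply(names(binding), function(line) {
    b <- binding[[line]]; r <- regulation[[line]]
    if (!identical(sort(b$gene_id), universe) ||
        !identical(sort(r$gene_id), universe))
      stopf("gene universe mismatch in cell line %s", line)
    bound <- b$gene_id[b$bound]
    reg <- r$gene_id[r$call != "unchanged"]
    sort(intersect(bound, reg))
  })
  names(per_line) <- names(binding)
  out <- list(per_line = per_line)
  if (all(c("LNCaP", "VCaP") %in% names(per_line)))
    out$LNCaP_VCaP <- sort(intersect(per_line$LNCaP, per_line$VCaP))
  if ("22Rv1" %in% names(per_line))
    out$R22Rv1 <- per_line[["22Rv1"]]
  out
}

#' CRPC lncRNA candidate funnel
#'
#' Implements the staged candidate selection: curated CRPC-upregulated
#' lncRNAs -> the subset with any androgen/AR regulation call -> the subset
#' with AR binding within the lncRNA window (10 kb by default) of the TSS.
#' Stages are nested by construction.
#'
#' @param classification [classify_genes()] output.
#' @param curation [curate_all()] calls for the classified lncRNA candidates.
#' @param regulation named list of [call_regulation()] results (e.g. 22Rv1
#'   siAR plus the DHT lines); any call other than `"unchanged"` counts.
#' @param binding [assign_peaks()] result at the lncRNA window.
#' @param models [gene_models] used for location strings.
#' @return List with `stages` (data frame of stage names and counts) and
#'   `candidates` (final-stage table ranked by CRPC mean RPKM: location,
#'   annotation, per-group mean RPKM, per-line fold, nearest peak distance).
#' @export
crpc_lnc_funnel <- function(classification, curation, regulation, binding,
                            models) {
  curated <- curation$gene_id[curation$verdict == "kept"]
  curated <- intersect(curated,
                       classification$gene_id[classification$class %in%
                                              c("Type_A", "Type_B")])
  reg_any <- unique(unlist(lapply(regulation, function(r)
    r$gene_id[r$call != "unchanged"])))
  regulated <- intersect(curated, reg_any)
  bound <- intersect(regulated, binding$gene_id[binding$bound])

  stages <- data.frame(
    stage = c("curated", "regulated", "bound_within_window"),
    n = c(length(curated), length(regulated), length(bound)),
    stringsAsFactors = FALSE)

  g <- models$genes
  ci <- match(bound, classification$gene_id)
  gi <- match(bound, g$gene_id)
  candidates <- data.frame(
    gene_id = bound,
    location = sprintf("%s:%d-%d", g$chrom[gi], g$start[gi] + 1L, g$end[gi]),
    annotation = g$name[gi],
    class = classification$class[ci],
    context = curation$context[match(bound, curation$gene_id)],
    mean_rpkm_benign = classification$mean_rpkm_benign[ci],
    mean_rpkm_pca = classification$mean_rpkm_pca[ci],
    mean_rpkm_crpc = classification$mean_rpkm_crpc[ci],
    nearest_peak_distance =
      binding$nearest_peak_distance[match(bound, binding$gene_id)],
    stringsAsFactors = FALSE)
  for (line in names(regulation)) {
    r <- regulation[[line]]
    candidates[[paste0("fold_", line)]] <- r$fold[match(bound, r$gene_id)]
  }
  if (nrow(candidates)) {
    ord <- order(-candidates$mean_rpkm_crpc, candidates$gene_id)
    candidates <- cbind(rank = seq_len(nrow(candidates)),
                        candidates[ord, , drop = FALSE])
  }
  rownames(candidates) <- NULL
  list(stages = stages, candidates = candidates)
}
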