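# End-to-end discovery pipeline: quantify -> classify -> curate -> integrate
# -> report. Every intermediate is written as TSV to the output directory;
# analysis stages are deterministic (all randomness is confined to the
# simulate stage), so re-running on identical inputs gives byte-identical
# outputs. Any stage error aborts with the stage name and cause.

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stopf("%s stage failed: %s", stage, conditionMessage(e)))
}

require_files <- function(stage, paths) {
  missing <- paths[!file.exists(unlist(paths))]
  if (length(missing))
    stopf("%s stage failed: missing input file(s): %s", stage,
          paste(unlist(missing), collapse = ", "))
}

#' Map a simulated cohort directory to discovery-pipeline inputs
#'
#' @param dir directory written by [simulate_crpc_cohort()].
#' @return Input list suitable for [run_discover()].
#' @export
sim_inputs <- function(dir) {
  line_spec <- function(line, contrast)
    list(counts = file.path(dir, sprintf("cellline_%s_counts.tsv", line)),
         samples = file.path(dir, sprintf("cellline_%s_samples.tsv", line)),
         peaks = file.path(dir, sprintf("peaks_%s.bed", line)),
         contrast = contrast)
  list(gtf = file.path(dir, "annotation.gtf"),
       tissue_counts = file.path(dir, "tissue_counts.tsv"),
       tissue_samples = file.path(dir, "tissue_samples.tsv"),
       cell_lines = list(
         LNCaP = line_spec("LNCaP", "DHT_vs_vehicle"),
         VCaP = line_spec("VCaP", "DHT_vs_vehicle"),
         `22Rv1` = line_spec("22Rv1", "siAR_vs_siControl")))
}

#' Run the simulate stage
#'
#' Thin wrapper over [simulate_crpc_cohort()] matching the other `run_*`
#' entry points.
#'
#' @param config a [sim_config()].
#' @param out_dir fixture directory to create.
#' @return See [simulate_crpc_cohort()].
#' @export
run_simulate <- function(config, out_dir) {
  stage_try("simulate", simulate_crpc_cohort(config, out_dir))
}

#' Run the full discovery pipeline
#'
#' Executes quantify (RPKM), classify (Type_A/Type_B), curate (lncRNA
#' context), integrate (AR binding + regulation + candidate funnel) and
#' report, writing every intermediate TSV plus a JSON run manifest to
#' `out_dir`.
#'
#' @param inputs list with `gtf`, `tissue_counts`, `tissue_samples`, and
#'   `cell_lines` (named list; each element has `counts`, `samples`,
#'   `peaks`, `contrast`). See [sim_inputs()].
#' @param out_dir output directory (created if needed).
#' @param thresholds a [crpc_thresholds()].
#' @return Invisibly, a list with all in-memory stage results.
#' @export
run_discover <- function(inputs, out_dir, thresholds = crpc_thresholds()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  require_files("quantify", inputs[c("gtf", "tissue_counts", "tissue_samples")])
  quant <- stage_try("quantify", {
    models <- read_gtf(inputs$gtf)
    sheet <- read_sample_sheet(inputs$tissue_samples,
                               groups = c("benign", "pca", "crpc"))
    counts <- read_matrix(inputs$tissue_counts, sheet)
    rpkm <- compute_rpkm(counts, models, sheet)
    write_matrix(rpkm, file.path(out_dir, "tissue_rpkm.tsv"))
    list(models = models, sheet = sheet, rpkm = rpkm)
  })

  classification <- stage_try("classify", {
    cl <- classify_genes(quant$rpkm, quant$sheet, quant$models, thresholds)
    write_tsv(cl, file.path(out_dir, "classification.tsv"))
    cl
  })

  curation <- stage_try("curate", {
    g <- quant$models$genes
    cand <- classification$gene_id[
      classification$class %in% c("Type_A", "Type_B") &
        g$biotype[match(classification$gene_id, g$gene_id)] == "noncoding"]
    classes <- stats::setNames(classification$class, classification$gene_id)
    cu <- curate_all(cand, quant$models, classes = classes[cand])
    write_tsv(cu$calls, file.path(out_dir, "curation.tsv"))
    write_tsv(cu$summary, file.path(out_dir, "curation_summary.tsv"))
    cu
  })

  for (line in names(inputs$cell_lines))
    require_files("regulon", inputs$cell_lines[[line]][c("counts", "samples",
                                                         "peaks")])
  integration <- stage_try("regulon",
    run_integrate(quant$models, classification, curation$calls,
                  inputs$cell_lines, out_dir, thresholds))
  report <- stage_try("report", {
    summary <- assemble_report(classification, curation$calls,
                               integration$funnel)
    write_tsv(summary, file.path(out_dir, "summary.tsv"))
    manifest <- list(
      inputs = inputs,
      input_md5 = as.list(tools::md5sum(c(
        unlist(inputs[c("gtf", "tissue_counts", "tissue_samples")]),
        unlist(lapply(inputs$cell_lines, function(s)
          unlist(s[c("counts", "samples", "peaks")])))))),
      thresholds = unclass(thresholds),
      package_version = as.character(utils::packageVersion("crpclnc")))
    jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    summary
  })

  invisible(list(models = quant$models, rpkm = quant$rpkm,
                 classification = classification, curation = curation,
                 integration = integration, summary = report))
}

#' Run the integrate stage standalone
#'
#' AR binding, regulation calls, AR-target sets and the lncRNA funnel, given
#' the outputs of the classify and curate stages. [run_discover()] delegates
#' to this; it is exported so the stage can be re-run on prior results.
#'
#' @param models [gene_models].
#' @param classification [classify_genes()] output (or the TSV read back).
#' @param curation_calls `calls` from [curate_all()] (or the TSV read back).
#' @param cell_lines named list of per-line inputs (`counts`, `samples`,
#'   `peaks`, `contrast`), as in [sim_inputs()].
#' @param out_dir directory for the stage TSVs.
#' @param thresholds a [crpc_thresholds()].
#' @return List with `binding`, `regulation`, `targets`, `binding_lnc`,
#'   `funnel`.
#' @export
run_integrate <- function(models, classification, curation_calls, cell_lines,
                          out_dir, thresholds = crpc_thresholds()) {
    quant <- list(models = models)
    binding <- list(); regulation <- list(); peak_list <- list()
    for (line in names(cell_lines)) {
      spec <- cell_lines[[line]]
      peaks <- read_bed(spec$peaks, source_label = line)
      cond_labels <- if (spec$contrast == "DHT_vs_vehicle")
        c("vehicle", "DHT") else c("siControl", "siAR")
      sheet <- read_sample_sheet(spec$samples, groups = cond_labels)
      counts <- read_matrix(spec$counts, sheet)
      rpkm <- compute_rpkm(counts, quant$models, sheet)
      b <- assign_peaks(peaks, quant$models, thresholds$window_target_bp,
                        closest_only = TRUE)
      r <- call_regulation(rpkm, sheet, spec$contrast, thresholds,
                           cell_line = line)
      write_tsv(b[, setdiff(names(b), "supporting_peaks")],
                file.path(out_dir, sprintf("binding_%s.tsv", line)))
      write_tsv(r, file.path(out_dir, sprintf("regulation_%s.tsv", line)))
      binding[[line]] <- b
      regulation[[line]] <- r
      peak_list[[line]] <- as.data.frame(peaks)[, c("chrom", "start", "end",
                                                    "score")]
    }
    # AR-target calling is defined over protein-coding genes; lncRNA
    # candidates are handled by the 10 kb funnel below
    coding_ids <- quant$models$genes$gene_id[
      quant$models$genes$biotype == "coding"]
    targets <- ar_target_genes(
      lapply(binding, function(b) b[b$gene_id %in% coding_ids, ]),
      lapply(regulation, function(r) r[r$gene_id %in% coding_ids, ]))
    tdf <- do.call(rbind, lapply(names(targets$per_line), function(line)
      if (length(targets$per_line[[line]]))
        data.frame(set = line, gene_id = targets$per_line[[line]],
                   stringsAsFactors = FALSE)))
    if (is.null(tdf)) tdf <- data.frame(set = character(0),
                                        gene_id = character(0))
    if (!is.null(targets$LNCaP_VCaP) && length(targets$LNCaP_VCaP))
      tdf <- rbind(tdf, data.frame(set = "LNCaP_VCaP",
                                   gene_id = targets$LNCaP_VCaP,
                                   stringsAsFactors = FALSE))
    write_tsv(tdf, file.path(out_dir, "ar_targets.tsv"))

    all_peaks <- unique(do.call(rbind, peak_list))
    union_peaks <- peak_set(all_peaks$chrom, all_peaks$start, all_peaks$end,
                            all_peaks$score, source_label = "union")
    binding_lnc <- assign_peaks(union_peaks, quant$models,
                                thresholds$window_lnc_bp,
                                closest_only = FALSE)
    funnel <- crpc_lnc_funnel(classification, curation_calls, regulation,
                              binding_lnc, quant$models)
    write_tsv(funnel$stages, file.path(out_dir, "funnel_stages.tsv"))
    write_tsv(funnel$candidates, file.path(out_dir, "candidates.tsv"))
    list(binding = binding, regulation = regulation, targets = targets,
         binding_lnc = binding_lnc, funnel = funnel)
}
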