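# Seeded synthetic cohort generator with ground truth.
#
# Emulates the study design end to end: a three-group tissue cohort
# (benign n=6, localized prostate cancer n=8, CRPC n=6) with negative-
# binomial counts, cell-line condition experiments (LNCaP/VCaP
# vehicle-vs-DHT, 22Rv1 siControl-vs-siAR) with planted fold changes, AR
# ChIP-seq peaks planted at known TSS offsets, and an annotation containing
# coding genes, antisense and intergenic lncRNAs, and "exonic decoy"
# lncRNAs whose exons coincide with coding exons. Every planted property is
# recorded in a ground-truth manifest.
#
# In "complete" separation mode the generator rejection-samples each gene
# until its realized data respect the planted label exactly (separated
# ranks for up-genes, fold changes strictly past/inside the cutoffs, null
# genes confined to the bulk of the rank distribution), so a correct
# pipeline must recover every label. "noisy" mode draws once with no
# constraint and is the honest setting for error-rate measurements.
#
# Genomic layout: genes are placed left to right with per-gene clearances
# chosen so that a peak planted at up to `offset_outside` bp from its gene's
# TSS is closer to that TSS than to any other, and farther than the AR-target
# window from every other TSS. Decoy peaks live in a reserved gene-free zone
# at the end of chromosome 1, beyond the window from every TSS.

#' Simulation configuration
#'
#' See the package vignette for the rationale behind each default. Counts of
#' planted Type_A/Type_B/null genes, AR-bound and regulated genes, and
#' lncRNA context classes are all explicit so that recovery can be checked
#' against the emitted ground truth.
#'
#' @param seed integer RNG seed; identical seed + config gives byte-identical
#'   output files.
#' @param n_chroms,chrom_length_bp genome shape.
#' @param n_coding,n_lnc_antisense,n_lnc_intergenic,n_lnc_exonic_decoy gene
#'   counts per category.
#' @param group_sizes named integer vector (benign/pca/crpc tissue design).
#' @param n_type_a,n_type_b planted CRPC-upregulated coding genes (remaining
#'   coding genes are null). Exonic decoys are additionally planted Type_A so
#'   that the curation stage is exercised inside the classified set.
#' @param n_ar_target,n_bound_only,n_regulated_only planted coding AR biology:
#'   bound-and-regulated targets, bound-but-unregulated, and
#'   regulated-with-a-peak-outside-the-window genes.
#' @param n_lnc_type_a,n_lnc_type_b planted CRPC-upregulated lncRNAs (drawn
#'   intergenic-first so peak-bearing candidates are always classified).
#' @param n_lnc_regulated,n_lnc_bound,n_lnc_near_miss planted lncRNA funnel:
#'   regulated in 22Rv1; of those, bound within the lncRNA window / carrying
#'   a peak just outside it.
#' @param offset_inside_bp,offset_outside_bp planted peak-to-TSS offsets for
#'   coding genes (inside/outside the 50 kb AR-target window).
#' @param lnc_offset_inside_bp,lnc_offset_outside_bp same for lncRNA
#'   candidates relative to the 10 kb lncRNA window.
#' @param n_decoy_peaks peaks planted farther than the AR-target window from
#'   every TSS.
#' @param separation `"complete"` (guaranteed-recoverable labels) or
#'   `"noisy"` (unconstrained draws).
#' @param dispersion negative-binomial dispersion (1/size).
#' @param base_rpkm_range,lnc_base_rpkm_range uniform ranges for baseline
#'   expression (RPKM) of coding genes and lncRNAs.
#' @param fold_type_a,fold_type_b CRPC over baseline fold for planted genes.
#' @param fold_dht,fold_siar planted treated/control RPKM ratios for induced
#'   genes (DHT contrast) and AR-induced genes (siAR contrast); repressed
#'   genes use the reciprocal.
#' @param n_reps_cell replicates per cell-line condition.
#' @param library_size_range uniform range for per-sample library sizes.
#' @param thresholds [crpc_thresholds()] the planted design is calibrated to.
#' @param max_tries rejection-sampling cap per gene in `"complete"` mode.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L, chrom_length_bp = 12e6,
                       n_coding = 300L, n_lnc_antisense = 30L,
                       n_lnc_intergenic = 30L, n_lnc_exonic_decoy = 20L,
                       group_sizes = c(benign = 6L, pca = 8L, crpc = 6L),
                       n_type_a = 50L, n_type_b = 30L,
                       n_ar_target = 40L, n_bound_only = 10L,
                       n_regulated_only = 10L,
                       n_lnc_type_a = 12L, n_lnc_type_b = 9L,
                       n_lnc_regulated = 10L, n_lnc_bound = 6L,
                       n_lnc_near_miss = 2L,
                       offset_inside_bp = 49000L, offset_outside_bp = 51000L,
                       lnc_offset_inside_bp = 8000L,
                       lnc_offset_outside_bp = 15000L,
                       n_decoy_peaks = 10L,
                       separation = c("complete", "noisy"),
                       dispersion = 0.1,
                       base_rpkm_range = c(8, 40),
                       lnc_base_rpkm_range = c(3, 15),
                       fold_type_a = 6, fold_type_b = 6,
                       fold_dht = 2.5, fold_siar = 0.4,
                       n_reps_cell = 2L,
                       library_size_range = c(2e7, 3e7),
                       thresholds = crpc_thresholds(),
                       max_tries = 1000L) {
  separation <- match.arg(separation)
  cfg <- list(seed = as.integer(seed), n_chroms = as.integer(n_chroms),
              chrom_length_bp = as.numeric(chrom_length_bp),
              n_coding = n_coding, n_lnc_antisense = n_lnc_antisense,
              n_lnc_intergenic = n_lnc_intergenic,
              n_lnc_exonic_decoy = n_lnc_exonic_decoy,
              group_sizes = group_sizes,
              n_type_a = n_type_a, n_type_b = n_type_b,
              n_ar_target = n_ar_target, n_bound_only = n_bound_only,
              n_regulated_only = n_regulated_only,
              n_lnc_type_a = n_lnc_type_a, n_lnc_type_b = n_lnc_type_b,
              n_lnc_regulated = n_lnc_regulated, n_lnc_bound = n_lnc_bound,
              n_lnc_near_miss = n_lnc_near_miss,
              offset_inside_bp = offset_inside_bp,
              offset_outside_bp = offset_outside_bp,
              lnc_offset_inside_bp = lnc_offset_inside_bp,
              lnc_offset_outside_bp = lnc_offset_outside_bp,
              n_decoy_peaks = n_decoy_peaks, separation = separation,
              dispersion = dispersion, base_rpkm_range = base_rpkm_range,
              lnc_base_rpkm_range = lnc_base_rpkm_range,
              fold_type_a = fold_type_a, fold_type_b = fold_type_b,
              fold_dht = fold_dht, fold_siar = fold_siar,
              n_reps_cell = as.integer(n_reps_cell),
              library_size_range = library_size_range,
              thresholds = thresholds, max_tries = as.integer(max_tries))

  n_sparse_c <- n_ar_target + n_bound_only + n_regulated_only
  if (n_sparse_c > n_coding)
    stopf("peak-bearing coding genes (%d) exceed n_coding (%d)",
          n_sparse_c, n_coding)
  n_dense_c <- n_coding - n_sparse_c
  if (n_type_a + n_type_b > n_dense_c)
    stopf("planted Type_A + Type_B exceed available dense coding genes")
  if (n_lnc_antisense + n_lnc_exonic_decoy > n_dense_c)
    stopf("not enough coding host genes for antisense/decoy lncRNAs")
  if (n_lnc_type_a + n_lnc_type_b > n_lnc_antisense + n_lnc_intergenic)
    stopf("planted lncRNA classes exceed available lncRNAs")
  if (n_lnc_regulated > n_lnc_type_a + n_lnc_type_b)
    stopf("regulated lncRNAs must be drawn from classified lncRNAs")
  n_peak_lnc <- n_lnc_bound + n_lnc_near_miss
  if (n_peak_lnc > min(n_lnc_regulated, n_lnc_intergenic,
                       n_lnc_type_a + n_lnc_type_b))
    stopf("peak-bearing lncRNAs must be regulated, classified and intergenic")
  if (any(group_sizes < 2L)) stopf("each tissue group needs >= 2 samples")
  if (dispersion <= 0) stopf("dispersion must be positive")
  cfg$n_sparse_c <- n_sparse_c
  cfg$n_dense_c <- n_dense_c
  cfg$n_peak_lnc <- n_peak_lnc
  structure(cfg, class = "sim_config")
}

# non-overlapping exons tiling [0, span): odd segments of a 2k-1 stick-break
random_exon_layout <- function(span, k, min_seg = 60L) {
  while (k > 1L && span < (2L * k - 1L) * min_seg) k <- k - 1L
  if (k == 1L) return(data.frame(start = 0L, end = as.integer(span)))
  nseg <- 2L * k - 1L
  w <- stats::runif(nseg)
  seg <- min_seg + floor((span - nseg * min_seg) * w / sum(w))
  seg[nseg] <- span - sum(seg[-nseg])
  ends <- cumsum(seg)
  starts <- c(0, ends[-nseg])
  odd <- seq(1L, nseg, by = 2L)
  data.frame(start = as.integer(starts[odd]), end = as.integer(ends[odd]))
}

sim_place_genes <- function(cfg) {
  th <- cfg$thresholds
  clear_spc <- cfg$offset_outside_bp + th$window_target_bp + 5000L
  clear_spl <- cfg$lnc_offset_outside_bp + th$window_target_bp + 5000L
  clear_dense <- 7000L

  ent <- data.frame(
    type = c(rep("spc", cfg$n_sparse_c), rep("spl", cfg$n_peak_lnc),
             rep("dc", cfg$n_dense_c),
             rep("dli", cfg$n_lnc_intergenic - cfg$n_peak_lnc)),
    stringsAsFactors = FALSE)
  ent <- ent[sample.int(nrow(ent)), , drop = FALSE]
  ent$clear <- c(spc = clear_spc, spl = clear_spl, dc = clear_dense,
                 dli = clear_dense)[ent$type]
  ent$span <- ifelse(ent$type %in% c("spc", "dc"),
                     sample(2000:6000, nrow(ent), replace = TRUE),
                     sample(1000:4000, nrow(ent), replace = TRUE))

  zone_len <- 70000 + max(1L, cfg$n_decoy_peaks) * 2000
  usable <- rep(cfg$chrom_length_bp - 10000, cfg$n_chroms)
  usable[1L] <- usable[1L] - zone_len
  chrom <- integer(nrow(ent)); gstart <- numeric(nrow(ent))
  ci <- 1L; cursor <- 10000
  for (i in seq_len(nrow(ent))) {
    width <- 2 * ent$clear[i] + ent$span[i]
    while (cursor + width > usable[ci]) {
      ci <- ci + 1L
      if (ci > cfg$n_chroms)
        stopf("infeasible placement: chromosomes too short for %d genes",
              nrow(ent))
      cursor <- 10000
    }
    chrom[i] <- ci
    gstart[i] <- cursor + ent$clear[i]
    cursor <- gstart[i] + ent$span[i] + ent$clear[i]
  }
  ent$chrom <- paste0("chr", chrom)
  ent$start <- as.integer(gstart)
  ent$end <- ent$start + ent$span
  ent$strand <- sample(c("+", "-"), nrow(ent), replace = TRUE)
  ent
}

#' Simulate a synthetic CRPC cohort with ground truth
#'
#' Writes, under `out_dir`: `annotation.gtf`; `tissue_counts.tsv` +
#' `tissue_samples.tsv`; per cell line `cellline_<line>_counts.tsv`,
#' `cellline_<line>_samples.tsv` and `peaks_<line>.bed` (LNCaP, VCaP,
#' 22Rv1); and `ground_truth.tsv` (one row per gene: planted class, lncRNA
#' context, AR binding flag + planted TSS distance and the window it refers
#' to, and the planted regulation per cell line). After writing, every
#' emitted file is re-read with the package readers and all planted peak
#' distances are re-verified with an exhaustive peak-by-TSS scan.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @return Invisibly, a list with the file `paths`, the `ground_truth` data
#'   frame, and the [gene_models].
#' @export
simulate_crpc_cohort <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  th <- cfg$thresholds
  set.seed(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  ent <- sim_place_genes(cfg)

  # --- gene tables -----------------------------------------------------------
  idx <- function(type) which(ent$type == type)
  spc <- idx("spc"); spl <- idx("spl"); dc <- idx("dc"); dli <- idx("dli")
  mkid <- function(prefix, n) sprintf("%s%04d", prefix, seq_len(n))

  genes <- list(); exons <- list(); truth <- list()
  add_gene <- function(gene_id, chrom, start, end, strand, biotype, database,
                       exdf) {
    genes[[length(genes) + 1L]] <<- data.frame(
      gene_id = gene_id, name = toupper(gene_id), chrom = chrom,
      start = start, end = end, strand = strand, biotype = biotype,
      database = database, stringsAsFactors = FALSE)
    exons[[length(exons) + 1L]] <<- data.frame(
      gene_id = gene_id, start = exdf$start, end = exdf$end,
      stringsAsFactors = FALSE)
  }
  lnc_db <- function(n) sample(GENE_DATABASES, n, replace = TRUE,
                               prob = c(0.2, 0.4, 0.4))

  coding_ids <- mkid("gco", cfg$n_coding)
  spc_ids <- coding_ids[seq_along(spc)]
  dc_ids <- coding_ids[length(spc) + seq_along(dc)]
  for (j in seq_along(c(spc, dc))) {
    i <- c(spc, dc)[j]
    ex <- random_exon_layout(ent$span[i], sample(2:5, 1L))
    add_gene(coding_ids[j], ent$chrom[i], ent$start[i], ent$end[i],
             ent$strand[i], "coding", "RefSeq",
             data.frame(start = ent$start[i] + ex$start,
                        end = ent$start[i] + ex$end))
  }

  li_ids <- mkid("gli", cfg$n_lnc_intergenic)
  spl_ids <- li_ids[seq_along(spl)]
  dli_ids <- li_ids[length(spl) + seq_along(dli)]
  li_dbs <- lnc_db(cfg$n_lnc_intergenic)
  for (j in seq_along(c(spl, dli))) {
    i <- c(spl, dli)[j]
    ex <- random_exon_layout(ent$span[i], sample(1:3, 1L))
    add_gene(li_ids[j], ent$chrom[i], ent$start[i], ent$end[i],
             ent$strand[i], "noncoding", li_dbs[j],
             data.frame(start = ent$start[i] + ex$start,
                        end = ent$start[i] + ex$end))
  }

  # antisense + decoy lncRNAs live inside dense coding hosts
  hosts <- sample(dc, cfg$n_lnc_antisense + cfg$n_lnc_exonic_decoy)
  as_hosts <- hosts[seq_len(cfg$n_lnc_antisense)]
  dec_hosts <- hosts[cfg$n_lnc_antisense + seq_len(cfg$n_lnc_exonic_decoy)]
  as_ids <- mkid("gas", cfg$n_lnc_antisense)
  as_dbs <- lnc_db(cfg$n_lnc_antisense)
  for (j in seq_along(as_hosts)) {
    h <- as_hosts[j]
    off <- sample(100:800, 1L)
    len <- min(ent$span[h] - off - 100L, sample(800:2000, 1L))
    s <- ent$start[h] + off
    ex <- random_exon_layout(len, sample(1:2, 1L))
    add_gene(as_ids[j], ent$chrom[h], s, s + len,
             if (ent$strand[h] == "+") "-" else "+", "noncoding", as_dbs[j],
             data.frame(start = s + ex$start, end = s + ex$end))
  }
  dec_ids <- mkid("gex", cfg$n_lnc_exonic_decoy)
  dec_dbs <- lnc_db(cfg$n_lnc_exonic_decoy)
  host_id_of <- function(i) coding_ids[match(i, c(spc, dc))]
  for (j in seq_along(dec_hosts)) {
    h <- dec_hosts[j]
    hid <- host_id_of(h)
    hex <- exons[[match(hid, vapply(genes, function(g) g$gene_id[1L],
                                    character(1)))]]
    add_gene(dec_ids[j], ent$chrom[h], min(hex$start), max(hex$end),
             ent$strand[h], "noncoding", dec_dbs[j],
             data.frame(start = hex$start, end = hex$end))
  }

  gene_df <- do.call(rbind, genes)
  exon_df <- do.call(rbind, exons)
  models <- gene_models(gene_df, exon_df)

  # --- planted truth ---------------------------------------------------------
  all_ids <- gene_df$gene_id
  tr <- data.frame(gene_id = all_ids,
                   biotype = gene_df$biotype, database = gene_df$database,
                   true_class = "null", lnc_context = "coding",
                   ar_bound = FALSE, tss_peak_distance = NA_integer_,
                   window_bp = NA_integer_,
                   reg_LNCaP = "none", reg_VCaP = "none", reg_22Rv1 = "none",
                   stringsAsFactors = FALSE)
  rownames(tr) <- tr$gene_id
  tr[li_ids, "lnc_context"] <- "intergenic"
  tr[as_ids, "lnc_context"] <- "antisense"
  tr[dec_ids, "lnc_context"] <- "exonic_decoy"

  dc_shuffled <- sample(dc_ids)
  tr[dc_shuffled[seq_len(cfg$n_type_a)], "true_class"] <- "Type_A"
  tr[dc_shuffled[cfg$n_type_a + seq_len(cfg$n_type_b)], "true_class"] <- "Type_B"
  tr[dec_ids, "true_class"] <- "Type_A"

  # lncRNA classes: peak-bearing intergenic first, then the rest
  lnc_pool <- c(spl_ids, sample(c(dli_ids, as_ids)))
  n_cls <- cfg$n_lnc_type_a + cfg$n_lnc_type_b
  classed <- lnc_pool[seq_len(n_cls)]
  cls <- sample(c(rep("Type_A", cfg$n_lnc_type_a),
                  rep("Type_B", cfg$n_lnc_type_b)))
  tr[classed, "true_class"] <- cls

  # coding AR biology
  spc_shuffled <- sample(spc_ids)
  ar_ids <- spc_shuffled[seq_len(cfg$n_ar_target)]
  bonly_ids <- spc_shuffled[cfg$n_ar_target + seq_len(cfg$n_bound_only)]
  ronly_ids <- spc_shuffled[cfg$n_ar_target + cfg$n_bound_only +
                              seq_len(cfg$n_regulated_only)]
  dirs <- sample(c("induced", "repressed"), length(c(ar_ids, ronly_ids)),
                 replace = TRUE)
  reg_coding <- c(ar_ids, ronly_ids)
  tr[reg_coding, "reg_LNCaP"] <- dirs
  tr[reg_coding, "reg_VCaP"] <- dirs
  tr[reg_coding, "reg_22Rv1"] <- dirs
  tr[c(ar_ids, bonly_ids), "ar_bound"] <- TRUE
  tr[c(ar_ids, bonly_ids), "tss_peak_distance"] <- cfg$offset_inside_bp
  tr[ronly_ids, "tss_peak_distance"] <- cfg$offset_outside_bp
  tr[c(ar_ids, bonly_ids, ronly_ids), "window_bp"] <- th$window_target_bp

  # lncRNA funnel biology
  reg_lnc <- c(spl_ids, setdiff(classed, spl_ids))[seq_len(cfg$n_lnc_regulated)]
  tr[reg_lnc, "reg_22Rv1"] <- sample(c("induced", "repressed"),
                                     length(reg_lnc), replace = TRUE)
  spl_shuffled <- sample(spl_ids)
  lbound_ids <- spl_shuffled[seq_len(cfg$n_lnc_bound)]
  lmiss_ids <- spl_shuffled[cfg$n_lnc_bound + seq_len(cfg$n_lnc_near_miss)]
  tr[lbound_ids, "ar_bound"] <- TRUE
  tr[lbound_ids, "tss_peak_distance"] <- cfg$lnc_offset_inside_bp
  tr[lmiss_ids, "tss_peak_distance"] <- cfg$lnc_offset_outside_bp
  tr[c(lbound_ids, lmiss_ids), "window_bp"] <- th$window_lnc_bp

  # baseline expression
  is_coding <- gene_df$biotype == "coding"
  base <- numeric(length(all_ids))
  base[is_coding] <- stats::runif(sum(is_coding), cfg$base_rpkm_range[1L],
                                  cfg$base_rpkm_range[2L])
  base[!is_coding] <- stats::runif(sum(!is_coding),
                                   cfg$lnc_base_rpkm_range[1L],
                                   cfg$lnc_base_rpkm_range[2L])
  # decoys mirror coding expression scale so they pass RefSeq-level filters
  base[match(dec_ids, all_ids)] <- stats::runif(length(dec_ids),
                                                cfg$base_rpkm_range[1L],
                                                cfg$base_rpkm_range[2L])
  tr$base_rpkm <- round(base, 4)

  # --- peaks -----------------------------------------------------------------
  peak_rows <- list()
  add_peak <- function(gene_id, offset) {
    g <- models$genes[models$genes$gene_id == gene_id, ]
    side <- sample(c("up", "down"), 1L)
    w <- sample(200:1000, 1L)
    if (side == "down") {
      s <- g$tss + offset; e <- s + w
    } else {
      e <- g$tss - offset + 1L; s <- e - w
    }
    peak_rows[[length(peak_rows) + 1L]] <<- data.frame(
      chrom = g$chrom, start = s, end = e, score = sample(50:1000, 1L),
      gene_id = gene_id, offset = offset, decoy = FALSE,
      stringsAsFactors = FALSE)
  }
  for (gid in c(ar_ids, bonly_ids)) add_peak(gid, cfg$offset_inside_bp)
  for (gid in ronly_ids) add_peak(gid, cfg$offset_outside_bp)
  for (gid in lbound_ids) add_peak(gid, cfg$lnc_offset_inside_bp)
  for (gid in lmiss_ids) add_peak(gid, cfg$lnc_offset_outside_bp)
  if (cfg$n_decoy_peaks > 0L) {
    for (k in seq_len(cfg$n_decoy_peaks)) {
      s <- cfg$chrom_length_bp - cfg$n_decoy_peaks * 2000 + (k - 1L) * 2000
      peak_rows[[length(peak_rows) + 1L]] <- data.frame(
        chrom = "chr1", start = s, end = s + 500, score = sample(50:1000, 1L),
        gene_id = NA_character_, offset = NA_integer_, decoy = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  peak_df <- if (length(peak_rows)) do.call(rbind, peak_rows) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               score = numeric(0), gene_id = character(0),
               offset = integer(0), decoy = logical(0))
  peaks <- peak_set(peak_df$chrom, peak_df$start, peak_df$end, peak_df$score,
                    source_label = "simulated")

  # exhaustive verification of planted distances
  verify_planted_peaks(peak_df, models, th$window_target_bp)

  # --- expression ------------------------------------------------------------
  gs <- cfg$group_sizes
  tissue_sheet <- sample_sheet(
    c(sprintf("benign_%d", seq_len(gs[["benign"]])),
      sprintf("pca_%d", seq_len(gs[["pca"]])),
      sprintf("crpc_%d", seq_len(gs[["crpc"]]))),
    rep(c("benign", "pca", "crpc"), gs[c("benign", "pca", "crpc")]),
    round(stats::runif(sum(gs), cfg$library_size_range[1L],
                       cfg$library_size_range[2L])))
  counts <- sim_tissue_counts(cfg, models, tr, tissue_sheet)

  lines <- list(
    LNCaP = list(contrast = "DHT_vs_vehicle", labels = c("vehicle", "DHT")),
    VCaP = list(contrast = "DHT_vs_vehicle", labels = c("vehicle", "DHT")),
    `22Rv1` = list(contrast = "siAR_vs_siControl",
                   labels = c("siControl", "siAR")))
  cell <- lapply(names(lines), function(line) {
    lab <- lines[[line]]$labels
    sheet <- sample_sheet(
      sprintf("%s_%s_%d", line, rep(lab, each = cfg$n_reps_cell),
              rep(seq_len(cfg$n_reps_cell), 2L)),
      rep(lab, each = cfg$n_reps_cell),
      round(stats::runif(2L * cfg$n_reps_cell, cfg$library_size_range[1L],
                         cfg$library_size_range[2L])))
    m <- sim_cellline_counts(cfg, models, tr, sheet, line,
                             lines[[line]]$contrast)
    list(sheet = sheet, counts = m)
  })
  names(cell) <- names(lines)

  # --- write -----------------------------------------------------------------
  paths <- list(
    gtf = file.path(out_dir, "annotation.gtf"),
    tissue_counts = file.path(out_dir, "tissue_counts.tsv"),
    tissue_samples = file.path(out_dir, "tissue_samples.tsv"),
    ground_truth = file.path(out_dir, "ground_truth.tsv"))
  write_gtf(models, paths$gtf)
  write_matrix(counts, paths$tissue_counts)
  write_tsv(tissue_sheet, paths$tissue_samples)
  for (line in names(cell)) {
    paths[[paste0("counts_", line)]] <-
      file.path(out_dir, sprintf("cellline_%s_counts.tsv", line))
    paths[[paste0("samples_", line)]] <-
      file.path(out_dir, sprintf("cellline_%s_samples.tsv", line))
    paths[[paste0("peaks_", line)]] <-
      file.path(out_dir, sprintf("peaks_%s.bed", line))
    write_matrix(cell[[line]]$counts, paths[[paste0("counts_", line)]])
    write_tsv(cell[[line]]$sheet, paths[[paste0("samples_", line)]])
    write_bed(peaks, paths[[paste0("peaks_", line)]])
  }
  truth_out <- tr[match(models$genes$gene_id, tr$gene_id), ]
  rownames(truth_out) <- NULL
  write_tsv(truth_out, paths$ground_truth)

  # emitted files must parse with the package readers
  reread <- read_gtf(paths$gtf)
  stopifnot(identical(reread$genes$gene_id, models$genes$gene_id))
  invisible(list(paths = paths, ground_truth = truth_out, models = models,
                 config = cfg))
}

verify_planted_peaks <- function(peak_df, models, window_bp) {
  if (!nrow(peak_df)) return(invisible(TRUE))
  tss <- models$genes$tss
  chrom <- models$genes$chrom
  for (k in seq_len(nrow(peak_df))) {
    on_chrom <- chrom == peak_df$chrom[k]
    d <- peak_tss_distance(peak_df$start[k], peak_df$end[k], tss[on_chrom])
    if (peak_df$decoy[k]) {
      if (length(d) && min(d) <= window_bp)
        stopf("generation error: decoy peak within %d bp of a TSS", window_bp)
    } else {
      own <- models$genes$gene_id[on_chrom] == peak_df$gene_id[k]
      if (d[own] != peak_df$offset[k])
        stopf("generation error: planted peak distance %d != offset %d",
              d[own], peak_df$offset[k])
      if (min(d) != d[own])
        stopf("generation error: planted peak closer to a foreign TSS")
    }
  }
  invisible(TRUE)
}

nb_counts <- function(mu, dispersion) {
  stats::rnbinom(length(mu), size = 1 / dispersion, mu = mu)
}

sim_tissue_counts <- function(cfg, models, tr, sheet) {
  th <- cfg$thresholds
  gs <- sheet$group
  lib <- sheet$library_size
  len_kb <- models$genes$exon_bp[match(tr$gene_id, models$genes$gene_id)] / 1000
  ben <- gs == "benign"; pca <- gs == "pca"; crpc <- gs == "crpc"
  m <- matrix(0L, nrow = nrow(tr), ncol = nrow(sheet),
              dimnames = list(tr$gene_id, sheet$sample_id))
  for (i in seq_len(nrow(tr))) {
    fold <- switch(tr$true_class[i], Type_A = cfg$fold_type_a,
                   Type_B = cfg$fold_type_b, 1)
    mu_rpkm <- rep(tr$base_rpkm[i], nrow(sheet))
    if (tr$true_class[i] == "Type_A") mu_rpkm[crpc] <- tr$base_rpkm[i] * fold
    if (tr$true_class[i] == "Type_B") mu_rpkm[crpc | pca] <- tr$base_rpkm[i] * fold
    mu <- mu_rpkm * len_kb[i] * lib / 1e6
    thr <- th$rpkm_min[[tr$database[i]]]
    for (try in seq_len(cfg$max_tries)) {
      cnt <- nb_counts(mu, cfg$dispersion)
      if (cfg$separation == "noisy") break
      rpkm <- cnt * 1e9 / (len_kb[i] * 1000 * lib)
      ok <- switch(
        tr$true_class[i],
        Type_A = min(rpkm[crpc]) > max(rpkm[ben | pca]) &&
          mean(rpkm[crpc]) > thr,
        Type_B = min(rpkm[crpc]) > max(rpkm[ben]) &&
          stats::median(rpkm[crpc]) <= stats::median(rpkm[pca]) &&
          mean(rpkm[crpc]) > thr,
        { # null: neither comparison may reach a significant "up" call
          t1 <- mann_whitney(rpkm[crpc], rpkm[pca])
          t2 <- mann_whitney(rpkm[crpc], rpkm[ben])
          !(t1$p_value < th$alpha && t1$direction == "up") &&
            !(t2$p_value < th$alpha && t2$direction == "up")
        })
      if (ok) break
      if (try == cfg$max_tries)
        stopf("generation error: could not satisfy separation for gene %s",
              tr$gene_id[i])
    }
    m[i, ] <- cnt
  }
  m
}

sim_cellline_counts <- function(cfg, models, tr, sheet, line, contrast) {
  th <- cfg$thresholds
  reg <- tr[[if (line == "22Rv1") "reg_22Rv1" else paste0("reg_", line)]]
  lib <- sheet$library_size
  treated_lab <- if (contrast == "DHT_vs_vehicle") "DHT" else "siAR"
  treated <- sheet$group == treated_lab
  len_kb <- models$genes$exon_bp[match(tr$gene_id, models$genes$gene_id)] / 1000
  m <- matrix(0L, nrow = nrow(tr), ncol = nrow(sheet),
              dimnames = list(tr$gene_id, sheet$sample_id))
  eps <- th$pseudocount
  for (i in seq_len(nrow(tr))) {
    fold <- if (contrast == "DHT_vs_vehicle") {
      switch(reg[i], induced = cfg$fold_dht, repressed = 1 / cfg$fold_dht, 1)
    } else {
      # siAR knockdown: AR-induced genes drop, AR-repressed genes rise
      switch(reg[i], induced = cfg$fold_siar, repressed = 1 / cfg$fold_siar, 1)
    }
    mu_rpkm <- rep(tr$base_rpkm[i], nrow(sheet))
    mu_rpkm[treated] <- tr$base_rpkm[i] * fold
    mu <- mu_rpkm * len_kb[i] * lib / 1e6
    for (try in seq_len(cfg$max_tries)) {
      cnt <- nb_counts(mu, cfg$dispersion)
      if (cfg$separation == "noisy") break
      rpkm <- cnt * 1e9 / (len_kb[i] * 1000 * lib)
      f <- (mean(rpkm[treated]) + eps) / (mean(rpkm[!treated]) + eps)
      want_high <- (contrast == "DHT_vs_vehicle" && reg[i] == "induced") ||
        (contrast == "siAR_vs_siControl" && reg[i] == "repressed")
      want_low <- (contrast == "DHT_vs_vehicle" && reg[i] == "repressed") ||
        (contrast == "siAR_vs_siControl" && reg[i] == "induced")
      ok <- if (want_high) f > th$fold_induced
            else if (want_low) f < th$fold_repressed
            else f >= th$fold_repressed && f <= th$fold_induced
      if (ok) break
      if (try == cfg$max_tries)
        stopf("generation error: could not satisfy fold for gene %s in %s",
              tr$gene_id[i], line)
    }
    m[i, ] <- cnt
  }
  m
}

#' Load a ground-truth manifest
#'
#' @param path `ground_truth.tsv` written by [simulate_crpc_cohort()].
#' @param models optional [gene_models]; when given, the manifest must cover
#'   exactly the same genes.
#' @return Data frame with one row per gene.
#' @export
load_ground_truth <- function(path, models = NULL) {
  if (!file.exists(path)) stopf("ground-truth manifest not found: %s", path)
  tr <- read_tsv(path)
  need <- c("gene_id", "biotype", "database", "true_class", "lnc_context",
            "ar_bound", "tss_peak_distance", "window_bp",
            "reg_LNCaP", "reg_VCaP", "reg_22Rv1")
  if (!all(need %in% names(tr)))
    stopf("manifest is missing columns: %s",
          paste(setdiff(need, names(tr)), collapse = ", "))
  if (!is.null(models)) {
    if (!setequal(tr$gene_id, models$genes$gene_id) ||
        nrow(tr) != nrow(models$genes))
      stopf("manifest genes do not match the annotation")
  }
  tr
}
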