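# Independent oracles and small fixture builders shared across tests.

# Brute-force two-sided Mann-Whitney p by full enumeration of all
# choose(n1+n2, n1) group assignments over midranks.
bf_mw_p <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  w_obs <- sum(r[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  combos <- utils::combn(n, n1)
  w_all <- colSums(matrix(r[combos], nrow = n1))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Exhaustive peak x gene scan: per-gene bound flag under both assignment
# conventions.
bf_assign <- function(peaks, models, window_bp, closest_only = TRUE) {
  g <- models$genes
  np <- nrow(peaks); ng <- nrow(g)
  D <- matrix(Inf, np, ng)
  for (p in seq_len(np)) for (j in seq_len(ng)) {
    if (peaks$chrom[p] != g$chrom[j]) next
    tss <- g$tss[j]
    D[p, j] <- if (tss >= peaks$start[p] && tss < peaks$end[p]) 0 else
      min(abs(peaks$start[p] - tss), abs(peaks$end[p] - 1 - tss))
  }
  bound <- rep(FALSE, ng)
  for (p in seq_len(np)) {
    if (all(is.infinite(D[p, ]))) next
    cand <- if (closest_only) which(D[p, ] == min(D[p, ])) else seq_len(ng)
    for (j in cand) if (D[p, j] <= window_bp) bound[j] <- TRUE
  }
  stats::setNames(bound, g$gene_id)
}

# Compact gene_models builder: one row per gene, exons as "s-e,s-e" strings
# (0-based half-open); defaults to a single exon spanning the gene.
toy_models <- function(df) {
  ex <- lapply(seq_len(nrow(df)), function(i) {
    spec <- if (!is.null(df$exons) && nzchar(df$exons[i])) df$exons[i] else
      sprintf("%d-%d", df$start[i], df$end[i])
    parts <- strsplit(strsplit(spec, ",")[[1]], "-")
    data.frame(gene_id = df$gene_id[i],
               start = as.integer(vapply(parts, `[`, character(1), 1L)),
               end = as.integer(vapply(parts, `[`, character(1), 2L)))
  })
  genes <- df[, c("gene_id", "chrom", "start", "end", "strand")]
  genes$name <- if (is.null(df$name)) toupper(df$gene_id) else df$name
  genes$biotype <- if (is.null(df$biotype)) "coding" else df$biotype
  genes$database <- if (is.null(df$database)) "RefSeq" else df$database
  gene_models(genes, do.call(rbind, ex))
}

# Small, fast simulation config reused by several tests.
quick_cfg <- function(seed = 42, chrom_length_bp = 8e6, ...) {
  sim_config(seed = seed, n_coding = 60, n_lnc_antisense = 8,
             n_lnc_intergenic = 8, n_lnc_exonic_decoy = 5,
             n_type_a = 10, n_type_b = 6, n_ar_target = 8, n_bound_only = 3,
             n_regulated_only = 3, n_lnc_type_a = 5, n_lnc_type_b = 3,
             n_lnc_regulated = 5, n_lnc_bound = 3, n_lnc_near_miss = 1,
             n_decoy_peaks = 4, chrom_length_bp = chrom_length_bp, ...)
}

# Shared quick fixture: simulated once per test run, reused read-only.
quick_sim_dir <- local({
  dir <- NULL
  function() {
    if (is.null(dir) || !file.exists(file.path(dir, "ground_truth.tsv"))) {
      dir <<- file.path(tempdir(), "crpclnc-quick-sim")
      unlink(dir, recursive = TRUE)
      simulate_crpc_cohort(quick_cfg(), dir)
    }
    dir
  }
})
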