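test_that("identical seed and config give byte-identical fixtures", {
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_crpc_cohort(quick_cfg(), d1)
  simulate_crpc_cohort(quick_cfg(), d2)
  f <- list.files(d1)
  expect_identical(f, list.files(d2))
  h1 <- unname(tools::md5sum(file.path(d1, f)))
  h2 <- unname(tools::md5sum(file.path(d2, f)))
  expect_identical(h1, h2)
})

test_that("complete separation holds for every planted up-gene", {
  sim <- quick_sim_dir()
  models <- read_gtf(file.path(sim, "annotation.gtf"))
  sheet <- read_sample_sheet(file.path(sim, "tissue_samples.tsv"))
  rpkm <- compute_rpkm(read_matrix(file.path(sim, "tissue_counts.tsv"), sheet),
                       models, sheet)
  tr <- load_ground_truth(file.path(sim, "ground_truth.tsv"), models)
  crpc <- sheet$sample_id[sheet$group == "crpc"]
  ben <- sheet$sample_id[sheet$group == "benign"]
  pca <- sheet$sample_id[sheet$group == "pca"]
  for (id in tr$gene_id[tr$true_class == "Type_A"])
    expect_gt(min(rpkm[id, crpc]), max(rpkm[id, c(ben, pca)]), label = id)
  for (id in tr$gene_id[tr$true_class == "Type_B"])
    expect_gt(min(rpkm[id, crpc]), max(rpkm[id, ben]), label = id)
})

test_that("planted peak offsets survive an exhaustive nearest-TSS scan", {
  sim <- quick_sim_dir()
  models <- read_gtf(file.path(sim, "annotation.gtf"))
  peaks <- read_bed(file.path(sim, "peaks_22Rv1.bed"))
  tr <- load_ground_truth(file.path(sim, "ground_truth.tsv"))
  g <- models$genes
  planted <- tr[!is.na(tr$tss_peak_distance), ]
  for (i in seq_len(nrow(planted))) {
    gi <- g[g$gene_id == planted$gene_id[i], ]
    d <- rep(Inf, nrow(peaks))
    for (p in seq_len(nrow(peaks))) {
      if (peaks$chrom[p] != gi$chrom) next
      d[p] <- if (gi$tss >= peaks$start[p] && gi$tss < peaks$end[p]) 0 else
        min(abs(peaks$start[p] - gi$tss), abs(peaks$end[p] - 1 - gi$tss))
    }
    expect_equal(min(d), planted$tss_peak_distance[i],
                 label = planted$gene_id[i])
  }
})

test_that("ground truth loads back and covers the annotation exactly", {
  sim <- quick_sim_dir()
  models <- read_gtf(file.path(sim, "annotation.gtf"))
  tr <- load_ground_truth(file.path(sim, "ground_truth.tsv"), models)
  expect_equal(nrow(tr), nrow(models$genes))
  expect_true(all(tr$true_class %in% c("Type_A", "Type_B", "null")))
  expect_true(all(tr$lnc_context %in%
                    c("antisense", "intergenic", "exonic_decoy", "coding")))
  # classes planted disjointly: one class per gene by construction
  expect_equal(anyDuplicated(tr$gene_id), 0L)
  truncated <- tr[-1, ]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tsv(truncated, path)
  expect_error(load_ground_truth(path, models), "match")
})

test_that("infeasible placements and inconsistent plants are rejected", {
  expect_error(sim_config(n_type_a = 500), "Type_A")
  expect_error(sim_config(n_lnc_bound = 40), "regulated")
  expect_error(simulate_crpc_cohort(quick_cfg(chrom_length_bp = 3e5),
                                    withr::local_tempdir()),
               "infeasible placement")
})

test_that("emitted count files parse as valid count matrices", {
  sim <- quick_sim_dir()
  for (line in c("LNCaP", "VCaP", "22Rv1")) {
    sheet <- read_sample_sheet(
      file.path(sim, sprintf("cellline_%s_samples.tsv", line)))
    m <- read_matrix(file.path(sim, sprintf("cellline_%s_counts.tsv", line)),
                     sheet)
    expect_true(all(m == round(m)))
    expect_equal(attr(m, "unit"), "count")
  }
})
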