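test_that("peak-to-TSS distance follows the interval-to-point convention", {
  models <- toy_models(data.frame(gene_id = "g1", chrom = "chr1",
                                  start = 100000L, end = 105000L,
                                  strand = "+"))
  inside <- peak_set("chr1", 149000L, 150500L)
  b <- assign_peaks(inside, models, window_bp = 50000L)
  expect_true(b$bound)
  expect_equal(b$nearest_peak_distance, 49000L)

  outside <- peak_set("chr1", 151000L, 152000L)
  b2 <- assign_peaks(outside, models, window_bp = 50000L)
  expect_false(b2$bound)
  expect_equal(b2$nearest_peak_distance, 51000L)

  covering <- peak_set("chr1", 99000L, 101000L)  # TSS inside the peak
  b3 <- assign_peaks(covering, models, window_bp = 50000L)
  expect_equal(b3$nearest_peak_distance, 0L)
})

test_that("assign_peaks matches the exhaustive oracle in both modes", {
  set.seed(21)
  for (i in 1:60) {
    ng <- sample(3:12, 1); np <- sample(2:15, 1)
    start <- sample.int(5e5, ng)
    models <- toy_models(data.frame(
      gene_id = sprintf("g%02d", seq_len(ng)),
      chrom = sample(c("chr1", "chr2"), ng, replace = TRUE),
      start = start, end = start + sample(500:3000, ng, replace = TRUE),
      strand = sample(c("+", "-"), ng, replace = TRUE)))
    ps <- sample.int(5e5, np)
    peaks <- peak_set(sample(c("chr1", "chr2"), np, replace = TRUE),
                      ps, ps + sample(200:2000, np, replace = TRUE))
    w <- sample(c(5000L, 20000L, 100000L), 1)
    for (co in c(TRUE, FALSE)) {
      got <- assign_peaks(peaks, models, w, closest_only = co)
      want <- bf_assign(peaks, models, w, closest_only = co)
      expect_equal(setNames(got$bound, got$gene_id), want,
                   label = sprintf("instance %d closest_only=%s", i, co))
    }
  }
})

test_that("enlarging the window never unbinds a gene", {
  set.seed(22)
  start <- sample.int(2e5, 20)
  models <- toy_models(data.frame(gene_id = sprintf("g%02d", 1:20),
                                  chrom = "chr1", start = start,
                                  end = start + 1000L,
                                  strand = sample(c("+", "-"), 20, TRUE)))
  ps <- sample.int(2e5, 15)
  peaks <- peak_set("chr1", ps, ps + 500L)
  b10 <- assign_peaks(peaks, models, 10000L, closest_only = FALSE)
  b50 <- assign_peaks(peaks, models, 50000L, closest_only = FALSE)
  expect_true(all(b50$bound[b10$bound]))
})

test_that("empty peak sets leave every gene unbound", {
  models <- toy_models(data.frame(gene_id = "g1", chrom = "chr1",
                                  start = 0L, end = 100L, strand = "+"))
  b <- assign_peaks(peak_set(character(0), integer(0), integer(0)),
                    models, 50000L)
  expect_false(b$bound)
  expect_true(is.na(b$nearest_peak_distance))
})

make_cond_rpkm <- function(ctrl_mean, treat_mean, labels) {
  sheet <- sample_sheet(c("c1", "c2", "t1", "t2"),
                        rep(labels, each = 2), rep(1e7, 4))
  m <- matrix(c(ctrl_mean, ctrl_mean, treat_mean, treat_mean),
              nrow = length(ctrl_mean),
              dimnames = list(names(ctrl_mean), sheet$sample_id))
  attr(m, "unit") <- "rpkm"
  list(m = m, sheet = sheet)
}

test_that("fold-change calls use strict thresholds per contrast", {
  x <- make_cond_rpkm(c(gA = 10, gB = 10, gC = 0),
                      c(gA = 16, gB = 7, gC = 0),
                      c("vehicle", "DHT"))
  r <- call_regulation(x$m, x$sheet, "DHT_vs_vehicle", cell_line = "LNCaP")
  expect_equal(setNames(r$call, r$gene_id),
               c(gA = "induced", gB = "repressed", gC = "unchanged"))
  expect_equal(r$fold[r$gene_id == "gC"], 1)  # eps/eps on all-zero gene

  y <- make_cond_rpkm(c(gA = 10), c(gA = 7), c("siControl", "siAR"))
  r2 <- call_regulation(y$m, y$sheet, "siAR_vs_siControl", cell_line = "22Rv1")
  expect_equal(r2$call, "induced")  # knockdown lowers an AR-induced gene

  # fold exactly at a threshold is "unchanged" (strict inequality)
  z <- make_cond_rpkm(c(g = 1e6), c(g = 1.5e6), c("vehicle", "DHT"))
  r3 <- call_regulation(z$m, z$sheet, "DHT_vs_vehicle",
                        thresholds = crpc_thresholds(pseudocount = 1e-9))
  expect_equal(r3$call, "unchanged")

  expect_error(call_regulation(x$m, x$sheet, "siAR_vs_siControl"),
               "missing")
})

test_that("AR targets are the bound-and-regulated intersection", {
  mk_b <- function(bound) data.frame(gene_id = names(bound), bound = bound,
                                     stringsAsFactors = FALSE)
  mk_r <- function(call) data.frame(gene_id = names(call), call = call,
                                    stringsAsFactors = FALSE)
  genes <- c("g1", "g2", "g3", "g4")
  binding <- list(
    LNCaP = mk_b(setNames(c(TRUE, TRUE, FALSE, TRUE), genes)),
    VCaP = mk_b(setNames(c(TRUE, FALSE, FALSE, TRUE), genes)),
    `22Rv1` = mk_b(setNames(c(FALSE, TRUE, TRUE, TRUE), genes)))
  regulation <- list(
    LNCaP = mk_r(setNames(c("induced", "unchanged", "induced", "induced"), genes)),
    VCaP = mk_r(setNames(c("induced", "induced", "unchanged", "repressed"), genes)),
    `22Rv1` = mk_r(setNames(c("induced", "induced", "unchanged", "unchanged"), genes)))
  t <- ar_target_genes(binding, regulation)
  expect_equal(t$per_line$LNCaP, c("g1", "g4"))   # g2 unregulated, g3 unbound
  expect_equal(t$LNCaP_VCaP, c("g1", "g4"))
  expect_equal(t$R22Rv1, "g2")
  bad <- binding; bad$VCaP <- bad$VCaP[-1, ]
  expect_error(ar_target_genes(bad, regulation), "universe")
})

test_that("funnel stages are nested and drop distant or unregulated genes", {
  sim <- quick_sim_dir()
  res <- run_discover(sim_inputs(sim), withr::local_tempdir())
  st <- res$integration$funnel$stages
  expect_true(all(diff(st$n) <= 0))
  # a regulated lncRNA whose only peak is outside the 10 kb window is
  # dropped at the last stage
  tr <- load_ground_truth(file.path(sim, "ground_truth.tsv"))
  near_miss <- tr$gene_id[!is.na(tr$window_bp) & tr$window_bp == 10000 &
                            !tr$ar_bound]
  expect_true(length(near_miss) > 0)
  expect_false(any(near_miss %in% res$integration$funnel$candidates$gene_id))

  # empty input -> zeroed funnel
  empty <- crpc_lnc_funnel(
    data.frame(gene_id = character(0), class = character(0),
               mean_rpkm_benign = numeric(0), mean_rpkm_pca = numeric(0),
               mean_rpkm_crpc = numeric(0)),
    data.frame(gene_id = character(0), verdict = character(0),
               context = character(0)),
    list(),
    data.frame(gene_id = character(0), bound = logical(0),
               nearest_peak_distance = integer(0)),
    res$models)
  expect_equal(empty$stages$n, c(0L, 0L, 0L))
  expect_equal(nrow(empty$candidates), 0L)
})
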