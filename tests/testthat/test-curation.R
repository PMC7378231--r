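# Layout used below (coordinates in bp on chr1):
#   coding   [10000, 20000) "+", exons 10000-12000, 15000-17000, 19000-20000
#   lnc_as   [13000, 16000) "-"  : inside the coding span, opposite strand
#   lnc_int  [40000, 42000) "+"  : > 10 kb from any coding gene
#   lnc_dec  [15000, 17000) "+"  : single exon coinciding with a coding exon
#   lnc_intr [12500, 14500) "+"  : wholly within the coding gene, exon in
#                                  the intron (no shared exonic bases)
curation_models <- function() toy_models(data.frame(
  gene_id = c("coding", "lnc_as", "lnc_int", "lnc_dec", "lnc_intr"),
  chrom = "chr1",
  start = c(10000L, 13000L, 40000L, 15000L, 12500L),
  end = c(20000L, 16000L, 42000L, 17000L, 14500L),
  strand = c("+", "-", "+", "+", "+"),
  biotype = c("coding", rep("noncoding", 4)),
  database = c("RefSeq", "GENCODE", "NONCODE", "GENCODE", "NONCODE"),
  exons = c("10000-12000,15000-17000,19000-20000", "", "",
            "15000-17000", "12600-13800")))

test_that("context classes follow strand and overlap structure", {
  m <- curation_models()
  calls <- curate_all(c("lnc_as", "lnc_int", "lnc_dec", "lnc_intr"), m)$calls
  got <- setNames(paste(calls$verdict, calls$context), calls$gene_id)
  expect_equal(got[["lnc_as"]], "kept antisense")
  expect_equal(got[["lnc_int"]], "kept intergenic")
  expect_equal(got[["lnc_dec"]], "excluded_exonic NA")
  expect_equal(got[["lnc_intr"]], "kept other")  # intronic same-strand
})

test_that("coding candidates are rejected and outcomes partition", {
  m <- curation_models()
  expect_error(curate_all("coding", m), "coding biotype")
  calls <- curate_all(c("lnc_as", "lnc_int", "lnc_dec", "lnc_intr"), m)$calls
  kept <- calls[calls$verdict == "kept", ]
  expect_true(all(kept$context %in% c("antisense", "intergenic", "other")))
  expect_true(all(is.na(calls$context[calls$verdict == "excluded_exonic"])))
})

test_that("a higher overlap-fraction requirement can rescue partial overlap", {
  m <- toy_models(data.frame(
    gene_id = c("cod", "lnc"), chrom = "chr1",
    start = c(1000L, 2900L), end = c(3000L, 6000L), strand = "+",
    biotype = c("coding", "noncoding"), database = c("RefSeq", "NONCODE"),
    exons = c("1000-3000", "2900-6000")))
  # 100 bp of a 3100 bp exon overlap a coding exon (~3%)
  expect_equal(curate_lnc("lnc", m)$verdict, "excluded_exonic")
  expect_equal(curate_lnc("lnc", m, min_overlap_frac = 0.5)$verdict, "kept")
})

test_that("flipping every strand leaves verdicts and contexts unchanged", {
  sim <- quick_sim_dir()
  m <- read_gtf(file.path(sim, "annotation.gtf"))
  cand <- m$genes$gene_id[m$genes$biotype == "noncoding"]
  a <- curate_all(cand, m)$calls
  flipped <- m
  flipped$genes$strand <- ifelse(flipped$genes$strand == "+", "-", "+")
  flipped$genes$tss <- ifelse(flipped$genes$strand == "+",
                              flipped$genes$start, flipped$genes$end - 1L)
  flipped$exons$strand <- ifelse(flipped$exons$strand == "+", "-", "+")
  b <- curate_all(cand, flipped)$calls
  expect_equal(a$verdict, b$verdict)
  expect_equal(a$context, b$context)
})

test_that("overlap decisions match a brute-force all-pairs scan", {
  sim <- quick_sim_dir()
  m <- read_gtf(file.path(sim, "annotation.gtf"))
  g <- m$genes
  cand <- g$gene_id[g$biotype == "noncoding"]
  coding <- g[g$biotype == "coding", ]
  calls <- curate_all(cand, m)$calls
  for (id in cand) {
    ci <- g[g$gene_id == id, ]
    cex <- m$exons[m$exons$gene_id == id, ]
    excl <- FALSE; anti <- FALSE; body_any <- FALSE
    for (j in seq_len(nrow(coding))) {
      cj <- coding[j, ]
      if (cj$chrom != ci$chrom) next
      if (ci$start < cj$end && cj$start < ci$end) {
        body_any <- TRUE
        if (cj$strand != ci$strand) anti <- TRUE
      }
      if (cj$strand == ci$strand) {
        jex <- m$exons[m$exons$gene_id == cj$gene_id, ]
        for (k in seq_len(nrow(cex))) for (l in seq_len(nrow(jex)))
          if (cex$start[k] < jex$end[l] && jex$start[l] < cex$end[k])
            excl <- TRUE
      }
    }
    want <- if (excl) "excluded_exonic NA"
            else if (anti) "kept antisense"
            else if (!body_any) "kept intergenic"
            else "kept other"
    got <- calls[calls$gene_id == id, ]
    expect_equal(paste(got$verdict, got$context), want, label = id)
  }
})

test_that("without coding genes every candidate is intergenic", {
  m <- toy_models(data.frame(
    gene_id = c("l1", "l2"), chrom = "chr1",
    start = c(100L, 150L), end = c(500L, 600L), strand = c("+", "-"),
    biotype = "noncoding", database = "NONCODE"))
  calls <- curate_all(c("l1", "l2"), m)$calls
  expect_equal(calls$context, c("intergenic", "intergenic"))
  expect_equal(nrow(curate_all(character(0), m)$calls), 0L)
})
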