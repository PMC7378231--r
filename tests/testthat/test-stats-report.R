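test_that("chisq_2x2 reproduces the hand-computed Pearson statistic", {
  res <- chisq_2x2(matrix(c(20, 10, 80, 90), 2))
  # expecteds 15/85/15/85 -> sum (O-E)^2/E = 3.9216
  expect_equal(res$statistic, 3.9216, tolerance = 1e-4)
  expect_equal(res$df, 1L)
})

test_that("identical rows give statistic 0 and p 1", {
  res <- chisq_2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
  res2 <- chisq_2x2(matrix(c(7, 7, 13, 13), 2))
  expect_equal(res2$statistic, 0)
})

test_that("statistic equals the closed-form shortcut on random tables", {
  set.seed(31)
  for (i in 1:200) {
    t <- matrix(sample(1:200, 4, replace = TRUE), 2)
    res <- chisq_2x2(t)
    n <- sum(t)
    shortcut <- n * (t[1, 1] * t[2, 2] - t[1, 2] * t[2, 1])^2 /
      prod(rowSums(t), colSums(t))
    expect_equal(res$statistic, shortcut, tolerance = 1e-10)
    # transposing (swapping set roles) leaves the statistic unchanged
    expect_equal(chisq_2x2(t(t))$statistic, res$statistic, tolerance = 1e-12)
  }
})

test_that("degenerate tables are rejected", {
  expect_error(chisq_2x2(matrix(c(0, 0, 5, 5), 2)), "marginal")
  expect_error(chisq_2x2(matrix(c(1.5, 1, 1, 1), 2)), "integer")
})

test_that("overlap_test builds the membership table and conserves marginals", {
  uni <- sprintf("g%03d", 1:100)
  s <- uni[1:30]
  res <- overlap_test(uni, s, s)
  expect_equal(unname(res$table), matrix(c(30, 0, 0, 70), 2))
  set.seed(33)
  s1 <- sample(uni, 40); s2 <- sample(uni, 25)
  r2 <- overlap_test(uni, s1, s2)
  expect_equal(unname(rowSums(r2$table)), c(40, 60))
  expect_equal(unname(colSums(r2$table)), c(25, 75))
  expect_error(overlap_test(uni, c(s1, "gX"), s2), "subsets")
})

test_that("heatmap entries are log2 ratios to the benign mean", {
  sheet <- sample_sheet(c("b1", "b2", "c1"), c("benign", "benign", "crpc"),
                        rep(1e7, 3))
  m <- rbind(g1 = c(4, 4, 8), g2 = c(0, 0, 0))
  colnames(m) <- sheet$sample_id
  attr(m, "unit") <- "rpkm"
  h <- heatmap_table(m, sheet, pseudocount = 1e-9)
  expect_equal(h["g1", "b1"], 0, tolerance = 1e-6)
  expect_equal(h["g1", "c1"], 1, tolerance = 1e-6)
  expect_equal(unname(h["g2", ]), c(0, 0, 0))  # eps/eps on an all-zero gene
  expect_error(heatmap_table(m, sheet, benign_label = "normal"), "missing")
})

test_that("report stage counts are consistent and non-increasing", {
  sim <- quick_sim_dir()
  res <- run_discover(sim_inputs(sim), withr::local_tempdir())
  s <- setNames(res$summary$n, res$summary$stage)
  expect_true(s[["curated_lnc"]] >= s[["regulated_lnc"]])
  expect_true(s[["regulated_lnc"]] >= s[["bound_within_window"]])
  expect_true(s[["passed_expression_filter"]] <= s[["genes_tested"]])
  tr <- load_ground_truth(file.path(sim, "ground_truth.tsv"))
  expect_equal(s[["Type_A"]], sum(tr$true_class == "Type_A"))
  expect_equal(s[["Type_B"]], sum(tr$true_class == "Type_B"))
})
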