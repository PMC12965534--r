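test_that("log2 fold change follows the CP10K + pseudocount arithmetic", {
  # gene g1 has CP10K mean 3 in A and 1 in B; pseudocount 1 -> log2(4/2) = 1
  A <- rbind(g1 = c(3, 3), filler = c(9997, 9997))
  B <- rbind(g1 = c(1, 1), filler = c(9999, 9999))
  fc <- log2FoldChange(A, B, pseudocount = 1)
  expect_equal(unname(fc["g1"]), 1)
  # identical groups -> 0 everywhere
  expect_equal(unname(log2FoldChange(A, A)), c(0, 0))
  # antisymmetry
  expect_equal(log2FoldChange(A, B), -log2FoldChange(B, A))
  expect_error(log2FoldChange(A[, 0, drop = FALSE], B), "at least one cell")
})

test_that("permutation background is seeded, centered, and degenerate-safe", {
  set.seed(2)
  counts <- matrix(rpois(50 * 60, 4), 50, 60,
                   dimnames = list(sprintf("g%02d", 1:50),
                                   sprintf("c%02d", 1:60)))
  b1 <- permuteBackground(counts, 100, seed = 9L)
  b2 <- permuteBackground(counts, 100, seed = 9L)
  expect_identical(b1, b2)
  expect_identical(dim(b1), c(50L, 100L))
  # random equal splits of exchangeable cells fluctuate around zero
  expect_lt(max(abs(rowMeans(b1))), 0.15)
  # identical cells -> all-zero background
  same <- matrix(rep(c(5, 3, 2), 10), 3, 10)
  rownames(same) <- c("a", "b", "c")
  expect_true(all(permuteBackground(same, 10, seed = 1L) == 0))
  expect_error(permuteBackground(counts[, 1:3], 10), "at least 4")
  expect_error(permuteBackground(counts, 0), "nIterations")
})

test_that("odd cell numbers split into floor/ceiling halves", {
  counts <- matrix(rpois(10 * 9, 5), 10, 9)
  rownames(counts) <- sprintf("g%02d", 1:10)
  bg <- permuteBackground(counts, 5, seed = 3L)
  expect_identical(dim(bg), c(10L, 5L))
  expect_true(all(is.finite(bg)))
})

test_that("threshold estimation matches a sort-and-interpolate oracle", {
  expect_equal(as.numeric(estimateThreshold(c(0.5, -0.5, 0.5))), 0.5)
  sym <- c(seq(0.1, 1, by = 0.1), -seq(0.1, 1, by = 0.1))
  thr <- estimateThreshold(sym, 95)
  expect_equal(as.numeric(thr), percentileOracle(abs(sym), 95))
  set.seed(17)
  x <- rnorm(500)
  for (p in c(50, 80, 95, 99))
    expect_equal(as.numeric(estimateThreshold(x, p)),
                 percentileOracle(abs(x), p))
  # replication invariance
  expect_equal(as.numeric(estimateThreshold(rep(sym, 3), 95)),
               as.numeric(estimateThreshold(sym, 95)))
  # monotone in the percentile
  ths <- vapply(c(50, 70, 90, 99), function(p)
    as.numeric(estimateThreshold(x, p)), numeric(1))
  expect_true(all(diff(ths) >= 0))
  expect_error(estimateThreshold(x, 0), "percentile")
  expect_error(estimateThreshold(x, 100), "percentile")
})

test_that("signed convention covers the two-tailed interval", {
  skewed <- c(rnorm(1000, 0.2, 0.1))
  t1 <- estimateThreshold(skewed, 95, convention = "signed")
  expect_equal(as.numeric(t1),
               max(abs(quantile(skewed, c(0.025, 0.975), type = 7))))
})

test_that("exceedance and fold-excess calls use strict inequality", {
  res <- assessGene(c(s1 = 0.85), 0.68)
  expect_true(res$exceeds)
  expect_equal(res$fold_excess, 0.85 / 0.68)
  expect_gte(res$fold_excess, 1.24)
  at <- assessGene(0.68, 0.68)
  expect_false(at$exceeds)
  expect_equal(at$fold_excess, 1)
  zero <- assessGene(0, 0.68)
  expect_false(zero$exceeds)
  expect_equal(zero$fold_excess, 0)
  expect_error(assessGene(0.5, 0), "degenerate")
})

test_that("the corpus-level wrapper flags planted drivers as exceeding", {
  corpus <- simulateCorpus(simulationSpec(
    nCellsControl = 300, nCellsDisease = 300, nGenes = 300,
    nDriverGenes = 5, driverLog2fc = 2, seed = 12L))
  fr <- fluctuationAnalysis(corpus, nIterations = 50, seed = 8L)
  expect_s4_class(fr, "FluctuationResult")
  expect_gt(fluctuationThreshold(fr), 0)
  drivers <- driverGenes(corpus)
  expect_true(all(fr@exceeds[drivers]))
  expect_true(all(fr@foldExcess[drivers] > 1))
  # planted changes dominate the (composition-shifted) background genes
  others <- setdiff(names(fr@observed), drivers)
  expect_gt(min(abs(fr@observed[drivers])),
            quantile(abs(fr@observed[others]), 0.95))
  f <- withr::local_tempfile(fileext = ".json")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeFluctuationResult(fr, f, tsv)
  js <- jsonlite::read_json(f)
  expect_equal(js$threshold, fluctuationThreshold(fr))
  tab <- read.delim(tsv)
  expect_identical(nrow(tab), 300L)
})
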