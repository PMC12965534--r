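# vocabulary A/B/C/D -> tokens 2/3/4/5
pvocab <- makeVocab(c("A", "B", "C", "D"), c(1, 1, 1, 1))
tok <- function(g) geneToken(pvocab, g)

test_that("in-silico deletion removes the token and preserves order", {
  bac <- tok(c("B", "A", "C"))
  expect_identical(deleteGene(bac, "A", pvocab), tok(c("B", "C")))
  expect_null(deleteGene(bac, "D", pvocab))          # absent -> skip
  expect_error(deleteGene(bac, "E", pvocab), "not in vocabulary")
})

test_that("in-silico overexpression moves or inserts at the top", {
  bac <- tok(c("B", "A", "C"))
  expect_identical(overexpressGene(bac, "C", pvocab), tok(c("C", "B", "A")))
  expect_identical(overexpressGene(tok(c("B", "A")), "D", pvocab, L = 2),
                   tok(c("D", "B")))
  expect_identical(overexpressGene(bac, "B", pvocab), bac)
  expect_error(overexpressGene(bac, "E", pvocab), "not in vocabulary")
})

test_that("perturbation ops never duplicate, never exceed L, preserve order", {
  set.seed(31)
  ids <- sprintf("g%02d", 1:30)
  vocab <- makeVocab(ids, rep(1, 30))
  for (i in 1:100) {
    n <- sample(3:20, 1)
    enc <- sample(tokenIds(vocab), n)
    gene <- sample(ids, 1)
    gtok <- geneToken(vocab, gene)
    L <- n  # encodings are at their length bound
    oe <- overexpressGene(enc, gene, vocab, L = L)
    expect_identical(oe[1], gtok)
    expect_identical(anyDuplicated(oe), 0L)
    expect_lte(length(oe), L)
    expect_identical(setdiff(oe[-1], gtok),
                     head(setdiff(enc, gtok), length(oe) - 1))
    del <- deleteGene(enc, gene, vocab)
    if (gtok %in% enc) {
      pos <- match(gtok, enc)
      expect_identical(length(del), n - 1L)
      expect_false(gtok %in% del)
      expect_identical(append(del, gtok, after = pos - 1L), enc)
    } else expect_null(del)
  }
})

test_that("goal states are embedding centroids, order-invariant", {
  e <- rbind(c(1, 0), c(0, 1))
  g <- computeGoalState(e, "disease")
  expect_equal(g@centroid, c(0.5, 0.5))
  expect_identical(g@nCells, 2L)
  g1 <- computeGoalState(e[1, , drop = FALSE], "disease")
  expect_equal(g1@centroid, c(1, 0))
  set.seed(6)
  m <- matrix(rnorm(40), 10, 4)
  expect_equal(computeGoalState(m, "x")@centroid,
               computeGoalState(m[sample(10), ], "x")@centroid)
  expect_error(computeGoalState(matrix(numeric(0), 0, 2), "x"),
               "at least one")
})

test_that("cosine shift matches hand arithmetic and its symmetries", {
  goal <- computeGoalState(rbind(c(0, 1)), "disease")
  expect_equal(shiftToGoal(c(1, 0), c(0, 1), goal), 1)
  expect_equal(shiftToGoal(c(1, 0), c(1, 0), goal), 0)
  o <- c(2, 1); p <- c(-1, 3)
  expect_equal(shiftToGoal(o, p, goal), -shiftToGoal(p, o, goal))
  expect_equal(shiftToGoal(o, p, goal), shiftToGoal(5 * o, 0.1 * p, goal))
  expect_error(shiftToGoal(c(0, 0), p, goal), "zero-norm")
  g2 <- computeGoalState(rbind(c(-1, 0)), "disease")
  expect_gte(shiftToGoal(c(1, 0), c(-1, 0), g2), 2 - 1e-12)  # bound attained
})

test_that("BH adjustment matches the step-up oracle on random p-vectors", {
  expect_equal(bhOracle(c(0.01, 0.02, 0.04)), c(0.03, 0.03, 0.04))
  set.seed(12)
  for (i in 1:50) {
    p <- runif(sample(2:20, 1))
    expect_equal(p.adjust(p, "BH"), bhOracle(p), tolerance = 1e-12)
  }
})

makePerturbResult <- function(shifts, mode = "delete") {
  rec <- data.frame(gene_id = names(shifts), mode = mode,
                    direction = "control->disease",
                    n_cells = lengths(shifts),
                    n_cells_eligible = lengths(shifts),
                    shift_to_goal_end = vapply(shifts, mean, numeric(1)),
                    excluded = FALSE, stringsAsFactors = FALSE)
  new("PerturbationResult", records = rec, shifts = shifts, mode = mode,
      direction = "control->disease", goalLabel = "disease",
      params = list(minCells = 5L, maxCellsPerGene = 50L, seed = 1L))
}

test_that("candidate ranking: fdr from the aggregate null, filter and order", {
  set.seed(23)
  shifts <- c(list(hit = rnorm(30, 2, 0.2)),
              setNames(lapply(1:50, function(i) rnorm(30, 0, 0.2)),
                       sprintf("null%02d", 1:50)))
  ranked <- rankCandidates(makePerturbResult(shifts), alpha = 0.05)
  expect_identical(ranked$tested$gene_id[1], "hit")
  expect_identical(ranked$candidates$gene_id[1], "hit")
  expect_equal(ranked$tested$fdr, bhOracle(ranked$tested$p_value))
  expect_true(all(ranked$tested$fdr >= ranked$tested$p_value))
  expect_true(all(ranked$candidates$shift_to_goal_end > 0))
  expect_true(all(ranked$candidates$fdr < 0.05))
  ord <- order(-ranked$candidates$shift_to_goal_end, ranked$candidates$fdr)
  expect_identical(ord, seq_len(nrow(ranked$candidates)))
})

test_that("a gene distributed like the pooled null is not a candidate", {
  set.seed(44)
  base <- rnorm(40, 0, 0.3)
  shifts <- setNames(lapply(1:20, function(i) base),
                     sprintf("g%02d", 1:20))
  ranked <- rankCandidates(makePerturbResult(shifts))
  expect_true(all(ranked$tested$fdr > 0.9))
  expect_identical(nrow(ranked$candidates), 0L)
  expect_error(rankCandidates(makePerturbResult(shifts[1])), "at least 2")
})

test_that("a constant-embedding model yields all-zero shifts and no candidates", {
  st <- tinyTrainedSetup()
  ft <- finetuneClassifier(newStateModel(st$cfg), st$enc, epochs = 1L)
  cm <- constantModel(ft)
  cond <- encodingConditions(st$enc)
  emb <- embedCells(cm, st$enc)
  goal <- computeGoalState(emb[cond == "disease", ], "disease")
  startEnc <- st$enc[which(cond == "control")]
  pr <- perturbCorpus(cm, startEnc, geneIds(st$vocab)[1:30], "delete",
                      goal, st$vocab, minCells = 3L, seed = 2L)
  sh <- unlist(perturbationShifts(pr))
  expect_lte(max(abs(sh)), 4 * .Machine$double.eps)
  ranked <- rankCandidates(pr)
  expect_identical(nrow(ranked$candidates), 0L)
})

test_that("perturbation eligibility and exclusion rules", {
  st <- tinyTrainedSetup()
  ft <- finetuneClassifier(newStateModel(st$cfg), st$enc, epochs = 1L)
  cond <- encodingConditions(st$enc)
  emb <- embedCells(ft, st$enc)
  goal <- computeGoalState(emb[cond == "disease", ], "disease")
  startEnc <- st$enc[which(cond == "control")[1:20]]
  genes <- genesExpressedInBoth(st$corpus)
  expect_true(length(genes) > 10)
  pr <- perturbCorpus(ft, startEnc, genes[1:25], "delete", goal, st$vocab,
                      minCells = 5L, maxCellsPerGene = 10L, seed = 3L)
  rec <- perturbationRecords(pr)
  expect_true(all(rec$n_cells[!rec$excluded] >= 5))
  expect_true(all(rec$n_cells <= 10))
  expect_true(all(is.na(rec$shift_to_goal_end[rec$excluded])))
  # overexpression: every start cell is eligible
  po <- perturbCorpus(ft, startEnc, genes[1:10], "overexpress", goal,
                      st$vocab, minCells = 5L, maxCellsPerGene = 50L,
                      seed = 3L)
  expect_true(all(perturbationRecords(po)$n_cells == 20))
  expect_error(perturbCorpus(ft, startEnc, character(), "delete", goal,
                             st$vocab), "empty gene list")
})

test_that("planted drivers shift more than random non-drivers on deletion", {
  st <- tinyTrainedSetup(seed = 71L)
  ft <- finetuneClassifier(newStateModel(st$cfg), st$enc, epochs = 3L)
  cond <- encodingConditions(st$enc)
  emb <- embedCells(ft, st$enc)
  goal <- computeGoalState(emb[cond == "disease", ], "disease")
  startEnc <- st$enc[which(cond == "control")]
  drivers <- driverGenes(st$corpus)
  set.seed(15)
  others <- sample(setdiff(genesExpressedInBoth(st$corpus), drivers), 20)
  pr <- perturbCorpus(ft, startEnc, c(drivers, others), "delete", goal,
                      st$vocab, minCells = 3L, seed = 5L)
  rec <- perturbationRecords(pr)
  sDriver <- rec$shift_to_goal_end[rec$gene_id %in% drivers & !rec$excluded]
  sOther <- rec$shift_to_goal_end[rec$gene_id %in% others & !rec$excluded]
  expect_gt(mean(sDriver), mean(sOther))
})
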