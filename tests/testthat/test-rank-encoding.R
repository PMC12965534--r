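test_that("normalization factors are nonzero medians of depth-normalized expression", {
  # gene gA has depth-normalized values 0.1, 0, 0.3 across the three cells
  counts <- rbind(gA = c(1, 0, 3),
                  gB = c(9, 10, 7))
  colnames(counts) <- c("c1", "c2", "c3")
  corpus <- makeCorpus(counts, c("control", "control", "disease"))
  vocab <- buildVocabulary(corpus)
  expect_equal(unname(normFactors(vocab)["gA"]), median(c(0.1, 0.3)))
  expect_equal(unname(normFactors(vocab)["gA"]), 0.2)
})

test_that("a gene expressed in exactly one cell gets that value as its factor", {
  counts <- rbind(gA = c(2, 0), gB = c(8, 5))
  colnames(counts) <- c("c1", "c2")
  corpus <- makeCorpus(counts, c("control", "disease"))
  vocab <- buildVocabulary(corpus)
  expect_equal(unname(normFactors(vocab)["gA"]), 0.2)
})

test_that("never-expressed genes are excluded; empty corpora are an error", {
  counts <- rbind(gA = c(1, 2), gB = c(0, 0), gC = c(3, 1))
  colnames(counts) <- c("c1", "c2")
  corpus <- makeCorpus(counts, c("control", "disease"))
  vocab <- buildVocabulary(corpus)
  expect_setequal(geneIds(vocab), c("gA", "gC"))
  zero <- makeCorpus(matrix(0, 2, 2), c("control", "disease"))
  expect_error(buildVocabulary(zero), "no expressed genes")
})

test_that("token ids are assigned lexicographically from 2", {
  counts <- rbind(zz = c(1, 1), aa = c(1, 1), mm = c(1, 1))
  colnames(counts) <- c("c1", "c2")
  vocab <- buildVocabulary(makeCorpus(counts, c("control", "disease")))
  expect_identical(geneIds(vocab), c("aa", "mm", "zz"))
  expect_identical(tokenIds(vocab), 2:4)
})

test_that("rank encoding follows normalized scores with token-id tie-breaks", {
  vocab <- makeVocab(c("A", "B", "C"), c(1.0, 0.25, 0.5))
  # scores: A = 0.5, B = 1.0, C = 0.5 -> B first, then A before C (tie)
  enc <- rankEncode(c(A = 10, B = 5, C = 5), vocab, L = 8)
  expect_identical(enc, geneToken(vocab, c("B", "A", "C")))
  expect_identical(rankEncode(c(A = 10, B = 5, C = 5), vocab, L = 1),
                   geneToken(vocab, "B"))
  expect_identical(rankEncode(c(A = 0, B = 7, C = 0), vocab, L = 8),
                   geneToken(vocab, "B"))
})

test_that("rank encoding matches the selection oracle on random cells", {
  set.seed(19)
  nGenes <- 25
  ids <- sprintf("g%02d", seq_len(nGenes))
  for (i in seq_len(200)) {
    vocab <- makeVocab(ids, exp(rnorm(nGenes)))
    counts <- setNames(rpois(nGenes, 2), ids)
    if (sum(counts) == 0) counts[1] <- 1
    L <- sample(1:30, 1)
    expect_identical(rankEncode(counts, vocab, L),
                     rankEncodeOracle(counts, vocab, L))
  }
})

test_that("encoding is invariant to depth scaling and respects length rules", {
  set.seed(4)
  ids <- sprintf("g%02d", 1:20)
  vocab <- makeVocab(ids, exp(rnorm(20)))
  counts <- setNames(rpois(20, 1.5), ids)
  counts[1] <- counts[1] + 1
  expect_identical(rankEncode(counts, vocab, 15),
                   rankEncode(counts * 7, vocab, 15))
  nExpressed <- sum(counts > 0)
  expect_length(rankEncode(counts, vocab, 100), nExpressed)
  expect_length(rankEncode(counts, vocab, 3), min(3, nExpressed))
})

test_that("all-zero cells signal an unencodable-cell condition", {
  vocab <- makeVocab(c("A", "B"), c(1, 1))
  expect_error(rankEncode(c(A = 0, B = 0), vocab, 4),
               class = "unencodableCell")
})

test_that("encodeCorpus agrees with per-cell rankEncode and drops unencodable cells", {
  set.seed(8)
  counts <- matrix(rpois(30 * 12, 1), 30, 12,
                   dimnames = list(sprintf("g%02d", 1:30),
                                   sprintf("c%02d", 1:12)))
  counts[, 3] <- 0
  corpus <- makeCorpus(counts, rep(c("control", "disease"), 6))
  vocab <- buildVocabulary(corpus)
  expect_message(enc <- encodeCorpus(corpus, vocab, 10), "unencodable")
  expect_identical(attr(enc, "dropped"), "c03")
  toks <- encodingTokens(enc)
  for (cid in names(toks))
    expect_identical(toks[[cid]],
                     rankEncode(counts[, cid], vocab, 10))
})

test_that("vocabulary TSV round-trips", {
  vocab <- makeVocab(c("A", "B", "C"), c(0.2, 1.5, 0.01))
  f <- withr::local_tempfile(fileext = ".tsv")
  writeVocabulary(vocab, f)
  back <- readVocabulary(f)
  expect_identical(geneIds(back), geneIds(vocab))
  expect_identical(tokenIds(back), tokenIds(vocab))
  expect_equal(normFactors(back), normFactors(vocab))
})
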