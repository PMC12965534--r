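# Shared fixtures and independent oracles, all built in code.

# Vocabulary over gene ids A..: tokens assigned lexicographically from 2.
makeVocab <- function(geneIds, normFactors) {
  ord <- order(geneIds)
  new("GeneVocabulary", geneIds = geneIds[ord],
      tokenIds = seq_along(geneIds) + 1L,
      normFactors = normFactors[ord])
}

# Corpus from a dense genes x cells count matrix.
makeCorpus <- function(counts, condition, ...) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("c%03d", seq_len(ncol(counts)))
  expressionCorpus(counts, condition, ...)
}

# Independent rank-encoding oracle: repeated selection of the best-scoring
# gene (never calls the package's sort-based implementation).
rankEncodeOracle <- function(cellCounts, vocab, L) {
  total <- sum(cellCounts)
  idx <- match(names(cellCounts), geneIds(vocab))
  keep <- which(!is.na(idx) & cellCounts > 0)
  score <- (cellCounts[keep] / total) / normFactors(vocab)[idx[keep]]
  tok <- tokenIds(vocab)[idx[keep]]
  out <- integer(0)
  while (length(tok) && length(out) < L) {
    best <- which(score == max(score))
    best <- best[which.min(tok[best])]
    out <- c(out, tok[best])
    score <- score[-best]; tok <- tok[-best]
  }
  out
}

# Brute-force Benjamini-Hochberg step-up.
bhOracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- p[ord] * m / seq_len(m)
  for (i in (m - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(m)
  out[ord] <- pmin(adj, 1)
  out
}

# Sort-and-interpolate percentile oracle (linear interpolation between
# order statistics, the type-7 convention).
percentileOracle <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p / 100 + 1
  lo <- floor(h); hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# A model whose embeddings ignore the input: zeroed token and position
# embeddings make every position identical, so pooled embeddings are a
# constant vector for every cell.
constantModel <- function(model) {
  model@params$tok[] <- 0
  model@params$pos[] <- 0
  model
}

# Tiny trained classifier shared by model-level tests.
tinyTrainedSetup <- function(seed = 7L, nDrivers = 5L) {
  spec <- simulationSpec(nCellsControl = 120, nCellsDisease = 120,
                         nGenes = 50, nDriverGenes = nDrivers,
                         driverLog2fc = 2, seed = seed)
  corpus <- simulateCorpus(spec)
  vocab <- buildVocabulary(corpus)
  enc <- encodeCorpus(corpus, vocab, 32L)
  cfg <- modelConfig(vocabSize = max(tokenIds(vocab)) + 1L, nLayers = 1L,
                     nHeads = 2L, hiddenDim = 16L, contextLength = 32L,
                     batchSize = 32L, epochs = 2L, seed = seed)
  list(corpus = corpus, vocab = vocab, enc = enc, cfg = cfg)
}
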