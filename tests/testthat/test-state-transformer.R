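test_that("model config enforces architectural invariants", {
  expect_error(modelConfig(vocabSize = 10, nHeads = 3, hiddenDim = 16),
               "divisible")
  expect_error(modelConfig(vocabSize = 10, dropout = 1), "dropout")
  cfg <- modelConfig(vocabSize = 10, nLayers = 1, hiddenDim = 8, nHeads = 2)
  expect_s4_class(cfg, "ModelConfig")
})

test_that("masked pretraining learns and is deterministic under a seed", {
  set.seed(21)
  tokens <- lapply(1:120, function(i) sample(2:29, sample(6:12, 1)))
  enc <- new("RankEncodingSet", tokens = tokens,
             cellIds = sprintf("c%03d", 1:120), condition = character(),
             contextLength = 16L)
  cfg <- modelConfig(vocabSize = 30L, nLayers = 1L, nHeads = 2L,
                     hiddenDim = 16L, contextLength = 16L, batchSize = 32L,
                     epochs = 3L, seed = 9L)
  m1 <- pretrainMasked(enc, cfg)
  expect_identical(modelPhase(m1), "pretrained")
  expect_lt(m1@trainLog$loss[3], m1@trainLog$loss[1])
  m2 <- pretrainMasked(enc, cfg)
  expect_identical(m1@trainLog$loss, m2@trainLog$loss)
  expect_identical(m1@params$tok, m2@params$tok)
  expect_error(pretrainMasked(enc[1:50], cfg), "at least 100")
})

test_that("a converged tiny model beats chance at masked-gene recovery", {
  # identical encodings everywhere: the masked token is fully predictable
  tokens <- rep(list(c(5L, 9L, 3L, 12L, 7L, 2L)), 110)
  enc <- new("RankEncodingSet", tokens = tokens,
             cellIds = sprintf("c%03d", 1:110), condition = character(),
             contextLength = 8L)
  cfg <- modelConfig(vocabSize = 14L, nLayers = 1L, nHeads = 2L,
                     hiddenDim = 16L, contextLength = 8L, batchSize = 32L,
                     epochs = 6L, dropout = 0, seed = 2L)
  m <- pretrainMasked(enc, cfg)
  finalAcc <- m@trainLog$acc[nrow(m@trainLog)]
  expect_gt(finalAcc, 1 / 14)
})

test_that("fine-tuning requires both labels and respects phase transitions", {
  st <- tinyTrainedSetup()
  onlyCtrl <- st$enc[which(encodingConditions(st$enc) == "control")]
  m <- newStateModel(st$cfg)
  expect_error(finetuneClassifier(m, onlyCtrl), "both condition labels")
  ft <- finetuneClassifier(m, st$enc)
  expect_identical(modelPhase(ft), "finetuned")
  expect_identical(unique(ft@trainLog$startPhase), "random")
  expect_error(finetuneClassifier(ft, st$enc), "already finetuned")
  # pretrain -> finetune is the other legal path
  pre <- pretrainMasked(st$enc, st$cfg)
  ft2 <- finetuneClassifier(pre, st$enc, epochs = 1L)
  expect_identical(modelPhase(ft2), "finetuned")
  expect_identical(unique(ft2@trainLog$startPhase[
    ft2@trainLog$objective != "mlm"]), "pretrained")
})

test_that("fine-tuning is deterministic under a fixed seed", {
  st <- tinyTrainedSetup()
  f1 <- finetuneClassifier(newStateModel(st$cfg), st$enc)
  f2 <- finetuneClassifier(newStateModel(st$cfg), st$enc)
  expect_identical(f1@trainLog$loss, f2@trainLog$loss)
  expect_equal(f1@params$clsW, f2@params$clsW)
})

test_that("classification reports compute the confusion arithmetic correctly", {
  build <- function(truth, pred) {
    probs <- cbind(ifelse(pred == "control", 0.9, 0.1),
                   ifelse(pred == "control", 0.1, 0.9))
    scStatePerturb:::buildClassificationReport(
      sprintf("c%d", seq_along(truth)), truth, pred, probs)
  }
  # TP=2, FP=1, FN=1, TN=2 (disease positive)
  truth <- c("disease", "disease", "disease", "control", "control", "control")
  pred <- c("disease", "disease", "control", "disease", "control", "control")
  rep <- build(truth, pred)
  expect_equal(accuracy(rep), 4 / 6)
  expect_equal(macroF1(rep), 2 / 3, tolerance = 1e-12)
  expect_identical(sum(confusionMatrix(rep)), 6L)
  # perfect predictions
  perfect <- build(truth, truth)
  expect_equal(accuracy(perfect), 1)
  expect_equal(macroF1(perfect), 1)
  # constant predictions on a balanced set
  const <- build(truth, rep("disease", 6))
  expect_equal(accuracy(const), 0.5)
  # probabilities sum to one per cell
  pr <- classProbabilities(rep)
  expect_equal(pr$p_control + pr$p_disease, rep(1, 6))
})

test_that("a separable tiny corpus is classified well above chance", {
  st <- tinyTrainedSetup(seed = 13L)
  ft <- finetuneClassifier(newStateModel(st$cfg), st$enc, epochs = 8L)
  rep <- classifyCells(ft, st$enc)
  expect_gt(accuracy(rep), 0.8)
  expect_error(classifyCells(newStateModel(st$cfg), st$enc), "finetuned")
})

test_that("embeddings have the configured width and are batch-invariant", {
  st <- tinyTrainedSetup()
  pre <- pretrainMasked(st$enc, st$cfg)
  sub <- st$enc[1:10]
  batch <- embedCells(pre, sub)
  expect_identical(dim(batch), c(10L, st$cfg@hiddenDim))
  single <- do.call(rbind, lapply(1:10, function(i)
    embedCells(pre, sub[i])))
  expect_equal(batch, single, tolerance = 1e-10, ignore_attr = TRUE)
  expect_error(embedCells(newStateModel(st$cfg), sub), "pretrained or finetuned")
})

test_that("identical encodings receive identical embeddings", {
  st <- tinyTrainedSetup()
  pre <- pretrainMasked(st$enc, st$cfg)
  toks <- encodingTokens(st$enc)[[1]]
  twin <- new("RankEncodingSet", tokens = list(toks, toks),
              cellIds = c("x1", "x2"), condition = character(),
              contextLength = st$enc@contextLength)
  emb <- embedCells(pre, twin)
  expect_equal(emb["x1", ], emb["x2", ])
})

test_that("analytic gradients match central finite differences", {
  ns <- asNamespace("scStatePerturb")
  cfg <- modelConfig(vocabSize = 12L, nLayers = 2L, nHeads = 2L,
                     hiddenDim = 8L, contextLength = 10L, dropout = 0,
                     batchSize = 4L)
  set.seed(42)
  tokens <- lapply(1:4, function(i) sample(2:11, sample(3:8, 1)))
  labels01 <- c(0L, 1L, 1L, 0L)
  w <- c(1.3, 0.8)
  p <- ns$initParams(cfg, 7L)
  lossOf <- function(p) {
    fw <- ns$encForward(p, cfg, tokens, 0, training = FALSE)
    pooled <- ns$poolHidden(fw)
    logits <- pooled %*% p$clsW + rep(p$clsB, each = 4)
    P <- ns$softmaxRows(logits)
    -sum(w[labels01 + 1] *
           log(P[cbind(1:4, labels01 + 1)] + 1e-12)) / sum(w[labels01 + 1])
  }
  g <- ns$clsBatch(p, cfg, tokens, labels01, w, 0)$grads
  eps <- 1e-5
  for (nm in c("tok", "pos", "l1_Wq", "l1_ln1g", "l1_W1", "l2_Wo",
               "l2_W2", "lnfg", "clsW")) {
    idx <- sample(length(p[[nm]]), 3)
    for (k in idx) {
      p2 <- p; p2[[nm]][k] <- p2[[nm]][k] + eps
      p3 <- p; p3[[nm]][k] <- p3[[nm]][k] - eps
      num <- (lossOf(p2) - lossOf(p3)) / (2 * eps)
      expect_equal(g[[nm]][k], num, tolerance = 1e-4,
                   label = paste("grad", nm, k))
    }
  }
})

test_that("compiled inference agrees with the reference R forward pass", {
  ns <- asNamespace("scStatePerturb")
  set.seed(5)
  cfg <- modelConfig(vocabSize = 40L, nLayers = 2L, nHeads = 4L,
                     hiddenDim = 16L, contextLength = 20L)
  p <- ns$initParams(cfg, 3L)
  tokens <- lapply(1:12, function(i) sample(2:39, sample(3:20, 1)))
  cppPooled <- ns$pooledEmbeddings(p, cfg, tokens)
  fw <- ns$encForward(p, cfg, tokens, training = FALSE)
  expect_equal(unname(cppPooled), unname(ns$poolHidden(fw)),
               tolerance = 1e-12)
})

test_that("encodings longer than the model context are rejected", {
  st <- tinyTrainedSetup()
  pre <- pretrainMasked(st$enc, st$cfg)
  long <- new("RankEncodingSet", tokens = list(2:35),
              cellIds = "x", condition = character(),
              contextLength = 40L)
  expect_error(embedCells(pre, long), "context length")
})

test_that("checkpoints round-trip through a single archive file", {
  st <- tinyTrainedSetup()
  ft <- finetuneClassifier(newStateModel(st$cfg), st$enc, epochs = 1L)
  f <- withr::local_tempfile(fileext = ".rds")
  saveStateModel(ft, f)
  back <- loadStateModel(f)
  expect_identical(modelPhase(back), "finetuned")
  expect_equal(back@params, ft@params)
  pr1 <- classifyCells(ft, st$enc[1:5])
  pr2 <- classifyCells(back, st$enc[1:5])
  expect_equal(classProbabilities(pr1), classProbabilities(pr2))
})
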