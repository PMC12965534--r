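#' Create a transformer model configuration
#'
#' Defaults are a deliberately small architecture (2 layers, 4 heads,
#' d = 64, context 128, dropout 0.1) that trains in minutes on one CPU
#' while preserving the mechanics of rank-encoding transformers: learned
#' token and position embeddings, pre-LayerNorm multi-head self-attention
#' blocks with ReLU feed-forward sublayers (width `2 * hiddenDim`), mean
#' pooling over non-pad positions, and linear masked-gene / two-class
#' heads.
#'
#' @param vocabSize embedding-table size; must be at least
#'   `max token + 1` (use `max(tokenIds(vocab)) + 1L`)
#' @param nLayers,nHeads,hiddenDim,contextLength architecture dimensions
#' @param dropout dropout rate applied after the attention and
#'   feed-forward projections during training
#' @param learningRate,batchSize,epochs Adam optimization settings
#' @param seed training seed
#' @return a validated [ModelConfig-class]
#' @export
modelConfig <- function(vocabSize, nLayers = 2L, nHeads = 4L,
                        hiddenDim = 64L, contextLength = 128L,
                        dropout = 0.1, learningRate = 1.5e-3,
                        batchSize = 64L, epochs = 3L, seed = 1L) {
  methods::new("ModelConfig",
    nLayers = as.integer(nLayers), nHeads = as.integer(nHeads),
    hiddenDim = as.integer(hiddenDim),
    contextLength = as.integer(contextLength),
    vocabSize = as.integer(vocabSize), dropout = as.numeric(dropout),
    learningRate = as.numeric(learningRate),
    batchSize = as.integer(batchSize), epochs = as.integer(epochs),
    seed = as.integer(seed))
}

#' Create an untrained (phase "random") state model
#'
#' @param config a [ModelConfig-class]
#' @return a [TrainedStateModel-class] with freshly initialized parameters
#' @export
newStateModel <- function(config) {
  methods::validObject(config)
  methods::new("TrainedStateModel",
    config = config, params = initParams(config, config@seed),
    phase = "random", labelMap = c(control = 0L, disease = 1L),
    trainLog = data.frame())
}

checkEncodings <- function(encodings, config) {
  if (!methods::is(encodings, "RankEncodingSet"))
    stop("encodings must be a RankEncodingSet")
  if (encodings@contextLength > config@contextLength)
    stop("encoding context length (", encodings@contextLength,
         ") exceeds the model context length (", config@contextLength, ")")
  mx <- suppressWarnings(max(vapply(encodings@tokens, function(t)
    if (length(t)) max(t) else 0L, integer(1))))
  if (mx >= config@vocabSize)
    stop("encodings contain token ", mx, " but vocabSize is ",
         config@vocabSize)
}

#' Masked-gene pretraining
#'
#' Trains a fresh encoder on the masked-token objective: 15% of the
#' positions of each encoding (at least one) are replaced by the MASK
#' token and the model is trained to recover the original gene token.
#' Deterministic under the config seed.
#'
#' @param encodings a [RankEncodingSet-class] with at least 100 cells
#' @param config a [ModelConfig-class]
#' @return a [TrainedStateModel-class] with phase `"pretrained"`; the
#'   per-epoch loss trajectory is in `trainLog`
#' @export
pretrainMasked <- function(encodings, config) {
  methods::validObject(config)
  if (length(encodings) < 100)
    stop("masked pretraining requires at least 100 encodings")
  checkEncodings(encodings, config)
  model <- newStateModel(config)
  res <- trainLoop(model@params, config, encodings@tokens, "mlm",
                   epochs = config@epochs,
                   seed = deriveSeed(config@seed, "pretrain"))
  model@params <- res$params
  res$log$startPhase <- "random"
  model@trainLog <- res$log
  model@phase <- "pretrained"
  model
}

#' Fine-tune the two-state classifier
#'
#' Trains the encoder plus a linear head on pooled cell embeddings with
#' weighted cross-entropy (inverse-frequency class weights, so imbalanced
#' training compositions do not swamp the minority class). A stratified
#' validation fraction is held out and its accuracy logged. Starting from
#' phase `"random"` (no pretraining) is permitted and recorded in the
#' training log.
#'
#' @param model a [TrainedStateModel-class] in phase "random" or
#'   "pretrained"
#' @param encodings a [RankEncodingSet-class] carrying condition labels
#'   for both classes
#' @param epochs optional override of `config@epochs`
#' @param valFraction fraction held out for validation logging (0 disables)
#' @return the model with phase `"finetuned"`
#' @export
finetuneClassifier <- function(model, encodings, epochs = NULL,
                               valFraction = 0.1) {
  stopifnot(methods::is(model, "TrainedStateModel"))
  if (model@phase == "finetuned")
    stop("model is already finetuned; phase can only advance random -> pretrained -> finetuned")
  cfg <- model@config
  checkEncodings(encodings, cfg)
  labels <- encodingConditions(encodings)
  if (is.null(labels)) stop("encodings carry no condition labels")
  if (length(unique(labels)) < 2)
    stop("both condition labels must be present in the training data")
  lab01 <- unname(model@labelMap[labels])
  seed <- deriveSeed(cfg@seed, "finetune")
  n <- length(encodings)
  valIdx <- integer(0)
  if (valFraction > 0) {
    valIdx <- withSeed(seed + 1L, unlist(lapply(split(seq_len(n), labels),
      function(ix) sample(ix, max(1L, round(valFraction * length(ix)))))))
  }
  trIdx <- setdiff(seq_len(n), valIdx)
  nc <- table(factor(labels[trIdx], levels = c("control", "disease")))
  classWeights <- as.numeric(sum(nc) / (2 * pmax(nc, 1)))
  res <- trainLoop(model@params, cfg, encodings@tokens[trIdx], "cls",
                   labels01 = lab01[trIdx], classWeights = classWeights,
                   epochs = if (is.null(epochs)) cfg@epochs else epochs,
                   seed = seed)
  model@params <- res$params
  log <- res$log
  log$startPhase <- model@phase
  if (length(valIdx)) {
    valProbs <- predictProbabilities(res$params, cfg,
                                     encodings@tokens[valIdx])
    valAcc <- mean((valProbs[, 2] > 0.5) == (lab01[valIdx] == 1L))
    log <- rbind(log, data.frame(objective = "validation", epoch = NA,
                                 loss = NA, acc = valAcc,
                                 startPhase = model@phase))
  }
  attr(log, "split") <- list(nTrain = length(trIdx), nVal = length(valIdx),
                             classWeights = classWeights)
  model@trainLog <- rbind(model@trainLog,
                          log[setdiff(names(log), character(0))])
  attr(model@trainLog, "split") <- attr(log, "split")
  model@phase <- "finetuned"
  model
}

# Eval-mode pooled embeddings via the compiled forward pass.
pooledEmbeddings <- function(params, cfg, tokens) {
  cpp_encode_pool(params,
                  list(nLayers = cfg@nLayers, nHeads = cfg@nHeads,
                       hiddenDim = cfg@hiddenDim),
                  tokens)
}

# Eval-mode class probabilities for a list of token sequences.
predictProbabilities <- function(params, cfg, tokens) {
  pooled <- pooledEmbeddings(params, cfg, tokens)
  logits <- pooled %*% params$clsW + rep(params$clsB, each = nrow(pooled))
  out <- softmaxRows(logits)
  colnames(out) <- c("p_control", "p_disease")
  out
}

# Assemble a ClassificationReport from truth, predictions and
# probabilities (disease = positive class).
buildClassificationReport <- function(cellIds, labels, predicted, probs,
                                      nExcluded = 0L) {
  lv <- c("control", "disease")
  conf <- table(factor(labels, lv), factor(predicted, lv))
  conf <- matrix(as.integer(conf), 2, 2, dimnames = list(truth = lv,
                                                         predicted = lv))
  acc <- sum(diag(conf)) / sum(conf)
  f1 <- function(tp, fp, fn) if (2 * tp + fp + fn == 0) 0
    else 2 * tp / (2 * tp + fp + fn)
  f1d <- f1(conf[2, 2], conf[1, 2], conf[2, 1])
  f1c <- f1(conf[1, 1], conf[2, 1], conf[1, 2])
  methods::new("ClassificationReport",
    confusion = conf, accuracy = acc, macroF1 = mean(c(f1d, f1c)),
    probabilities = data.frame(cell_id = cellIds,
                               p_control = probs[, 1],
                               p_disease = probs[, 2],
                               label = labels, predicted = predicted,
                               stringsAsFactors = FALSE),
    nExcluded = as.integer(nExcluded))
}

#' Classify cells with a fine-tuned model
#'
#' @param model a [TrainedStateModel-class] with phase `"finetuned"`
#' @param encodings a [RankEncodingSet-class] carrying condition labels
#' @param nExcluded number of cells that were dropped as unencodable
#'   before this call (recorded in the report)
#' @return a [ClassificationReport-class] with confusion matrix
#'   (disease = positive), accuracy, macro-F1 and per-cell class
#'   probabilities
#' @export
classifyCells <- function(model, encodings, nExcluded = 0L) {
  if (model@phase != "finetuned")
    stop("classification requires a finetuned model (phase is '",
         model@phase, "')")
  checkEncodings(encodings, model@config)
  labels <- encodingConditions(encodings)
  if (is.null(labels)) stop("encodings carry no condition labels")
  probs <- predictProbabilities(model@params, model@config,
                                encodings@tokens)
  predicted <- ifelse(probs[, 2] > 0.5, "disease", "control")
  buildClassificationReport(encodings@cellIds, labels, predicted, probs,
                            nExcluded)
}

#' Compute per-cell embeddings
#'
#' The embedding of a cell is the mean of the final encoder layer's hidden
#' states (after the final LayerNorm) over its non-pad positions. Because
#' attention and pooling only ever touch a cell's own real positions, the
#' result is independent of batch composition.
#'
#' @param model a [TrainedStateModel-class] in phase "pretrained" or
#'   "finetuned"
#' @param encodings a [RankEncodingSet-class]
#' @return numeric matrix, one row per cell (rownames = cell ids), d
#'   columns; condition labels, when present, are kept in the
#'   `"condition"` attribute
#' @export
embedCells <- function(model, encodings) {
  if (!model@phase %in% c("pretrained", "finetuned"))
    stop("embeddings require a pretrained or finetuned model")
  checkEncodings(encodings, model@config)
  emb <- pooledEmbeddings(model@params, model@config, encodings@tokens)
  rownames(emb) <- encodings@cellIds
  attr(emb, "condition") <- encodingConditions(encodings)
  emb
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single archive file with the configuration, phase,
#' label map, parameters and training log embedded.
#'
#' @param model a [TrainedStateModel-class]
#' @param file checkpoint path
#' @return `loadStateModel` returns the [TrainedStateModel-class]
#' @export
saveStateModel <- function(model, file) {
  saveRDS(list(config = model@config, params = model@params,
               phase = model@phase, labelMap = model@labelMap,
               trainLog = model@trainLog), file)
  invisible(file)
}

#' @rdname saveStateModel
#' @export
loadStateModel <- function(file) {
  x <- readRDS(file)
  methods::new("TrainedStateModel", config = x$config, params = x$params,
               phase = x$phase, labelMap = x$labelMap,
               trainLog = x$trainLog)
}
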