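#' Assemble and validate a pipeline configuration
#'
#' Bundles every stage's settings: the simulation spec (or a path to an
#' existing corpus directory), the model configuration (built later once
#' the vocabulary size is known), the encoding context length, the
#' perturbation scenarios, the fluctuation settings, the evaluation
#' holdout, the Model-B-style extra-control-cells composition axis, and
#' one global seed from which every stage seed is derived.
#'
#' @param simulation a [SimulationSpec-class], or `NULL` when
#'   `corpusDir` points at an existing corpus
#' @param corpusDir optional directory of an existing corpus (read with
#'   [readCorpus()])
#' @param contextLength encoding context length L
#' @param nLayers,nHeads,hiddenDim,dropout,learningRate,batchSize,epochs
#'   model settings (see [modelConfig()])
#' @param pretrain run masked-gene pretraining before fine-tuning
#' @param holdoutFraction evaluation fraction held out (stratified by
#'   condition) before any training
#' @param extraControlCells extra control cells appended to the training
#'   set only (the imbalanced-composition analogue)
#' @param modes,directions perturbation scenarios to run; directions are
#'   `"control->disease"` and/or `"disease->control"`
#' @param alpha,minCells,maxCellsPerGene candidate selection settings
#' @param fluctuationIterations,fluctuationPercentile,pseudocount
#'   fluctuation-stage settings
#' @param seed global pipeline seed
#' @return a validated configuration list of class `"PipelineConfig"`
#' @export
pipelineConfig <- function(simulation = simulationSpec(),
                           corpusDir = NULL,
                           contextLength = 128L,
                           nLayers = 2L, nHeads = 4L, hiddenDim = 64L,
                           dropout = 0.1, learningRate = 1.5e-3,
                           batchSize = 64L, epochs = 3L,
                           pretrain = FALSE,
                           holdoutFraction = 0.2,
                           extraControlCells = 0L,
                           modes = "delete",
                           directions = "control->disease",
                           alpha = 0.05, minCells = 5L,
                           maxCellsPerGene = 50L,
                           fluctuationIterations = 100L,
                           fluctuationPercentile = 95,
                           pseudocount = 1,
                           seed = 1L) {
  if (is.null(simulation) && is.null(corpusDir))
    stop("either a simulation spec or a corpus directory is required")
  if (!is.null(simulation)) methods::validObject(simulation)
  stopifnot(holdoutFraction > 0, holdoutFraction < 1,
            all(modes %in% c("delete", "overexpress")),
            all(directions %in% c("control->disease", "disease->control")))
  structure(list(
    simulation = simulation, corpusDir = corpusDir,
    contextLength = as.integer(contextLength),
    nLayers = as.integer(nLayers), nHeads = as.integer(nHeads),
    hiddenDim = as.integer(hiddenDim), dropout = dropout,
    learningRate = learningRate, batchSize = as.integer(batchSize),
    epochs = as.integer(epochs), pretrain = isTRUE(pretrain),
    holdoutFraction = holdoutFraction,
    extraControlCells = as.integer(extraControlCells),
    modes = modes, directions = directions, alpha = alpha,
    minCells = as.integer(minCells),
    maxCellsPerGene = as.integer(maxCellsPerGene),
    fluctuationIterations = as.integer(fluctuationIterations),
    fluctuationPercentile = fluctuationPercentile,
    pseudocount = pseudocount, seed = as.integer(seed)),
    class = "PipelineConfig")
}

# Stratified holdout indices (deterministic for a given seed).
stratifiedHoldout <- function(condition, fraction, seed) {
  withSeed(seed, {
    sort(unlist(lapply(split(seq_along(condition), condition), function(ix)
      sample(ix, max(1L, round(fraction * length(ix)))))))
  })
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> hold out evaluation cells -> build vocabulary on
#' the training cells -> encode -> (optionally pretrain) -> fine-tune ->
#' classify the held-out cells -> perturb each requested scenario on the
#' held-out start-condition cells -> rank candidates -> fluctuation
#' analysis. All artifacts (corpus, vocabulary TSV, model checkpoint,
#' classification JSON/TSV, candidate tables, fluctuation JSON/TSV, run
#' log) are written under `outDir`. Stage seeds are derived
#' deterministically from the global seed, so re-running a config
#' reproduces the run.
#'
#' @param config a `"PipelineConfig"` (see [pipelineConfig()])
#' @param outDir output directory
#' @param writeArtifacts write stage artifacts to `outDir` (set `FALSE`
#'   for purely in-memory runs)
#' @return invisibly, a list with the corpus, vocabulary, model, report,
#'   per-scenario ranked candidates, and the fluctuation result
#' @export
runPipeline <- function(config, outDir = tempfile("pipeline"),
                        writeArtifacts = TRUE) {
  stopifnot(inherits(config, "PipelineConfig"))
  if (writeArtifacts) dir.create(outDir, recursive = TRUE,
                                 showWarnings = FALSE)
  logLines <- character()
  stage <- function(name, expr) {
    logLines <<- c(logLines, paste0(format(Sys.time(), "%H:%M:%S"),
                                    " stage: ", name))
    tryCatch(expr, error = function(e) {
      logLines <<- c(logLines, paste0("ERROR in stage '", name, "': ",
                                      conditionMessage(e)))
      if (writeArtifacts)
        writeLines(logLines, file.path(outDir, "run_log.txt"))
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  seedOf <- function(name) deriveSeed(config$seed, name)

  corpus <- stage("corpus", {
    if (!is.null(config$corpusDir)) readCorpus(config$corpusDir)
    else {
      sp <- config$simulation
      sp@seed <- seedOf("simulate")
      simulateCorpus(sp)
    }
  })
  extra <- NULL
  if (config$extraControlCells > 0) {
    extra <- stage("extra-controls", {
      sp <- config$simulation
      if (is.null(sp)) stop("extra control cells require a simulation spec")
      spx <- simulationSpec(
        nCellsControl = config$extraControlCells, nCellsDisease = 1,
        nGenes = sp@nGenes, nDriverGenes = sp@nDriverGenes,
        driverLog2fc = sp@driverLog2fc,
        baselineMeanLog = sp@baselineMeanLog,
        nbDispersion = sp@nbDispersion,
        librarySizeLog = sp@librarySizeLog,
        seed = seedOf("extra-controls"))
      x <- simulateCorpus(spx)
      x[, conditionLabels(x) == "control"]
    })
  }
  cond <- conditionLabels(corpus)
  evalIdx <- stratifiedHoldout(cond, config$holdoutFraction,
                               seedOf("holdout"))
  trainIdx <- setdiff(seq_len(ncol(corpus)), evalIdx)
  trainCorpus <- corpus[, trainIdx]
  if (!is.null(extra)) {
    cts <- cbind(SummarizedExperiment::assay(trainCorpus, "counts"),
                 SummarizedExperiment::assay(extra, "counts"))
    colnames(cts) <- make.unique(colnames(cts))
    trainCorpus <- expressionCorpus(
      cts, c(conditionLabels(trainCorpus), conditionLabels(extra)))
  }
  vocab <- stage("vocabulary", buildVocabulary(trainCorpus))
  L <- config$contextLength
  trainEnc <- stage("encode-train", encodeCorpus(trainCorpus, vocab, L))
  evalEnc <- stage("encode-eval", encodeCorpus(corpus, vocab, L,
                                               cells = evalIdx))
  cfg <- modelConfig(vocabSize = max(tokenIds(vocab)) + 1L,
                     nLayers = config$nLayers, nHeads = config$nHeads,
                     hiddenDim = config$hiddenDim, contextLength = L,
                     dropout = config$dropout,
                     learningRate = config$learningRate,
                     batchSize = config$batchSize, epochs = config$epochs,
                     seed = seedOf("model"))
  model <- stage("train", {
    m <- if (config$pretrain) pretrainMasked(trainEnc, cfg)
      else newStateModel(cfg)
    finetuneClassifier(m, trainEnc)
  })
  nDroppedEval <- length(attr(evalEnc, "dropped"))
  report <- stage("classify", classifyCells(model, evalEnc,
                                            nExcluded = nDroppedEval))
  evalEmb <- stage("embed", embedCells(model, evalEnc))
  evalCond <- encodingConditions(evalEnc)
  genes <- stage("gene-universe", genesExpressedInBoth(corpus))
  drivers <- driverGenes(corpus)
  scenarios <- list()
  for (mode in config$modes) for (dirn in config$directions) {
    startLabel <- sub("->.*", "", dirn)
    goalLabel <- sub(".*->", "", dirn)
    key <- paste0(mode, "_", startLabel, "_to_", goalLabel)
    scenarios[[key]] <- stage(paste0("perturb-", key), {
      goal <- computeGoalState(evalEmb[evalCond == goalLabel, ,
                                       drop = FALSE], goalLabel)
      startEnc <- evalEnc[which(evalCond == startLabel)]
      pr <- perturbCorpus(model, startEnc, genes, mode, goal, vocab,
                          minCells = config$minCells,
                          maxCellsPerGene = config$maxCellsPerGene,
                          seed = seedOf(paste0("perturb-", key)))
      rankCandidates(pr, alpha = config$alpha)
    })
  }
  fluct <- stage("fluctuation", fluctuationAnalysis(
    corpus, nIterations = config$fluctuationIterations,
    percentile = config$fluctuationPercentile,
    pseudocount = config$pseudocount, seed = seedOf("fluctuation")))

  if (writeArtifacts) stage("artifacts", {
    if (is.null(config$corpusDir))
      writeCorpus(corpus, file.path(outDir, "corpus"))
    writeVocabulary(vocab, file.path(outDir, "vocabulary.tsv"))
    saveStateModel(model, file.path(outDir, "model_checkpoint.rds"))
    jsonlite::write_json(
      list(accuracy = accuracy(report), macro_f1 = macroF1(report),
           confusion = confusionMatrix(report),
           n_excluded = report@nExcluded),
      file.path(outDir, "classification_report.json"), digits = NA)
    write.table(classProbabilities(report),
                file.path(outDir, "probabilities.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (key in names(scenarios))
      writeCandidateTable(scenarios[[key]],
                          file.path(outDir, paste0("candidates_", key, ".tsv")),
                          driverGenes = if (length(drivers)) drivers else NULL)
    writeFluctuationResult(fluct, file.path(outDir, "fluctuation.json"),
                           file.path(outDir, "fluctuation.tsv"))
    cfgOut <- config
    cfgOut$simulation <- if (is.null(config$simulation)) NULL else
      S4Vectors::metadata(corpus)$simulationSpec
    jsonlite::write_json(cfgOut, file.path(outDir, "config.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
    logLines <- c(logLines, paste0("seeds: global=", config$seed))
    writeLines(logLines, file.path(outDir, "run_log.txt"))
  })
  invisible(list(corpus = corpus, vocabulary = vocab, model = model,
                 report = report, scenarios = scenarios,
                 fluctuation = fluct, evalIdx = evalIdx,
                 outDir = if (writeArtifacts) outDir else NULL))
}

#' Compare training-set compositions on a common held-out set
#'
#' Runs one pipeline per configuration and tabulates accuracy and macro-F1
#' on the evaluation split. All configurations must share the evaluation
#' split definition (same base simulation, holdout fraction and global
#' seed); only training composition settings may differ. Descriptive only:
#' no significance testing is performed.
#'
#' @param configs a list of `"PipelineConfig"` objects
#' @return data.frame with one row per composition
#' @export
compareCompositions <- function(configs) {
  if (length(configs) < 2) stop("at least two configurations are required")
  key <- function(cf) list(sim = if (is.null(cf$simulation)) cf$corpusDir
                           else list(cf$simulation@nCellsControl,
                                     cf$simulation@nCellsDisease,
                                     cf$simulation@nGenes,
                                     cf$simulation@nDriverGenes,
                                     cf$simulation@driverLog2fc,
                                     cf$simulation@seed),
                           holdout = cf$holdoutFraction, seed = cf$seed)
  k1 <- key(configs[[1]])
  for (cf in configs[-1])
    if (!identical(key(cf), k1))
      stop("all configurations must share the evaluation split definition")
  rows <- lapply(seq_along(configs), function(i) {
    res <- runPipeline(configs[[i]], writeArtifacts = FALSE)
    data.frame(composition = i,
               extra_control_cells = configs[[i]]$extraControlCells,
               pretrain = configs[[i]]$pretrain,
               n_eval = sum(confusionMatrix(res$report)),
               accuracy = accuracy(res$report),
               macro_f1 = macroF1(res$report))
  })
  do.call(rbind, rows)
}
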