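#' @import methods
#' @importFrom stats median quantile rnbinom rlnorm runif p.adjust wilcox.test setNames
#' @importFrom utils head read.delim write.table
#' @importClassesFrom SingleCellExperiment SingleCellExperiment
#' @importFrom Rcpp sourceCpp
#' @useDynLib scStatePerturb, .registration = TRUE
NULL

#' Simulation specification for a two-condition synthetic corpus
#'
#' Holds all parameters of the negative-binomial corpus simulator:
#' cell numbers per condition, gene number, the planted driver set size and
#' its log2 effect, the log-normal distribution of per-gene baseline means,
#' the negative-binomial dispersion (the `size` parameter of
#' [stats::rnbinom()]: variance = mu + mu^2/size), the log-normal per-cell
#' library-size factor, and the simulation seed.
#'
#' Driver genes are *higher in control* by `driverLog2fc` log2 units, so
#' deleting them from control cells is expected to move embeddings toward
#' the disease state.
#'
#' @slot nCellsControl number of control cells (>= 1)
#' @slot nCellsDisease number of disease cells (>= 1)
#' @slot nGenes number of genes (>= 1)
#' @slot nDriverGenes number of planted driver genes (>= 0, <= nGenes)
#' @slot driverLog2fc planted log2 effect size (finite; control / disease)
#' @slot baselineMeanLog length-2 numeric `c(meanlog, sdlog)` of the
#'   log-normal per-gene baseline mean
#' @slot nbDispersion NB size parameter (> 0)
#' @slot librarySizeLog length-2 numeric `c(meanlog, sdlog)` of the
#'   log-normal per-cell depth factor
#' @slot seed integer simulation seed
#' @exportClass SimulationSpec
setClass("SimulationSpec",
  representation(
    nCellsControl = "integer",
    nCellsDisease = "integer",
    nGenes = "integer",
    nDriverGenes = "integer",
    driverLog2fc = "numeric",
    baselineMeanLog = "numeric",
    nbDispersion = "numeric",
    librarySizeLog = "numeric",
    seed = "integer"
  )
)

setValidity("SimulationSpec", function(object) {
  chk <- function(cond, field, msg) if (!cond) paste0("invalid '", field, "': ", msg) else NULL
  errs <- c(
    chk(length(object@nCellsControl) == 1 && object@nCellsControl >= 1L,
        "nCellsControl", "must be a single integer >= 1"),
    chk(length(object@nCellsDisease) == 1 && object@nCellsDisease >= 1L,
        "nCellsDisease", "must be a single integer >= 1"),
    chk(length(object@nGenes) == 1 && object@nGenes >= 1L,
        "nGenes", "must be a single integer >= 1"),
    chk(length(object@nDriverGenes) == 1 && object@nDriverGenes >= 0L,
        "nDriverGenes", "must be a single integer >= 0"),
    chk(object@nDriverGenes <= object@nGenes,
        "nDriverGenes", "must not exceed nGenes"),
    chk(length(object@driverLog2fc) == 1 && is.finite(object@driverLog2fc),
        "driverLog2fc", "must be a single finite number"),
    chk(length(object@baselineMeanLog) == 2 && all(is.finite(object@baselineMeanLog)) &&
          object@baselineMeanLog[2] >= 0,
        "baselineMeanLog", "must be finite c(meanlog, sdlog) with sdlog >= 0"),
    chk(length(object@nbDispersion) == 1 && is.finite(object@nbDispersion) &&
          object@nbDispersion > 0,
        "nbDispersion", "must be a single number > 0"),
    chk(length(object@librarySizeLog) == 2 && all(is.finite(object@librarySizeLog)) &&
          object@librarySizeLog[2] >= 0,
        "librarySizeLog", "must be finite c(meanlog, sdlog) with sdlog >= 0"),
    chk(length(object@seed) == 1 && !is.na(object@seed),
        "seed", "must be a single integer")
  )
  if (length(errs)) errs else TRUE
})

#' Two-condition expression corpus
#'
#' An [SingleCellExperiment::SingleCellExperiment] with a `counts` assay
#' (genes as rows, cells as columns), a `condition` column in `colData`
#' restricted to the two states `"control"` and `"disease"`, and, for
#' simulated corpora, planted-driver ground truth in
#' `metadata(x)$groundTruth` (`driverGenes`, `driverLog2fc`).
#'
#' @exportClass ExpressionCorpus
setClass("ExpressionCorpus", contains = "SingleCellExperiment")

setValidity("ExpressionCorpus", function(object) {
  errs <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    errs <- c(errs, "assay 'counts' is required")
  else {
    cts <- SummarizedExperiment::assay(object, "counts")
    v <- if (methods::is(cts, "sparseMatrix")) cts@x else as.numeric(cts)
    if (length(v) && (any(v < 0) || any(v != round(v))))
      errs <- c(errs, "counts must be non-negative integers")
  }
  if (!"condition" %in% colnames(SummarizedExperiment::colData(object)))
    errs <- c(errs, "colData column 'condition' is required")
  else {
    cond <- as.character(object$condition)
    if (!all(cond %in% c("control", "disease")))
      errs <- c(errs, "condition labels must be 'control' or 'disease'")
  }
  gt <- S4Vectors::metadata(object)$groundTruth
  if (!is.null(gt) && !all(gt$driverGenes %in% rownames(object)))
    errs <- c(errs, "groundTruth driver genes must be a subset of gene ids")
  if (length(errs)) errs else TRUE
})

#' Gene token vocabulary with nonzero-median normalization factors
#'
#' Maps gene ids to integer tokens (token 0 = PAD and token 1 = MASK are
#' reserved; gene tokens start at 2, assigned in lexicographic order of
#' gene id) and stores, per gene, the nonzero median across the reference
#' corpus of the gene's depth-normalized expression. Genes never expressed
#' in the reference corpus are excluded.
#'
#' @slot geneIds character vector of gene ids
#' @slot tokenIds integer tokens, parallel to `geneIds`
#' @slot normFactors positive normalization factors, parallel to `geneIds`
#' @exportClass GeneVocabulary
setClass("GeneVocabulary",
  representation(geneIds = "character", tokenIds = "integer",
                 normFactors = "numeric"))

setValidity("GeneVocabulary", function(object) {
  errs <- character()
  n <- length(object@geneIds)
  if (length(object@tokenIds) != n || length(object@normFactors) != n)
    errs <- c(errs, "geneIds, tokenIds and normFactors must have equal length")
  if (anyDuplicated(object@tokenIds)) errs <- c(errs, "token ids must be unique")
  if (anyDuplicated(object@geneIds)) errs <- c(errs, "gene ids must be unique")
  if (length(object@tokenIds) && min(object@tokenIds) < 2L)
    errs <- c(errs, "gene tokens must be >= 2 (0/1 are reserved)")
  if (any(!is.finite(object@normFactors)) || any(object@normFactors <= 0))
    errs <- c(errs, "every normalization factor must be finite and > 0")
  if (length(errs)) errs else TRUE
})

#' A set of per-cell rank encodings
#'
#' Each element of `tokens` is one cell's ordered gene-token sequence,
#' highest normalized expression first, truncated to `contextLength`.
#' Encodings contain only expressed vocabulary genes, never reserved
#' tokens, and never duplicates.
#'
#' @slot tokens list of integer vectors
#' @slot cellIds character, parallel to `tokens`
#' @slot condition character labels parallel to `tokens` (may be empty)
#' @slot contextLength maximum encoding length L
#' @exportClass RankEncodingSet
setClass("RankEncodingSet",
  representation(tokens = "list", cellIds = "character",
                 condition = "character", contextLength = "integer"))

setValidity("RankEncodingSet", function(object) {
  errs <- character()
  if (length(object@tokens) != length(object@cellIds))
    errs <- c(errs, "tokens and cellIds must have equal length")
  if (length(object@condition) &&
      length(object@condition) != length(object@tokens))
    errs <- c(errs, "condition must be empty or parallel to tokens")
  L <- object@contextLength
  bad <- vapply(object@tokens, function(tk)
    anyDuplicated(tk) > 0L || (length(tk) && min(tk) < 2L) || length(tk) > L,
    logical(1))
  if (any(bad))
    errs <- c(errs, "encodings must be duplicate-free, contain no reserved tokens, and respect contextLength")
  if (length(errs)) errs else TRUE
})

#' Transformer model configuration
#'
#' @slot nLayers number of encoder layers
#' @slot nHeads attention heads (must divide `hiddenDim`)
#' @slot hiddenDim model width d
#' @slot contextLength maximum sequence length L
#' @slot vocabSize embedding-table size (>= max token + 1)
#' @slot dropout dropout rate in `[0, 1)`
#' @slot learningRate Adam learning rate
#' @slot batchSize minibatch size
#' @slot epochs training epochs
#' @slot seed training seed
#' @exportClass ModelConfig
setClass("ModelConfig",
  representation(nLayers = "integer", nHeads = "integer", hiddenDim = "integer",
                 contextLength = "integer", vocabSize = "integer",
                 dropout = "numeric", learningRate = "numeric",
                 batchSize = "integer", epochs = "integer", seed = "integer"))

setValidity("ModelConfig", function(object) {
  errs <- character()
  if (object@hiddenDim %% object@nHeads != 0L)
    errs <- c(errs, "hiddenDim must be divisible by nHeads")
  if (object@dropout < 0 || object@dropout >= 1)
    errs <- c(errs, "dropout must be in [0, 1)")
  if (object@nLayers < 1L || object@nHeads < 1L || object@hiddenDim < 1L ||
      object@contextLength < 1L || object@vocabSize < 3L ||
      object@batchSize < 1L || object@epochs < 1L)
    errs <- c(errs, "nLayers, nHeads, hiddenDim, contextLength, batchSize, epochs must be >= 1 and vocabSize >= 3")
  if (object@learningRate <= 0) errs <- c(errs, "learningRate must be > 0")
  if (length(errs)) errs else TRUE
})

#' Trained transformer state model
#'
#' @slot config the [ModelConfig-class]
#' @slot params named list of parameter matrices/vectors
#' @slot phase one of `"random"`, `"pretrained"`, `"finetuned"`
#' @slot labelMap named integer vector `c(control = 0L, disease = 1L)`
#' @slot trainLog data.frame of per-epoch losses/metrics accumulated over
#'   training phases
#' @exportClass TrainedStateModel
setClass("TrainedStateModel",
  representation(config = "ModelConfig", params = "list", phase = "character",
                 labelMap = "integer", trainLog = "data.frame"))

setValidity("TrainedStateModel", function(object) {
  errs <- character()
  if (!object@phase %in% c("random", "pretrained", "finetuned"))
    errs <- c(errs, "phase must be 'random', 'pretrained' or 'finetuned'")
  if (length(object@labelMap) != 2L ||
      !setequal(names(object@labelMap), c("control", "disease")))
    errs <- c(errs, "labelMap must name exactly 'control' and 'disease'")
  if (length(errs)) errs else TRUE
})

#' Two-class cell classification report
#'
#' Disease is the positive class of the confusion matrix.
#'
#' @slot confusion 2x2 integer matrix (rows = truth, cols = predicted,
#'   order control, disease)
#' @slot accuracy overall accuracy
#' @slot macroF1 macro-averaged F1 over the two classes
#' @slot probabilities data.frame with cell_id, p_control, p_disease,
#'   label, predicted
#' @slot nExcluded number of cells excluded as unencodable
#' @exportClass ClassificationReport
setClass("ClassificationReport",
  representation(confusion = "matrix", accuracy = "numeric",
                 macroF1 = "numeric", probabilities = "data.frame",
                 nExcluded = "integer"))

#' Goal state for perturbation scoring
#'
#' The centroid (arithmetic mean) of the embeddings of the cells in the
#' target condition.
#'
#' @slot label target condition label
#' @slot centroid numeric embedding centroid of length d
#' @slot nCells number of cells averaged
#' @exportClass GoalState
setClass("GoalState",
  representation(label = "character", centroid = "numeric",
                 nCells = "integer"))

setValidity("GoalState", function(object) {
  if (object@nCells < 1L) "nCells must be >= 1"
  else if (!length(object@centroid) || any(!is.finite(object@centroid)))
    "centroid must be a finite numeric vector"
  else TRUE
})

#' Result of an in-silico perturbation scan
#'
#' One row of `records` per tested gene: mode, direction, number of
#' eligible (scored) cells, mean cosine shift toward the goal centroid.
#' Per-cell shift distributions are kept in `shifts` for the significance
#' step. Genes with fewer than `minCells` eligible cells are retained with
#' `excluded = TRUE` and `NA` shift.
#'
#' @slot records data.frame (gene_id, mode, direction, n_cells,
#'   shift_to_goal_end, excluded)
#' @slot shifts named list of per-cell shift vectors
#' @slot mode `"delete"` or `"overexpress"`
#' @slot direction e.g. `"control->disease"`
#' @slot goalLabel goal condition label
#' @slot params list of scan parameters (minCells, maxCellsPerGene, seed)
#' @exportClass PerturbationResult
setClass("PerturbationResult",
  representation(records = "data.frame", shifts = "list", mode = "character",
                 direction = "character", goalLabel = "character",
                 params = "list"))

#' Natural-fluctuation permutation result
#'
#' @slot background genes x iterations matrix of background log2 fold
#'   changes from random equal splits of control cells
#' @slot threshold non-negative magnitude of the +/- fluctuation bound
#' @slot percentile percentile used
#' @slot convention `"absolute"` (percentile of pooled |log2FC|) or
#'   `"signed"` (symmetric bound covering the two-tailed signed interval)
#' @slot observed named per-gene observed log2FC (disease vs control)
#' @slot exceeds named logical, `|observed| > threshold`
#' @slot foldExcess named numeric, `|observed| / threshold`
#' @slot nIterations number of permutation iterations
#' @slot seed permutation seed
#' @exportClass FluctuationResult
setClass("FluctuationResult",
  representation(background = "matrix", threshold = "numeric",
                 percentile = "numeric", convention = "character",
                 observed = "numeric", exceeds = "logical",
                 foldExcess = "numeric", nIterations = "integer",
                 seed = "integer"))
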