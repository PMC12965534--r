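#' Planted driver genes of a corpus
#'
#' @param x an [ExpressionCorpus-class]
#' @return character vector of driver gene ids (possibly empty)
#' @export
setGeneric("driverGenes", function(x) standardGeneric("driverGenes"))

#' @rdname driverGenes
#' @export
setMethod("driverGenes", "ExpressionCorpus", function(x) {
  gt <- S4Vectors::metadata(x)$groundTruth
  if (is.null(gt)) character() else gt$driverGenes
})

#' Condition labels of a corpus
#'
#' @param x an [ExpressionCorpus-class]
#' @return character vector, one of "control"/"disease" per cell
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))

#' @rdname conditionLabels
#' @export
setMethod("conditionLabels", "ExpressionCorpus",
          function(x) as.character(x$condition))

#' @export
#' @rdname vocabularyAccessors
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @export
#' @rdname vocabularyAccessors
setGeneric("tokenIds", function(x) standardGeneric("tokenIds"))

#' @export
#' @rdname vocabularyAccessors
setGeneric("normFactors", function(x) standardGeneric("normFactors"))

#' Accessors for GeneVocabulary
#'
#' `geneIds()`, `tokenIds()` and `normFactors()` return the parallel
#' vectors of a [GeneVocabulary-class]; `geneToken()` maps gene ids to
#' tokens (error on unknown genes); `tokenGene()` is the inverse.
#'
#' @param x a [GeneVocabulary-class]
#' @param gene,token gene id(s) / token(s) to map
#' @name vocabularyAccessors
NULL

#' @rdname vocabularyAccessors
#' @export
setMethod("geneIds", "GeneVocabulary", function(x) x@geneIds)

#' @rdname vocabularyAccessors
#' @export
setMethod("tokenIds", "GeneVocabulary", function(x) x@tokenIds)

#' @rdname vocabularyAccessors
#' @export
setMethod("normFactors", "GeneVocabulary",
          function(x) setNames(x@normFactors, x@geneIds))

#' @rdname vocabularyAccessors
#' @export
geneToken <- function(x, gene) {
  idx <- match(gene, x@geneIds)
  if (anyNA(idx))
    stop("gene(s) not in vocabulary: ",
         paste(gene[is.na(idx)], collapse = ", "))
  x@tokenIds[idx]
}

#' @rdname vocabularyAccessors
#' @export
tokenGene <- function(x, token) {
  idx <- match(token, x@tokenIds)
  if (anyNA(idx))
    stop("token(s) not in vocabulary: ",
         paste(token[is.na(idx)], collapse = ", "))
  x@geneIds[idx]
}

#' Model phase accessor
#' @param x a [TrainedStateModel-class]
#' @return one of "random", "pretrained", "finetuned"
#' @export
setGeneric("modelPhase", function(x) standardGeneric("modelPhase"))

#' @rdname modelPhase
#' @export
setMethod("modelPhase", "TrainedStateModel", function(x) x@phase)

#' Accessors for classification reports and fluctuation results
#'
#' @param x a [ClassificationReport-class] or [FluctuationResult-class]
#' @name resultAccessors
NULL

#' @rdname resultAccessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))

#' @rdname resultAccessors
#' @export
setMethod("accuracy", "ClassificationReport", function(x) x@accuracy)

#' @rdname resultAccessors
#' @export
setGeneric("macroF1", function(x) standardGeneric("macroF1"))

#' @rdname resultAccessors
#' @export
setMethod("macroF1", "ClassificationReport", function(x) x@macroF1)

#' @rdname resultAccessors
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' @rdname resultAccessors
#' @export
setMethod("confusionMatrix", "ClassificationReport", function(x) x@confusion)

#' @rdname resultAccessors
#' @export
setGeneric("classProbabilities", function(x) standardGeneric("classProbabilities"))

#' @rdname resultAccessors
#' @export
setMethod("classProbabilities", "ClassificationReport",
          function(x) x@probabilities)

#' @rdname resultAccessors
#' @export
setGeneric("fluctuationThreshold", function(x) standardGeneric("fluctuationThreshold"))

#' @rdname resultAccessors
#' @export
setMethod("fluctuationThreshold", "FluctuationResult", function(x) x@threshold)

#' Perturbation records accessor
#' @param x a [PerturbationResult-class]
#' @return data.frame of per-gene records
#' @export
setGeneric("perturbationRecords", function(x) standardGeneric("perturbationRecords"))

#' @rdname perturbationRecords
#' @export
setMethod("perturbationRecords", "PerturbationResult", function(x) x@records)

#' Per-gene shift distributions accessor
#' @param x a [PerturbationResult-class]
#' @return named list of per-cell shift vectors
#' @export
setGeneric("perturbationShifts", function(x) standardGeneric("perturbationShifts"))

#' @rdname perturbationShifts
#' @export
setMethod("perturbationShifts", "PerturbationResult", function(x) x@shifts)

setMethod("show", "GeneVocabulary", function(object) {
  cat("GeneVocabulary with", length(object@geneIds), "genes",
      "(tokens", if (length(object@tokenIds)) min(object@tokenIds) else NA,
      "-", if (length(object@tokenIds)) max(object@tokenIds) else NA, ")\n")
})

setMethod("show", "RankEncodingSet", function(object) {
  lens <- lengths(object@tokens)
  cat("RankEncodingSet:", length(object@tokens), "cells, L =",
      object@contextLength, "\n")
  if (length(lens))
    cat("  encoding lengths: min", min(lens), "median", median(lens),
        "max", max(lens), "\n")
})

setMethod("show", "TrainedStateModel", function(object) {
  cfg <- object@config
  cat("TrainedStateModel (phase:", object@phase, ")\n")
  cat("  layers:", cfg@nLayers, " heads:", cfg@nHeads,
      " d:", cfg@hiddenDim, " L:", cfg@contextLength,
      " vocab:", cfg@vocabSize, "\n")
})

setMethod("show", "ClassificationReport", function(object) {
  cat("ClassificationReport on", sum(object@confusion), "cells\n")
  cat("  accuracy:", round(object@accuracy, 4),
      " macro-F1:", round(object@macroF1, 4), "\n")
  print(object@confusion)
})

setMethod("show", "PerturbationResult", function(object) {
  cat("PerturbationResult:", object@mode, object@direction, "\n")
  cat("  genes tested:", sum(!object@records$excluded),
      " excluded:", sum(object@records$excluded), "\n")
})

setMethod("show", "FluctuationResult", function(object) {
  cat("FluctuationResult:", object@nIterations, "iterations,",
      object@percentile, "th percentile (", object@convention, ")\n")
  cat("  threshold: +/-", round(object@threshold, 4), "\n")
  if (length(object@observed))
    cat("  genes exceeding threshold:", sum(object@exceeds), "of",
        length(object@observed), "\n")
})

#' Number of cells in a rank-encoding set
#' @param x a [RankEncodingSet-class]
#' @export
setMethod("length", "RankEncodingSet", function(x) length(x@tokens))

#' Subset a rank-encoding set by cell index or id
#' @param x a [RankEncodingSet-class]
#' @param i indices or cell ids
#' @param j,drop,... ignored
#' @export
setMethod("[", "RankEncodingSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, x@cellIds)
  methods::new("RankEncodingSet",
    tokens = x@tokens[i], cellIds = x@cellIds[i],
    condition = if (length(x@condition)) x@condition[i] else character(),
    contextLength = x@contextLength)
})

#' Cell ids of a rank-encoding set
#' @param x a [RankEncodingSet-class]
#' @export
encodingCellIds <- function(x) x@cellIds

#' Token sequences of a rank-encoding set
#' @param x a [RankEncodingSet-class]
#' @return named list of integer token vectors
#' @export
encodingTokens <- function(x) setNames(x@tokens, x@cellIds)

#' Condition labels carried by a rank-encoding set
#' @param x a [RankEncodingSet-class]
#' @export
encodingConditions <- function(x)
  if (length(x@condition)) setNames(x@condition, x@cellIds) else NULL
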