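#' In-silico deletion of a gene from a rank encoding
#'
#' Removes the gene's token from the ordered sequence, preserving the
#' relative order of all other tokens. If the gene is not expressed in the
#' cell (token absent) the cell is ineligible for this perturbation and
#' `NULL` is returned (a "skip", distinct from the error raised for genes
#' missing from the vocabulary altogether).
#'
#' @param encoding integer token vector (one cell's rank encoding)
#' @param gene gene id to delete
#' @param vocabulary a [GeneVocabulary-class]
#' @return the shortened encoding, or `NULL` when the gene is absent from
#'   the cell
#' @export
deleteGene <- function(encoding, gene, vocabulary) {
  tok <- geneToken(vocabulary, gene)
  pos <- match(tok, encoding)
  if (is.na(pos)) return(NULL)
  encoding[-pos]
}

#' In-silico overexpression of a gene in a rank encoding
#'
#' Moves the gene's token to the top of the ranking (position 1). A gene
#' not expressed in the cell is inserted at the front and the sequence is
#' truncated back to the context length; a gene already present is moved,
#' all other tokens keeping their relative order. The result never
#' contains duplicates.
#'
#' @param encoding integer token vector
#' @param gene gene id to overexpress
#' @param vocabulary a [GeneVocabulary-class]
#' @param L context length bound applied after insertion
#' @return the perturbed encoding
#' @export
overexpressGene <- function(encoding, gene, vocabulary, L = 128L) {
  tok <- geneToken(vocabulary, gene)
  pos <- match(tok, encoding)
  if (!is.na(pos)) c(tok, encoding[-pos])
  else head(c(tok, encoding), L)
}

#' Goal state from the embeddings of the target condition's cells
#'
#' @param embeddings numeric matrix of cell embeddings (rows = cells of
#'   the goal condition)
#' @param label the goal condition label
#' @return a [GoalState-class] whose centroid is the arithmetic mean of
#'   the embeddings
#' @export
computeGoalState <- function(embeddings, label) {
  embeddings <- rbind(embeddings)
  if (nrow(embeddings) < 1) stop("goal state requires at least one cell")
  methods::new("GoalState", label = as.character(label),
               centroid = colMeans(embeddings),
               nCells = nrow(embeddings))
}

#' Cosine shift of an embedding toward a goal state
#'
#' `cos(perturbed, centroid) - cos(original, centroid)`, bounded in
#' `[-2, 2]`. Errors on zero-norm vectors.
#'
#' @param original,perturbed embedding vectors of length d
#' @param goal a [GoalState-class]
#' @return a scalar shift
#' @export
shiftToGoal <- function(original, perturbed, goal) {
  cosineSim(perturbed, goal@centroid) - cosineSim(original, goal@centroid)
}

#' Scan a gene list by in-silico perturbation
#'
#' For each gene, perturbs the rank encodings of the start-condition cells
#' (deletion: only cells expressing the gene are eligible; overexpression:
#' all cells), re-embeds the perturbed cells, and records the mean cosine
#' shift of their embeddings toward the goal centroid. Genes with fewer
#' than `minCells` eligible cells are reported as excluded. To keep the
#' scan desk-scale, at most `maxCellsPerGene` eligible cells per gene are
#' scored (a seeded subsample).
#'
#' @param model a [TrainedStateModel-class] (pretrained or finetuned)
#' @param encodings start-condition cells as a [RankEncodingSet-class]
#' @param genes gene ids to perturb (conventionally genes expressed in at
#'   least one cell of each condition; see [genesExpressedInBoth()])
#' @param mode `"delete"` or `"overexpress"`
#' @param goal a [GoalState-class]
#' @param vocabulary the frozen [GeneVocabulary-class]
#' @param minCells minimum eligible cells for a gene to be tested
#' @param maxCellsPerGene cap on scored cells per gene
#' @param seed seed for the per-gene cell subsample
#' @return a [PerturbationResult-class]
#' @export
perturbCorpus <- function(model, encodings, genes, mode = c("delete", "overexpress"),
                          goal, vocabulary, minCells = 5L,
                          maxCellsPerGene = 50L, seed = 1L) {
  mode <- match.arg(mode)
  if (!model@phase %in% c("pretrained", "finetuned"))
    stop("perturbation requires a pretrained or finetuned model")
  if (!length(genes)) stop("empty gene list")
  if (!length(encodings)) stop("no start-condition cells to perturb")
  startLabel <- unique(encodingConditions(encodings))
  direction <- paste0(
    if (length(startLabel) == 1) startLabel else "mixed", "->", goal@label)
  L <- encodings@contextLength
  tokensOf <- encodings@tokens
  originalEmb <- embedCells(model, encodings)
  geneTok <- geneToken(vocabulary, genes)

  # assemble every (gene, cell) perturbed encoding, then embed in batches
  perturbedTokens <- list()
  owner <- list()  # per gene: indices into perturbedTokens + cell indices
  withSeed(seed, {
    for (gi in seq_along(genes)) {
      tok <- geneTok[gi]
      eligible <- if (mode == "delete")
        which(vapply(tokensOf, function(tk) tok %in% tk, logical(1)))
      else seq_along(tokensOf)
      nEligible <- length(eligible)
      if (nEligible > maxCellsPerGene)
        eligible <- sort(sample(eligible, maxCellsPerGene))
      if (nEligible < minCells) {
        owner[[gi]] <- list(cells = integer(0), nEligible = nEligible)
        next
      }
      pert <- lapply(tokensOf[eligible], function(tk) {
        if (mode == "delete") tk[-match(tok, tk)]
        else if (tok %in% tk) c(tok, tk[-match(tok, tk)])
        else head(c(tok, tk), L)
      })
      keep <- lengths(pert) > 0  # deletion of a cell's only gene
      at <- length(perturbedTokens) + seq_len(sum(keep))
      perturbedTokens <- c(perturbedTokens, pert[keep])
      owner[[gi]] <- list(cells = eligible[keep], rows = at,
                          nEligible = nEligible)
    }
  })
  pertEmb <- if (length(perturbedTokens)) {
    es <- methods::new("RankEncodingSet", tokens = perturbedTokens,
                       cellIds = sprintf("p%06d", seq_along(perturbedTokens)),
                       condition = character(), contextLength = L)
    embedCells(model, es)
  } else matrix(0, 0, model@config@hiddenDim)

  cosGoal <- function(M) {
    cn <- goal@centroid / sqrt(sum(goal@centroid^2))
    as.numeric(M %*% cn) / sqrt(rowSums(M * M))
  }
  cosOrig <- cosGoal(originalEmb)
  cosPert <- cosGoal(pertEmb)
  shifts <- vector("list", length(genes))
  names(shifts) <- genes
  rec <- data.frame(gene_id = genes, mode = mode, direction = direction,
                    n_cells = 0L, n_cells_eligible = 0L,
                    shift_to_goal_end = NA_real_,
                    excluded = TRUE, stringsAsFactors = FALSE)
  for (gi in seq_along(genes)) {
    ow <- owner[[gi]]
    rec$n_cells_eligible[gi] <- ow$nEligible
    rec$n_cells[gi] <- length(ow$cells)
    if (!length(ow$cells)) next
    sh <- cosPert[ow$rows] - cosOrig[ow$cells]
    shifts[[gi]] <- sh
    rec$shift_to_goal_end[gi] <- mean(sh)
    rec$excluded[gi] <- FALSE
  }
  if (all(rec$excluded))
    stop("no eligible cells corpus-wide for any tested gene")
  methods::new("PerturbationResult", records = rec, shifts = shifts,
               mode = mode, direction = direction, goalLabel = goal@label,
               params = list(minCells = as.integer(minCells),
                             maxCellsPerGene = as.integer(maxCellsPerGene),
                             seed = as.integer(seed),
                             goalNCells = goal@nCells))
}

#' Genes expressed in at least one cell of each condition
#'
#' The conventional perturbation gene universe: genes with a nonzero count
#' in at least one control cell and at least one disease cell.
#'
#' @param corpus an [ExpressionCorpus-class]
#' @return character vector of gene ids
#' @export
genesExpressedInBoth <- function(corpus) {
  cts <- SummarizedExperiment::assay(corpus, "counts")
  cond <- conditionLabels(corpus)
  inCtrl <- Matrix::rowSums(cts[, cond == "control", drop = FALSE] > 0) > 0
  inDis <- Matrix::rowSums(cts[, cond == "disease", drop = FALSE] > 0) > 0
  rownames(cts)[inCtrl & inDis]
}

#' Rank candidate disease-related genes
#'
#' Per tested gene, a two-sided Wilcoxon rank-sum test compares its
#' per-cell shift distribution against the pooled per-cell shifts of all
#' tested genes (the aggregate null); p-values are Benjamini-Hochberg
#' adjusted across the tested genes. Candidates are the genes with a
#' positive `shift_to_goal_end` and FDR below `alpha`, ordered by shift
#' descending with ties broken by FDR ascending.
#'
#' @param result a [PerturbationResult-class]
#' @param alpha FDR threshold for candidate selection
#' @return list with `candidates` (the filtered, ordered data.frame) and
#'   `tested` (all tested genes with p_value and fdr columns)
#' @export
rankCandidates <- function(result, alpha = 0.05) {
  stopifnot(methods::is(result, "PerturbationResult"))
  rec <- result@records[!result@records$excluded, , drop = FALSE]
  if (nrow(rec) < 2)
    stop("at least 2 tested genes are required to form the aggregate null")
  sh <- result@shifts[rec$gene_id]
  pooled <- unlist(sh, use.names = FALSE)
  rec$p_value <- vapply(sh, function(s) {
    # a fully tied comparison (e.g. a constant-embedding model) carries no
    # evidence against the aggregate null
    if (length(unique(c(s, pooled))) == 1) return(1)
    p <- suppressWarnings(wilcox.test(s, pooled, exact = FALSE)$p.value)
    if (is.na(p)) 1 else p
  }, numeric(1))
  rec$fdr <- p.adjust(rec$p_value, method = "BH")
  tested <- rec[order(-rec$shift_to_goal_end, rec$fdr), , drop = FALSE]
  rownames(tested) <- NULL
  cand <- tested[tested$shift_to_goal_end > 0 & tested$fdr < alpha, ,
                 drop = FALSE]
  rownames(cand) <- NULL
  list(candidates = cand, tested = tested,
       params = c(result@params, list(alpha = alpha)))
}

#' Write a candidate table and its scenario metadata
#'
#' TSV columns: gene_id, mode, direction, n_cells, shift_to_goal_end,
#' p_value, fdr and, when planted ground truth is supplied,
#' is_planted_driver. A JSON metadata file is written alongside.
#'
#' @param ranked output of [rankCandidates()]
#' @param file TSV path (metadata goes to `<file>.meta.json`)
#' @param driverGenes optional planted-driver gene ids
#' @export
writeCandidateTable <- function(ranked, file, driverGenes = NULL) {
  tab <- ranked$candidates
  keep <- c("gene_id", "mode", "direction", "n_cells",
            "shift_to_goal_end", "p_value", "fdr")
  tab <- tab[, keep, drop = FALSE]
  if (!is.null(driverGenes))
    tab$is_planted_driver <- tab$gene_id %in% driverGenes
  write.table(tab, file, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(ranked$params, paste0(file, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(file)
}
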