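#' Build a gene token vocabulary with nonzero-median normalization
#'
#' For each gene expressed in at least one reference cell, the
#' normalization factor is the median, across cells with a nonzero count,
#' of the gene's depth-normalized expression (count / cell total counts).
#' Dividing by this factor before ranking deprioritizes ubiquitously
#' highly expressed genes, so the top of a cell's ranking reflects genes
#' unusually high *for that gene*. Tokens 0 and 1 are reserved (PAD, MASK);
#' gene tokens start at 2 in lexicographic order of gene id. Genes with
#' zero counts in every reference cell are excluded.
#'
#' @param corpus reference [ExpressionCorpus-class] (typically the
#'   training corpus; the vocabulary is then frozen)
#' @return a [GeneVocabulary-class]
#' @examples
#' corpus <- simulateCorpus(simulationSpec(50, 50, 40, 0))
#' vocab <- buildVocabulary(corpus)
#' @export
buildVocabulary <- function(corpus) {
  stopifnot(methods::is(corpus, "ExpressionCorpus"))
  cts <- methods::as(SummarizedExperiment::assay(corpus, "counts"),
                     "CsparseMatrix")
  if (length(cts@x) == 0 || all(cts@x == 0)) stop("no expressed genes")
  tot <- Matrix::colSums(cts)
  trip <- Matrix::summary(cts)
  trip <- trip[trip$x > 0, , drop = FALSE]
  norm <- trip$x / tot[trip$j]
  med <- tapply(norm, trip$i, median)
  geneIdx <- as.integer(names(med))
  genes <- rownames(cts)[geneIdx]
  ord <- order(genes)
  methods::new("GeneVocabulary",
    geneIds = genes[ord],
    tokenIds = seq_along(ord) + 1L,
    normFactors = as.numeric(med)[ord])
}

#' Rank-encode a single cell
#'
#' Scores each expressed vocabulary gene as
#' `(count / cell total counts) / normalization_factor`, sorts tokens by
#' score descending (ties broken by ascending token id, for determinism),
#' and truncates to the first `L` tokens. Genes absent from the vocabulary
#' are dropped; a cell with no expressed vocabulary gene raises an
#' `unencodableCell` error.
#'
#' @param cellCounts named numeric vector of counts for one cell (names =
#'   gene ids), or an unnamed vector parallel to the vocabulary genes
#' @param vocabulary a [GeneVocabulary-class]
#' @param L context length (maximum encoding length), >= 1
#' @return integer vector of gene tokens, highest score first
#' @examples
#' vocab <- new("GeneVocabulary", geneIds = c("A", "B", "C"),
#'              tokenIds = 2:4, normFactors = c(1, 0.25, 0.5))
#' rankEncode(c(A = 10, B = 5, C = 5), vocab, L = 8)  # B, A, C
#' @export
rankEncode <- function(cellCounts, vocabulary, L = 128L) {
  if (L < 1) stop("context length L must be >= 1")
  if (is.null(names(cellCounts))) {
    if (length(cellCounts) != length(vocabulary@geneIds))
      stop("unnamed cellCounts must be parallel to the vocabulary genes")
    names(cellCounts) <- vocabulary@geneIds
  }
  total <- sum(cellCounts)
  idx <- match(names(cellCounts), vocabulary@geneIds)
  keep <- !is.na(idx) & cellCounts > 0
  if (total == 0 || !any(keep)) {
    cond <- structure(
      class = c("unencodableCell", "error", "condition"),
      list(message = "unencodable cell: no expressed vocabulary gene",
           call = sys.call()))
    stop(cond)
  }
  vi <- idx[keep]
  score <- (cellCounts[keep] / total) / vocabulary@normFactors[vi]
  tok <- vocabulary@tokenIds[vi]
  ord <- order(-score, tok)
  unname(head(tok[ord], L))
}

#' Rank-encode every cell of a corpus
#'
#' Applies [rankEncode()] with a frozen vocabulary to all cells (or a
#' subset). Unencodable cells (no expressed vocabulary gene) are dropped
#' with a message; their ids are recorded in the `dropped` attribute.
#'
#' @param corpus an [ExpressionCorpus-class]
#' @param vocabulary a [GeneVocabulary-class]
#' @param L context length
#' @param cells optional cell ids or indices to encode
#' @return a [RankEncodingSet-class] carrying condition labels
#' @export
encodeCorpus <- function(corpus, vocabulary, L = 128L, cells = NULL) {
  cts <- methods::as(SummarizedExperiment::assay(corpus, "counts"),
                     "CsparseMatrix")
  if (!is.null(cells)) {
    if (is.character(cells)) cells <- match(cells, colnames(cts))
    cts <- cts[, cells, drop = FALSE]
    cond <- conditionLabels(corpus)[cells]
  } else cond <- conditionLabels(corpus)
  vidx <- match(rownames(cts), vocabulary@geneIds)
  tokOfRow <- vocabulary@tokenIds[vidx]
  facOfRow <- vocabulary@normFactors[vidx]
  tot <- Matrix::colSums(cts)
  p <- cts@p; i <- cts@i; x <- cts@x
  enc <- vector("list", ncol(cts))
  ok <- logical(ncol(cts))
  for (c in seq_len(ncol(cts))) {
    if (p[c + 1] == p[c] || tot[c] == 0) next
    rng <- (p[c] + 1):p[c + 1]
    rows <- i[rng] + 1L
    vals <- x[rng]
    keep <- !is.na(tokOfRow[rows]) & vals > 0
    if (!any(keep)) next
    rows <- rows[keep]; vals <- vals[keep]
    score <- (vals / tot[c]) / facOfRow[rows]
    tok <- tokOfRow[rows]
    ord <- order(-score, tok)
    enc[[c]] <- head(tok[ord], L)
    ok[c] <- TRUE
  }
  if (any(!ok))
    message(sum(!ok), " unencodable cell(s) dropped")
  res <- methods::new("RankEncodingSet",
    tokens = enc[ok], cellIds = colnames(cts)[ok],
    condition = as.character(cond)[ok], contextLength = as.integer(L))
  attr(res, "dropped") <- colnames(cts)[!ok]
  res
}

#' Serialize / deserialize a vocabulary as TSV
#'
#' Columns: gene_id, token_id, normalization_factor (with header).
#'
#' @param vocabulary a [GeneVocabulary-class]
#' @param file path to write / read
#' @return `readVocabulary` returns a [GeneVocabulary-class]
#' @export
writeVocabulary <- function(vocabulary, file) {
  df <- data.frame(gene_id = vocabulary@geneIds,
                   token_id = vocabulary@tokenIds,
                   normalization_factor = vocabulary@normFactors)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname writeVocabulary
#' @export
readVocabulary <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  methods::new("GeneVocabulary",
    geneIds = as.character(df$gene_id),
    tokenIds = as.integer(df$token_id),
    normFactors = as.numeric(df$normalization_factor))
}
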