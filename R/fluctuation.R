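#' Per-gene log2 fold change between two cell groups
#'
#' Counts are depth-normalized to counts per 10,000 per cell; the log2
#' fold change of a gene is
#' `log2((mean CP10K in A + pseudocount) / (mean CP10K in B + pseudocount))`.
#'
#' @param countsA,countsB genes x cells count matrices for the two groups
#'   (same genes, same order)
#' @param pseudocount added to both group means before the ratio
#' @return named numeric vector of per-gene log2 fold changes (A over B)
#' @export
log2FoldChange <- function(countsA, countsB, pseudocount = 1) {
  if (ncol(countsA) < 1 || ncol(countsB) < 1)
    stop("both groups must contain at least one cell")
  if (nrow(countsA) != nrow(countsB))
    stop("the two groups must cover the same genes")
  mA <- Matrix::rowMeans(cp10k(countsA))
  mB <- Matrix::rowMeans(cp10k(countsB))
  setNames(log2((mA + pseudocount) / (mB + pseudocount)), rownames(countsA))
}

#' Permutation background of log2 fold changes
#'
#' Randomly splits the control cells into two equal groups (for odd n,
#' sizes floor(n/2) and ceiling(n/2)) `nIterations` times and records the
#' per-gene log2 fold change of each split. This is the natural-fluctuation
#' background against which observed changes are calibrated.
#'
#' @param counts genes x cells count matrix of control cells (>= 4 cells)
#' @param nIterations number of random splits
#' @param pseudocount passed to [log2FoldChange()]
#' @param seed split seed
#' @return genes x iterations matrix of background log2 fold changes
#' @export
permuteBackground <- function(counts, nIterations = 100L, pseudocount = 1,
                              seed = 1L) {
  n <- ncol(counts)
  if (n < 4) stop("at least 4 control cells are required")
  if (nIterations < 1) stop("nIterations must be >= 1")
  half <- n %/% 2
  withSeed(seed, {
    bg <- vapply(seq_len(nIterations), function(i) {
      grpA <- sample.int(n, half)
      log2FoldChange(counts[, grpA, drop = FALSE],
                     counts[, -grpA, drop = FALSE], pseudocount)
    }, numeric(nrow(counts)))
  })
  rownames(bg) <- rownames(counts)
  colnames(bg) <- paste0("iter", seq_len(nIterations))
  bg
}

#' Natural-fluctuation threshold from a permutation background
#'
#' With the default `"absolute"` convention the threshold is the given
#' percentile of the pooled `|log2FC|` values across all genes and
#' iterations (the symmetric +/- bound within which random equal splits
#' fall that fraction of the time). The `"signed"` convention instead
#' takes the symmetric bound covering the central two-tailed signed
#' interval (e.g. the 2.5th/97.5th percentiles for 95). Percentiles use
#' the linear-interpolation convention ([stats::quantile()] type 7).
#'
#' @param background matrix or vector of background log2 fold changes
#' @param percentile coverage percentile in (0, 100)
#' @param convention `"absolute"` or `"signed"`
#' @return the non-negative threshold magnitude, with the convention and
#'   percentile recorded as attributes
#' @export
estimateThreshold <- function(background, percentile = 95,
                              convention = c("absolute", "signed")) {
  convention <- match.arg(convention)
  v <- as.numeric(background)
  if (!length(v)) stop("background is empty")
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must be inside (0, 100)")
  thr <- if (convention == "absolute")
    unname(quantile(abs(v), percentile / 100, type = 7))
  else {
    tail <- (100 - percentile) / 200
    q <- quantile(v, c(tail, 1 - tail), type = 7)
    max(abs(q))
  }
  structure(thr, percentile = percentile, convention = convention)
}

#' Exceedance call and fold-excess for observed log2 fold changes
#'
#' A gene exceeds the natural-fluctuation zone when `|observed|` is
#' strictly greater than the threshold; its fold-excess is
#' `|observed| / threshold`.
#'
#' @param observed per-gene observed log2 fold change (may be named)
#' @param threshold positive threshold magnitude
#' @return data.frame with observed_log2fc, exceeds, fold_excess
#' @examples
#' assessGene(0.85, 0.68)  # exceeds, fold-excess 1.25
#' @export
assessGene <- function(observed, threshold) {
  if (length(threshold) != 1 || !is.finite(threshold) || threshold <= 0)
    stop("degenerate background: threshold must be a single value > 0")
  data.frame(gene_id = if (is.null(names(observed)))
               rep(NA_character_, length(observed)) else names(observed),
             observed_log2fc = as.numeric(observed),
             exceeds = abs(observed) > threshold,
             fold_excess = abs(observed) / threshold,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Full natural-fluctuation analysis of a corpus
#'
#' Estimates the permutation threshold from the control cells and assesses
#' the observed disease-vs-control log2 fold change of every gene against
#' it.
#'
#' @param corpus an [ExpressionCorpus-class] containing both conditions
#' @param nIterations,percentile,pseudocount,convention,seed see
#'   [permuteBackground()] and [estimateThreshold()]
#' @return a [FluctuationResult-class]
#' @export
fluctuationAnalysis <- function(corpus, nIterations = 100L, percentile = 95,
                                pseudocount = 1,
                                convention = c("absolute", "signed"),
                                seed = 1L) {
  convention <- match.arg(convention)
  cts <- SummarizedExperiment::assay(corpus, "counts")
  cond <- conditionLabels(corpus)
  ctrl <- cts[, cond == "control", drop = FALSE]
  dis <- cts[, cond == "disease", drop = FALSE]
  bg <- permuteBackground(ctrl, nIterations, pseudocount, seed)
  thr <- estimateThreshold(bg, percentile, convention)
  observed <- if (ncol(dis))
    log2FoldChange(dis, ctrl, pseudocount) else setNames(numeric(0), NULL)
  assess <- if (length(observed)) assessGene(observed, as.numeric(thr))
    else data.frame(exceeds = logical(0), fold_excess = numeric(0))
  methods::new("FluctuationResult",
    background = bg, threshold = as.numeric(thr),
    percentile = percentile, convention = convention,
    observed = observed,
    exceeds = setNames(assess$exceeds, names(observed)),
    foldExcess = setNames(assess$fold_excess, names(observed)),
    nIterations = as.integer(nIterations), seed = as.integer(seed))
}

#' Write a fluctuation result as JSON + per-gene TSV
#'
#' @param result a [FluctuationResult-class]
#' @param jsonFile path for the summary JSON (threshold, percentile,
#'   convention, n_iterations, seed)
#' @param tsvFile path for the per-gene TSV (gene_id, observed_log2fc,
#'   exceeds, fold_excess); skipped when no observed values exist
#' @export
writeFluctuationResult <- function(result, jsonFile, tsvFile = NULL) {
  jsonlite::write_json(
    list(threshold = result@threshold, percentile = result@percentile,
         convention = result@convention,
         n_iterations = result@nIterations, seed = result@seed),
    jsonFile, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsvFile) && length(result@observed)) {
    df <- data.frame(gene_id = names(result@observed),
                     observed_log2fc = as.numeric(result@observed),
                     exceeds = as.logical(result@exceeds),
                     fold_excess = as.numeric(result@foldExcess))
    write.table(df, tsvFile, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(jsonFile)
}
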