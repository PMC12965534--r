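#' Create a simulation specification
#'
#' Defaults describe the standard desk-scale study corpus: 1000 + 1000
#' cells, 300 genes, 10 planted drivers at a log2 effect of 2 (drivers are
#' higher in control), per-gene baseline means drawn log-normal(1, 1),
#' negative-binomial dispersion (size) 2, and log-normal(0, 0.3) per-cell
#' library-size factors.
#'
#' @param nCellsControl,nCellsDisease cells per condition
#' @param nGenes number of genes
#' @param nDriverGenes number of planted driver genes
#' @param driverLog2fc planted log2 fold change (control over disease)
#' @param baselineMeanLog `c(meanlog, sdlog)` of per-gene baseline means
#' @param nbDispersion negative-binomial size parameter
#'   (variance = mu + mu^2 / size)
#' @param librarySizeLog `c(meanlog, sdlog)` of per-cell depth factors
#' @param seed simulation seed
#' @return a validated [SimulationSpec-class]
#' @examples
#' spec <- simulationSpec(nCellsControl = 50, nCellsDisease = 50,
#'                        nGenes = 40, nDriverGenes = 4)
#' corpus <- simulateCorpus(spec)
#' @export
simulationSpec <- function(nCellsControl = 1000, nCellsDisease = 1000,
                           nGenes = 300, nDriverGenes = 10,
                           driverLog2fc = 2,
                           baselineMeanLog = c(1, 1),
                           nbDispersion = 2,
                           librarySizeLog = c(0, 0.3),
                           seed = 1L) {
  methods::new("SimulationSpec",
    nCellsControl = asCount(nCellsControl, "nCellsControl"),
    nCellsDisease = asCount(nCellsDisease, "nCellsDisease"),
    nGenes = asCount(nGenes, "nGenes"),
    nDriverGenes = asCount(nDriverGenes, "nDriverGenes"),
    driverLog2fc = as.numeric(driverLog2fc),
    baselineMeanLog = as.numeric(baselineMeanLog),
    nbDispersion = as.numeric(nbDispersion),
    librarySizeLog = as.numeric(librarySizeLog),
    seed = as.integer(seed))
}

#' Simulate a two-condition corpus with planted driver genes
#'
#' Counts are negative-binomial with per-gene baseline means mu_g drawn
#' log-normal and a per-cell library-size factor s_c applied
#' multiplicatively to the mean before sampling. For the planted drivers
#' the control-condition mean is `2^driverLog2fc * mu_g` while the disease
#' mean stays `mu_g`; non-driver genes are identically distributed across
#' conditions. The same spec (including seed) always yields a bit-identical
#' corpus.
#'
#' @param spec a [SimulationSpec-class]
#' @return an [ExpressionCorpus-class]; planted drivers are recorded in
#'   `metadata(x)$groundTruth`
#' @export
simulateCorpus <- function(spec) {
  stopifnot(methods::is(spec, "SimulationSpec"))
  methods::validObject(spec)
  nGenes <- spec@nGenes
  nCells <- spec@nCellsControl + spec@nCellsDisease
  geneIds <- sprintf("gene%04d", seq_len(nGenes))
  cellIds <- sprintf("cell%05d", seq_len(nCells))
  condition <- rep(c("control", "disease"),
                   c(spec@nCellsControl, spec@nCellsDisease))
  withSeed(spec@seed, {
    baseMu <- rlnorm(nGenes, spec@baselineMeanLog[1], spec@baselineMeanLog[2])
    drivers <- if (spec@nDriverGenes > 0)
      sort(sample.int(nGenes, spec@nDriverGenes)) else integer()
    libFactor <- rlnorm(nCells, spec@librarySizeLog[1], spec@librarySizeLog[2])
    # genes x cells mean matrix: baseline, driver boost in control only
    mu <- matrix(baseMu, nGenes, nCells)
    if (length(drivers))
      mu[drivers, condition == "control"] <-
        mu[drivers, condition == "control"] * 2^spec@driverLog2fc
    mu <- t(t(mu) * libFactor)
    counts <- matrix(rnbinom(nGenes * nCells, mu = as.numeric(mu),
                             size = spec@nbDispersion),
                     nGenes, nCells, dimnames = list(geneIds, cellIds))
  })
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                       "CsparseMatrix")),
    colData = S4Vectors::DataFrame(condition = condition, row.names = cellIds))
  S4Vectors::metadata(sce)$groundTruth <- list(
    driverGenes = geneIds[drivers], driverLog2fc = spec@driverLog2fc)
  S4Vectors::metadata(sce)$simulationSpec <- list(
    nCellsControl = spec@nCellsControl, nCellsDisease = spec@nCellsDisease,
    nGenes = nGenes, nDriverGenes = spec@nDriverGenes,
    driverLog2fc = spec@driverLog2fc,
    baselineMeanLog = spec@baselineMeanLog,
    nbDispersion = spec@nbDispersion,
    librarySizeLog = spec@librarySizeLog, seed = spec@seed)
  methods::as(sce, "ExpressionCorpus")
}

#' Assemble an ExpressionCorpus from components
#'
#' @param counts genes x cells matrix of non-negative integers
#' @param condition per-cell labels, "control" or "disease"
#' @param driverGenes optional planted-driver gene ids
#' @param driverLog2fc optional planted effect size
#' @return an [ExpressionCorpus-class]
#' @export
expressionCorpus <- function(counts, condition, driverGenes = NULL,
                             driverLog2fc = NA_real_) {
  counts <- toCountsMatrix(counts)
  sce <- SingleCellExperiment::SingleCellExperiment(
    assays = list(counts = counts),
    colData = S4Vectors::DataFrame(condition = as.character(condition),
                                   row.names = colnames(counts)))
  if (!is.null(driverGenes))
    S4Vectors::metadata(sce)$groundTruth <- list(
      driverGenes = driverGenes, driverLog2fc = driverLog2fc)
  methods::as(sce, "ExpressionCorpus")
}

#' Write a corpus as Matrix Market plus TSV sidecars
#'
#' Writes `matrix.mtx` (genes as rows, cells as columns, 10x convention),
#' `barcodes.tsv` (one cell id per line), `features.tsv` (gene id TAB gene
#' name), `labels.tsv` (cell id TAB condition) and, when planted ground
#' truth is present, `ground_truth.tsv` (gene id TAB log2fc). All TSVs are
#' UTF-8 and headerless.
#'
#' @param corpus an [ExpressionCorpus-class]
#' @param directory output directory (created if needed)
#' @return the directory, invisibly
#' @export
writeCorpus <- function(corpus, directory) {
  stopifnot(methods::is(corpus, "ExpressionCorpus"))
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  cts <- SummarizedExperiment::assay(corpus, "counts")
  Matrix::writeMM(methods::as(cts, "CsparseMatrix"),
                  file.path(directory, "matrix.mtx"))
  writeLines(colnames(corpus), file.path(directory, "barcodes.tsv"))
  writeLines(paste(rownames(corpus), rownames(corpus), sep = "\t"),
             file.path(directory, "features.tsv"))
  writeLines(paste(colnames(corpus), conditionLabels(corpus), sep = "\t"),
             file.path(directory, "labels.tsv"))
  gt <- S4Vectors::metadata(corpus)$groundTruth
  if (!is.null(gt) && length(gt$driverGenes))
    writeLines(paste(gt$driverGenes, gt$driverLog2fc, sep = "\t"),
               file.path(directory, "ground_truth.tsv"))
  invisible(directory)
}

#' Read a corpus written by [writeCorpus()]
#'
#' Validates dimensions against the sidecar files and the label alphabet;
#' parse problems name the offending file (and line where known).
#'
#' @param directory directory containing matrix.mtx, barcodes.tsv,
#'   features.tsv and labels.tsv
#' @return an [ExpressionCorpus-class]
#' @export
readCorpus <- function(directory) {
  need <- c("matrix.mtx", "barcodes.tsv", "features.tsv", "labels.tsv")
  missing <- need[!file.exists(file.path(directory, need))]
  if (length(missing))
    stop("corpus directory is missing: ", paste(missing, collapse = ", "))
  mtxFile <- file.path(directory, "matrix.mtx")
  cts <- tryCatch(toCountsMatrix(Matrix::readMM(mtxFile)),
                  error = function(e)
                    stop("malformed MTX file '", mtxFile, "': ",
                         conditionMessage(e), call. = FALSE))
  barcodes <- readLines(file.path(directory, "barcodes.tsv"))
  featLines <- readLines(file.path(directory, "features.tsv"))
  features <- vapply(strsplit(featLines, "\t", fixed = TRUE), `[`, "", 1)
  if (length(features) != nrow(cts))
    stop("features.tsv has ", length(features), " rows but '", mtxFile,
         "' declares ", nrow(cts), " genes")
  if (length(barcodes) != ncol(cts))
    stop("barcodes.tsv has ", length(barcodes), " rows but '", mtxFile,
         "' declares ", ncol(cts), " cells")
  dimnames(cts) <- list(features, barcodes)
  labLines <- readLines(file.path(directory, "labels.tsv"))
  labParts <- strsplit(labLines, "\t", fixed = TRUE)
  bad <- which(lengths(labParts) != 2)
  if (length(bad))
    stop("labels.tsv line ", bad[1], ": expected 'cell_id<TAB>condition'")
  labCells <- vapply(labParts, `[`, "", 1)
  labVals <- vapply(labParts, `[`, "", 2)
  badVal <- which(!labVals %in% c("control", "disease"))
  if (length(badVal))
    stop("labels.tsv line ", badVal[1], ": unknown label '",
         labVals[badVal[1]], "' (expected 'control' or 'disease')")
  idx <- match(barcodes, labCells)
  if (anyNA(idx))
    stop("labels.tsv is missing labels for ", sum(is.na(idx)),
         " cell(s), first: '", barcodes[which(is.na(idx))[1]], "'")
  gtFile <- file.path(directory, "ground_truth.tsv")
  drivers <- NULL; fc <- NA_real_
  if (file.exists(gtFile)) {
    gtParts <- strsplit(readLines(gtFile), "\t", fixed = TRUE)
    drivers <- vapply(gtParts, `[`, "", 1)
    fc <- as.numeric(vapply(gtParts, `[`, "", 2))[1]
  }
  expressionCorpus(cts, labVals[idx], driverGenes = drivers,
                   driverLog2fc = fc)
}
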