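# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-stage seed derived from a base seed and a stage name.
# Keeps results independent across stages while reproducible end to end.
deriveSeed <- function(baseSeed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(baseSeed) * 7919 + h) %% 2147483587)
}

cosineSim <- function(a, b) {
  na <- sqrt(sum(a * a)); nb <- sqrt(sum(b * b))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero-norm vector")
  sum(a * b) / (na * nb)
}

# counts-per-10k depth normalization of a genes x cells matrix
cp10k <- function(counts) {
  tot <- Matrix::colSums(counts)
  if (any(tot == 0)) stop("cannot depth-normalize cells with zero total counts")
  if (methods::is(counts, "Matrix"))
    Matrix::t(Matrix::t(counts) / tot) * 1e4
  else t(t(counts) / tot) * 1e4
}

# Coerce any matrix-like input (incl. pattern/logical sparse matrices read
# from MTX) to a numeric dgC sparse matrix.
toCountsMatrix <- function(x) {
  if (!methods::is(x, "Matrix")) x <- Matrix::Matrix(x, sparse = TRUE)
  methods::as(methods::as(methods::as(x, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

asCount <- function(x, field) {
  if (length(x) != 1 || is.na(x) || x < 0 || x != round(x))
    stop("invalid '", field, "': must be a single non-negative integer", call. = FALSE)
  as.integer(x)
}
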