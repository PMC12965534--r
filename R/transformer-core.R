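# Transformer encoder over rank encodings: pure matrix-op forward pass and
# manually derived backpropagation. Pre-LayerNorm blocks (LN -> multi-head
# self-attention -> residual; LN -> GELU feed-forward -> residual), a final
# LayerNorm, learned token + position embeddings, Adam updates.
#
# Sequences are grouped row-wise: a batch of B cells padded to the batch
# maximum length M lives in a (B*M) x d matrix, cell c occupying rows
# (c-1)*M + 1 .. (c-1)*M + len_c. Attention, pooling and the losses only
# touch the first len_c rows of each block, so padding never leaks into
# any output or gradient (this is what makes embeddings batch-invariant).

LN_EPS <- 1e-5
FF_MULT <- 2L  # feed-forward width = FF_MULT * hiddenDim

initParams <- function(cfg, seed) {
  d <- cfg@hiddenDim; V <- cfg@vocabSize; L <- cfg@contextLength
  ff <- FF_MULT * d
  rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 0.02), nr, nc)
  withSeed(seed, {
    p <- list(tok = rmat(V, d), pos = rmat(L, d))
    for (l in seq_len(cfg@nLayers)) {
      pre <- paste0("l", l, "_")
      p[[paste0(pre, "ln1g")]] <- rep(1, d)
      p[[paste0(pre, "ln1b")]] <- rep(0, d)
      for (w in c("Wq", "Wk", "Wv", "Wo")) p[[paste0(pre, w)]] <- rmat(d, d)
      for (b in c("bq", "bk", "bv", "bo")) p[[paste0(pre, b)]] <- rep(0, d)
      p[[paste0(pre, "ln2g")]] <- rep(1, d)
      p[[paste0(pre, "ln2b")]] <- rep(0, d)
      p[[paste0(pre, "W1")]] <- rmat(d, ff)
      p[[paste0(pre, "b1")]] <- rep(0, ff)
      p[[paste0(pre, "W2")]] <- rmat(ff, d)
      p[[paste0(pre, "b2")]] <- rep(0, d)
    }
    p$lnfg <- rep(1, d); p$lnfb <- rep(0, d)
    p$mlmW <- rmat(d, V); p$mlmB <- rep(0, V)
    p$clsW <- rmat(d, 2L); p$clsB <- rep(0, 2L)
    p
  })
}

lnForward <- function(X, g, b) {
  n <- nrow(X)
  mu <- rowMeans(X)
  xc <- X - mu
  invstd <- 1 / sqrt(rowMeans(xc * xc) + LN_EPS)
  xhat <- xc * invstd
  list(Y = xhat * rep(g, each = n) + rep(b, each = n),
       xhat = xhat, invstd = invstd)
}

lnBackward <- function(dY, cache, g) {
  xhat <- cache$xhat
  dxhat <- dY * rep(g, each = nrow(dY))
  dX <- cache$invstd *
    (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat))
  list(dX = dX, dg = colSums(dY * xhat), db = colSums(dY))
}

# feed-forward activation: ReLU (cheap elementwise, standard choice)
reluForward <- function(x) x * (x > 0)

reluBackward <- function(dY, x) dY * (x > 0)

softmaxRows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

# rowRanges[[c]] = integer vector of the real (non-pad) flat row indices
# of cell c; precomputed once per batch.
batchLayout <- function(lens, M) {
  B <- length(lens)
  lapply(seq_len(B), function(c) ((c - 1L) * M + 1L):((c - 1L) * M + lens[c]))
}

# Forward through the encoder. tokens: list of integer token vectors.
# Returns final hidden states H ((B*M) x d, post final-LN) plus caches
# needed for the backward pass when training = TRUE.
encForward <- function(params, cfg, tokens, dropout = 0, training = FALSE) {
  B <- length(tokens)
  lens <- lengths(tokens)
  if (any(lens > cfg@contextLength))
    stop("encoding longer than the model context length")
  if (any(lens == 0)) stop("empty encoding cannot be embedded")
  M <- max(lens)
  d <- cfg@hiddenDim; H <- cfg@nHeads; dh <- d %/% H
  flatTok <- integer(B * M)  # 0 = PAD
  for (c in seq_len(B)) flatTok[((c - 1) * M + 1):((c - 1) * M + lens[c])] <-
    tokens[[c]]
  posIdx <- rep(seq_len(M), times = B)
  X <- params$tok[flatTok + 1L, , drop = FALSE] +
    params$pos[posIdx, , drop = FALSE]
  rows <- batchLayout(lens, M)
  headCols <- lapply(seq_len(H), function(h) ((h - 1) * dh + 1):(h * dh))
  caches <- vector("list", cfg@nLayers)
  useDrop <- training && dropout > 0
  for (l in seq_len(cfg@nLayers)) {
    pre <- paste0("l", l, "_")
    ln1 <- lnForward(X, params[[paste0(pre, "ln1g")]],
                     params[[paste0(pre, "ln1b")]])
    Q <- ln1$Y %*% params[[paste0(pre, "Wq")]] +
      rep(params[[paste0(pre, "bq")]], each = B * M)
    K <- ln1$Y %*% params[[paste0(pre, "Wk")]] +
      rep(params[[paste0(pre, "bk")]], each = B * M)
    Vv <- ln1$Y %*% params[[paste0(pre, "Wv")]] +
      rep(params[[paste0(pre, "bv")]], each = B * M)
    O <- matrix(0, B * M, d)
    A <- vector("list", B * H)
    for (c in seq_len(B)) {
      rc <- rows[[c]]
      for (h in seq_len(H)) {
        hc <- headCols[[h]]
        S <- tcrossprod(Q[rc, hc, drop = FALSE],
                        K[rc, hc, drop = FALSE]) / sqrt(dh)
        Ach <- softmaxRows(S)
        A[[(c - 1) * H + h]] <- Ach
        O[rc, hc] <- Ach %*% Vv[rc, hc, drop = FALSE]
      }
    }
    attnOut <- O %*% params[[paste0(pre, "Wo")]] +
      rep(params[[paste0(pre, "bo")]], each = B * M)
    dm1 <- NULL
    if (useDrop) {
      dm1 <- matrix(runif(length(attnOut)) >= dropout, B * M, d) /
        (1 - dropout)
      attnOut <- attnOut * dm1
    }
    X1 <- X + attnOut
    ln2 <- lnForward(X1, params[[paste0(pre, "ln2g")]],
                     params[[paste0(pre, "ln2b")]])
    A1 <- ln2$Y %*% params[[paste0(pre, "W1")]] +
      rep(params[[paste0(pre, "b1")]], each = B * M)
    G <- reluForward(A1)
    F2 <- G %*% params[[paste0(pre, "W2")]] +
      rep(params[[paste0(pre, "b2")]], each = B * M)
    dm2 <- NULL
    if (useDrop) {
      dm2 <- matrix(runif(length(F2)) >= dropout, B * M, d) / (1 - dropout)
      F2 <- F2 * dm2
    }
    Xout <- X1 + F2
    if (training)
      caches[[l]] <- list(X = X, ln1 = ln1, Q = Q, K = K, V = Vv, A = A,
                          O = O, dm1 = dm1, X1 = X1, ln2 = ln2, A1 = A1,
                          G = G, dm2 = dm2)
    X <- Xout
  }
  lnf <- lnForward(X, params$lnfg, params$lnfb)
  list(H = lnf$Y, lnf = lnf, Xpre = X, caches = caches, lens = lens, M = M,
       rows = rows, flatTok = flatTok, posIdx = posIdx, B = B)
}

# Backward pass given dH (gradient on the post-final-LN hidden states).
# Returns a named list of gradients matching the encoder parameters.
encBackward <- function(dH, fw, params, cfg) {
  B <- fw$B; M <- fw$M
  d <- cfg@hiddenDim; H <- cfg@nHeads; dh <- d %/% H
  rows <- fw$rows
  headCols <- lapply(seq_len(H), function(h) ((h - 1) * dh + 1):(h * dh))
  g <- list()
  lb <- lnBackward(dH, fw$lnf, params$lnfg)
  g$lnfg <- lb$dg; g$lnfb <- lb$db
  dX <- lb$dX
  for (l in rev(seq_len(cfg@nLayers))) {
    pre <- paste0("l", l, "_")
    cc <- fw$caches[[l]]
    dF2 <- dX
    if (!is.null(cc$dm2)) dF2 <- dF2 * cc$dm2
    g[[paste0(pre, "b2")]] <- colSums(dF2)
    g[[paste0(pre, "W2")]] <- crossprod(cc$G, dF2)
    dG <- tcrossprod(dF2, params[[paste0(pre, "W2")]])
    dA1 <- reluBackward(dG, cc$A1)
    g[[paste0(pre, "b1")]] <- colSums(dA1)
    g[[paste0(pre, "W1")]] <- crossprod(cc$ln2$Y, dA1)
    dln2Y <- tcrossprod(dA1, params[[paste0(pre, "W1")]])
    lb2 <- lnBackward(dln2Y, cc$ln2, params[[paste0(pre, "ln2g")]])
    g[[paste0(pre, "ln2g")]] <- lb2$dg; g[[paste0(pre, "ln2b")]] <- lb2$db
    dX1 <- dX + lb2$dX
    dAttn <- dX1
    if (!is.null(cc$dm1)) dAttn <- dAttn * cc$dm1
    g[[paste0(pre, "bo")]] <- colSums(dAttn)
    g[[paste0(pre, "Wo")]] <- crossprod(cc$O, dAttn)
    dO <- tcrossprod(dAttn, params[[paste0(pre, "Wo")]])
    dQ <- matrix(0, B * M, d); dK <- matrix(0, B * M, d)
    dV <- matrix(0, B * M, d)
    for (c in seq_len(B)) {
      rc <- rows[[c]]
      for (h in seq_len(H)) {
        hc <- headCols[[h]]
        Ach <- cc$A[[(c - 1) * H + h]]
        doh <- dO[rc, hc, drop = FALSE]
        vh <- cc$V[rc, hc, drop = FALSE]
        dAch <- tcrossprod(doh, vh)
        dV[rc, hc] <- crossprod(Ach, doh)
        dS <- Ach * (dAch - rowSums(dAch * Ach))
        dQ[rc, hc] <- dS %*% cc$K[rc, hc, drop = FALSE] / sqrt(dh)
        dK[rc, hc] <- crossprod(dS, cc$Q[rc, hc, drop = FALSE]) / sqrt(dh)
      }
    }
    g[[paste0(pre, "bq")]] <- colSums(dQ)
    g[[paste0(pre, "bk")]] <- colSums(dK)
    g[[paste0(pre, "bv")]] <- colSums(dV)
    g[[paste0(pre, "Wq")]] <- crossprod(cc$ln1$Y, dQ)
    g[[paste0(pre, "Wk")]] <- crossprod(cc$ln1$Y, dK)
    g[[paste0(pre, "Wv")]] <- crossprod(cc$ln1$Y, dV)
    dln1Y <- tcrossprod(dQ, params[[paste0(pre, "Wq")]]) +
      tcrossprod(dK, params[[paste0(pre, "Wk")]]) +
      tcrossprod(dV, params[[paste0(pre, "Wv")]])
    lb1 <- lnBackward(dln1Y, cc$ln1, params[[paste0(pre, "ln1g")]])
    g[[paste0(pre, "ln1g")]] <- lb1$dg; g[[paste0(pre, "ln1b")]] <- lb1$db
    dX <- dX1 + lb1$dX
  }
  # embedding gradients (pad rows carry zero upstream gradient by
  # construction, so scatter-add over all rows is safe)
  dTok <- matrix(0, cfg@vocabSize, d)
  dPos <- matrix(0, cfg@contextLength, d)
  tokIdx <- fw$flatTok + 1L
  dTokAgg <- rowsum(dX, tokIdx)
  dTok[as.integer(rownames(dTokAgg)), ] <- dTokAgg
  dPosAgg <- rowsum(dX, fw$posIdx)
  dPos[as.integer(rownames(dPosAgg)), ] <- dPosAgg
  g$tok <- dTok; g$pos <- dPos
  g
}

# Mean-pool the final hidden states over the real positions of each cell.
poolHidden <- function(fw) {
  t(vapply(seq_len(fw$B),
           function(c) colMeans(fw$H[fw$rows[[c]], , drop = FALSE]),
           numeric(ncol(fw$H))))
}

poolBackward <- function(dPooled, fw) {
  dH <- matrix(0, nrow(fw$H), ncol(fw$H))
  for (c in seq_len(fw$B))
    dH[fw$rows[[c]], ] <- matrix(dPooled[c, ] / fw$lens[c],
                                 fw$lens[c], ncol(fw$H), byrow = TRUE)
  dH
}

# Masked-gene objective on one batch: 15% of positions per cell (at least
# one) are replaced by the MASK token (1); the model predicts the original
# token. Returns loss, gradients, and masked-position accuracy.
mlmBatch <- function(params, cfg, tokens, dropout, maskFrac = 0.15,
                     computeGrads = TRUE) {
  masked <- tokens
  targets <- integer(0)
  rowsSel <- integer(0)
  lens <- lengths(tokens)
  M <- max(lens)
  for (c in seq_along(tokens)) {
    n <- max(1L, round(maskFrac * lens[c]))
    sel <- sample.int(lens[c], n)
    targets <- c(targets, tokens[[c]][sel])
    rowsSel <- c(rowsSel, (c - 1L) * M + sel)
    masked[[c]][sel] <- 1L
  }
  fw <- encForward(params, cfg, masked, dropout, training = computeGrads)
  Hm <- fw$H[rowsSel, , drop = FALSE]
  logits <- Hm %*% params$mlmW + rep(params$mlmB, each = nrow(Hm))
  P <- softmaxRows(logits)
  n <- nrow(P)
  ll <- log(P[cbind(seq_len(n), targets + 1L)] + 1e-12)
  loss <- -mean(ll)
  acc <- mean(max.col(P) == targets + 1L)
  if (!computeGrads) return(list(loss = loss, acc = acc))
  dLogits <- P
  dLogits[cbind(seq_len(n), targets + 1L)] <-
    dLogits[cbind(seq_len(n), targets + 1L)] - 1
  dLogits <- dLogits / n
  g <- list(mlmW = crossprod(Hm, dLogits), mlmB = colSums(dLogits))
  dH <- matrix(0, nrow(fw$H), ncol(fw$H))
  dH[rowsSel, ] <- tcrossprod(dLogits, params$mlmW)
  g <- c(g, encBackward(dH, fw, params, cfg))
  list(loss = loss, acc = acc, grads = g)
}

# Two-class objective on one batch. labels01: 0 = control, 1 = disease.
# classWeights: length-2 weights (control, disease) applied per cell.
clsBatch <- function(params, cfg, tokens, labels01, classWeights, dropout,
                     computeGrads = TRUE) {
  fw <- encForward(params, cfg, tokens, dropout, training = computeGrads)
  pooled <- poolHidden(fw)
  logits <- pooled %*% params$clsW + rep(params$clsB, each = nrow(pooled))
  P <- softmaxRows(logits)
  w <- classWeights[labels01 + 1L]
  ll <- log(P[cbind(seq_along(labels01), labels01 + 1L)] + 1e-12)
  loss <- -sum(w * ll) / sum(w)
  acc <- mean((P[, 2] > 0.5) == (labels01 == 1L))
  if (!computeGrads) return(list(loss = loss, acc = acc, probs = P))
  dLogits <- P
  dLogits[cbind(seq_along(labels01), labels01 + 1L)] <-
    dLogits[cbind(seq_along(labels01), labels01 + 1L)] - 1
  dLogits <- dLogits * w / sum(w)
  g <- list(clsW = crossprod(pooled, dLogits), clsB = colSums(dLogits))
  dPooled <- tcrossprod(dLogits, params$clsW)
  dH <- poolBackward(dPooled, fw)
  g <- c(g, encBackward(dH, fw, params, cfg))
  list(loss = loss, acc = acc, probs = P, grads = g)
}

adamInit <- function(params)
  list(m = lapply(params, function(p) p * 0), v = lapply(params, function(p) p * 0),
       t = 0L)

adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

# Shared minibatch training loop over either objective. The learning rate
# warms up linearly over the first `warmupSteps` updates (standard for
# transformer optimization; prevents early divergence at useful peak
# rates) and is constant afterwards.
trainLoop <- function(params, cfg, tokens, objective = c("mlm", "cls"),
                      labels01 = NULL, classWeights = c(1, 1),
                      epochs, seed, warmupSteps = NULL) {
  objective <- match.arg(objective)
  state <- adamInit(params)
  log <- data.frame()
  step <- 0L
  totalSteps <- epochs * ceiling(length(tokens) / cfg@batchSize)
  if (is.null(warmupSteps))
    warmupSteps <- min(30L, ceiling(totalSteps / 2.5))
  withSeed(seed, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(length(tokens))
      losses <- c(); accs <- c()
      for (start in seq(1, length(ord), by = cfg@batchSize)) {
        idx <- ord[start:min(start + cfg@batchSize - 1, length(ord))]
        res <- if (objective == "mlm")
          mlmBatch(params, cfg, tokens[idx], cfg@dropout)
        else
          clsBatch(params, cfg, tokens[idx], labels01[idx], classWeights,
                   cfg@dropout)
        step <- step + 1L
        lr <- cfg@learningRate * min(1, step / max(1L, warmupSteps))
        st <- adamStep(params, res$grads, state, lr)
        params <- st$params; state <- st$state
        losses <- c(losses, res$loss); accs <- c(accs, res$acc)
      }
      log <- rbind(log, data.frame(objective = objective, epoch = ep,
                                   loss = mean(losses), acc = mean(accs)))
    }
  })
  list(params = params, log = log)
}
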