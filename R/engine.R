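## Internal neural-network engine: tanh+batch-norm blocks, forward/backward
## through the ontology DAG and the drug branch, Adam updates.
##
## Conventions: batches are rows; a block's weight matrix W is (out x in) so
## the affine map is X %*% t(W) + b. Batch norm follows the subsystem formula
## literally: normalization is applied AFTER tanh. In train mode statistics
## come from the batch (running stats updated with momentum 0.1); in eval
## mode, or for batches of a single row, stored running statistics are used.

.BN_EPS <- 1e-5
.BN_MOMENTUM <- 0.1

.bnForward <- function(A, gamma, beta, rm, rv, mode) {
  n <- nrow(A)
  if (mode == "train" && n >= 2L) {
    mu <- colMeans(A)
    v <- pmax(colMeans(A * A) - mu * mu, 0)
    invstd <- 1 / sqrt(v + .BN_EPS)
    xhat <- sweep(sweep(A, 2L, mu, "-"), 2L, invstd, "*")
    rmNew <- (1 - .BN_MOMENTUM) * rm + .BN_MOMENTUM * mu
    rvNew <- (1 - .BN_MOMENTUM) * rv + .BN_MOMENTUM * v
    stat <- "batch"
  } else {
    invstd <- 1 / sqrt(rv + .BN_EPS)
    xhat <- sweep(sweep(A, 2L, rm, "-"), 2L, invstd, "*")
    rmNew <- rm; rvNew <- rv
    stat <- "running"
  }
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out,
       cache = list(xhat = xhat, invstd = invstd, gamma = gamma, stat = stat),
       rm = rmNew, rv = rvNew)
}

.bnBackward <- function(dOut, cache) {
  xhat <- cache$xhat
  n <- nrow(xhat)
  dgamma <- colSums(dOut * xhat)
  dbeta <- colSums(dOut)
  dxhat <- sweep(dOut, 2L, cache$gamma, "*")
  if (cache$stat == "batch") {
    s1 <- colSums(dxhat)
    s2 <- colSums(dxhat * xhat)
    dA <- sweep(
      n * dxhat - matrix(s1, n, length(s1), byrow = TRUE) -
        sweep(xhat, 2L, s2, "*"),
      2L, cache$invstd / n, "*")
  } else {
    dA <- sweep(dxhat, 2L, cache$invstd, "*")
  }
  list(dA = dA, dgamma = dgamma, dbeta = dbeta)
}

## affine -> tanh -> batch norm
.blockForward <- function(X, W, b, gamma, beta, rm, rv, mode) {
  Z <- X %*% t(W)
  Z <- sweep(Z, 2L, b, "+")
  A <- tanh(Z)
  bn <- .bnForward(A, gamma, beta, rm, rv, mode)
  list(out = bn$out,
       cache = list(X = X, A = A, bn = bn$cache),
       rm = bn$rm, rv = bn$rv)
}

.blockBackward <- function(dOut, cache, W) {
  bb <- .bnBackward(dOut, cache$bn)
  dZ <- bb$dA * (1 - cache$A * cache$A)
  list(dW = unname(t(dZ) %*% cache$X),     # inputs may carry gene names
       db = unname(colSums(dZ)),
       dgamma = unname(bb$dgamma), dbeta = unname(bb$dbeta),
       dX = dZ %*% W)
}

## ---- parameter initialization ----------------------------------------------

.uinit <- function(n, range) {
  if (range == 0) rep(0, n) else stats::runif(n, -range, range)
}

## gene feature columns of term t inside the fused input matrix
.geneCols <- function(arch, t) {
  g <- arch@termGenes[[t]]
  if (!length(g)) return(integer(0))
  idx <- match(g, arch@geneIndex)
  w <- arch@geneChannelWidth
  if (w == 1L) idx else as.vector(vapply(idx, function(j) {
    (j - 1L) * w + seq_len(w)
  }, integer(w)))
}

## ---- VNN engine ------------------------------------------------------------

.vnnForwardEngine <- function(params, buffers, arch, cellX, mode,
                              withCache = FALSE) {
  states <- list()
  aux <- list()
  caches <- if (withCache) list() else NULL
  for (t in arch@termOrder) {
    kids <- arch@termChildren[[t]]
    parts <- c(lapply(kids, function(c) states[[c]]),
               list(cellX[, .geneCols(arch, t), drop = FALSE]))
    X <- do.call(cbind, parts)
    bf <- .blockForward(X, params[[paste0("W.", t)]],
                        params[[paste0("b.", t)]],
                        params[[paste0("g.", t)]],
                        params[[paste0("be.", t)]],
                        buffers[[paste0("rm.", t)]],
                        buffers[[paste0("rv.", t)]], mode)
    buffers[[paste0("rm.", t)]] <- bf$rm
    buffers[[paste0("rv.", t)]] <- bf$rv
    states[[t]] <- bf$out
    aux[[t]] <- drop(bf$out %*% params[[paste0("aW.", t)]]) +
      params[[paste0("ab.", t)]]
    if (withCache) caches[[t]] <- bf$cache
  }
  list(states = states, aux = aux, caches = caches, buffers = buffers)
}

## Backprop through the DAG. dStates: named list of (nCell x k) gradients
## already accumulated at each term's output (head / aux contributions);
## missing entries are treated as zero. Returns VNN parameter gradients.
.vnnBackwardEngine <- function(params, arch, caches, states, dStates, lambda) {
  grads <- list()
  for (t in rev(arch@termOrder)) {
    dO <- dStates[[t]]
    if (is.null(dO)) dO <- matrix(0, nrow(states[[t]]), ncol(states[[t]]))
    W <- params[[paste0("W.", t)]]
    bb <- .blockBackward(dO, caches[[t]], W)
    grads[[paste0("W.", t)]] <- bb$dW + 2 * lambda * W
    grads[[paste0("b.", t)]] <- bb$db
    grads[[paste0("g.", t)]] <- bb$dgamma
    grads[[paste0("be.", t)]] <- bb$dbeta
    off <- 0L
    for (c in arch@termChildren[[t]]) {
      kc <- arch@termNeurons[[c]]
      seg <- bb$dX[, off + seq_len(kc), drop = FALSE]
      dStates[[c]] <- if (is.null(dStates[[c]])) seg else dStates[[c]] + seg
      off <- off + kc
    }
  }
  grads
}

## ---- drug ANN engine -------------------------------------------------------

.annForwardEngine <- function(params, buffers, nLayers, fpX, mode,
                              withCache = FALSE) {
  X <- fpX
  caches <- if (withCache) list() else NULL
  for (l in seq_len(nLayers)) {
    bf <- .blockForward(X, params[[paste0("annW.", l)]],
                        params[[paste0("annb.", l)]],
                        params[[paste0("anng.", l)]],
                        params[[paste0("annbe.", l)]],
                        buffers[[paste0("annrm.", l)]],
                        buffers[[paste0("annrv.", l)]], mode)
    buffers[[paste0("annrm.", l)]] <- bf$rm
    buffers[[paste0("annrv.", l)]] <- bf$rv
    if (withCache) caches[[l]] <- bf$cache
    X <- bf$out
  }
  list(emb = X, caches = caches, buffers = buffers)
}

.annBackwardEngine <- function(params, nLayers, caches, dEmb) {
  grads <- list()
  d <- dEmb
  for (l in rev(seq_len(nLayers))) {
    W <- params[[paste0("annW.", l)]]
    bb <- .blockBackward(d, caches[[l]], W)
    grads[[paste0("annW.", l)]] <- bb$dW
    grads[[paste0("annb.", l)]] <- bb$db
    grads[[paste0("anng.", l)]] <- bb$dgamma
    grads[[paste0("annbe.", l)]] <- bb$dbeta
    d <- bb$dX
  }
  grads
}

## ---- per-entity gradient aggregation ---------------------------------------

## Sum per-pair gradient rows into per-entity rows (cells or drugs).
.aggregateRows <- function(dPairs, idx, nEntities) {
  out <- matrix(0, nEntities, ncol(dPairs))
  rs <- rowsum(dPairs, group = idx)
  out[as.integer(rownames(rs)), ] <- rs
  out
}

.aggregateVec <- function(dPairs, idx, nEntities) {
  out <- numeric(nEntities)
  rs <- rowsum(dPairs, group = idx)
  out[as.integer(rownames(rs))] <- rs
  out
}

## ---- Adam ------------------------------------------------------------------

.adamInit <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adamStep <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (n in names(grads)) {
    g <- grads[[n]]
    state$m[[n]] <- beta1 * state$m[[n]] + (1 - beta1) * g
    state$v[[n]] <- beta2 * state$v[[n]] + (1 - beta2) * g * g
    params[[n]] <- params[[n]] -
      lr * (state$m[[n]] / c1) / (sqrt(state$v[[n]] / c2) + eps)
  }
  list(params = params, state = state)
}
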