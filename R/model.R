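## Full two-branch model: construction, objective, training, prediction,
## evaluation, cross-validation, checkpointing.

#' Training configuration
#'
#' Bundles every tunable of the joint training protocol. \code{alpha} weights
#' the auxiliary per-subsystem losses, \code{lambda} the L2 penalty on
#' subsystem weight matrices (tuned by 4-fold cross-validation via
#' [tuneLambda()]), \code{lr} the Adam learning rate (canonically picked from
#' \code{lrGrid} by grid search). The batch size is capped at 10,000 pairs
#' and shrinks to the dataset size for smaller cohorts. A single \code{seed}
#' drives initialization, the train/validation split, fold assignment and
#' batch shuffling.
#'
#' @param alpha auxiliary-loss weight (>= 0).
#' @param lambda L2 factor (>= 0).
#' @param lr Adam learning rate.
#' @param lrGrid learning-rate grid for [tuneLearningRate()].
#' @param strictGrid error if \code{lr} is not in \code{lrGrid}.
#' @param lambdaGrid grid for [tuneLambda()].
#' @param batchSize minibatch cap.
#' @param epochs training epochs.
#' @param valFraction fraction of pairs held out for epoch selection.
#' @param seed master RNG seed.
#' @param neuronRule,fusion,gray,annSizes,headHidden,initRange architecture
#'   and encoding choices (see [layerArchitecture()], [fuseGenotypes()],
#'   [grayEncode()], [buildDrugANN()]).
#' @param cvFoldsEval,cvFoldsLambda fold counts for evaluation and lambda
#'   tuning cross-validation.
#' @param twoStage pre-train the two branches separately, then fine-tune the
#'   fusion head, instead of end-to-end joint optimization.
#' @return a validated list of class \code{TrainConfig}.
#' @export
trainConfig <- function(alpha = 0.3, lambda = 1e-4, lr = 1e-2,
                        lrGrid = c(1e-1, 1e-2, 1e-3, 1e-4),
                        strictGrid = FALSE,
                        lambdaGrid = c(1e-5, 1e-4, 1e-3),
                        batchSize = 10000L, epochs = 100L,
                        valFraction = 0.1, seed = 1L,
                        neuronRule = list(fixed = 6L),
                        fusion = c("mean", "stack"), gray = FALSE,
                        annSizes = c(100L, 50L, 6L), headHidden = 6L,
                        initRange = 0.01,
                        cvFoldsEval = 10L, cvFoldsLambda = 4L,
                        twoStage = FALSE) {
  fusion <- match.arg(fusion)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (lambda < 0) stop("lambda must be >= 0", call. = FALSE)
  if (strictGrid && !any(abs(lr - lrGrid) < 1e-15)) {
    stop(sprintf("lr %g is not in the grid {%s}", lr,
                 paste(lrGrid, collapse = ", ")), call. = FALSE)
  }
  structure(list(
    alpha = alpha, lambda = lambda, lr = lr, lrGrid = lrGrid,
    strictGrid = strictGrid, lambdaGrid = lambdaGrid,
    batchSize = as.integer(batchSize), epochs = as.integer(epochs),
    valFraction = valFraction, seed = as.integer(seed),
    neuronRule = neuronRule, fusion = fusion, gray = gray,
    annSizes = as.integer(annSizes), headHidden = as.integer(headHidden),
    initRange = initRange,
    cvFoldsEval = as.integer(cvFoldsEval),
    cvFoldsLambda = as.integer(cvFoldsLambda),
    twoStage = twoStage), class = "TrainConfig")
}

#' Assemble an untrained two-branch model
#'
#' Builds the VNN blocks from the compiled architecture, the drug branch and
#' the fusion head (concatenated root + drug embeddings -> one tanh+BN hidden
#' layer -> linear scalar). All weights are initialized uniformly in
#' (-initRange, +initRange) from the seed.
#'
#' @param arch a [LayeredArchitecture-class].
#' @param cfg a [trainConfig()].
#' @param nBits drug fingerprint width.
#' @return an untrained [DrugVNNModel-class].
#' @export
newDrugVNN <- function(arch, cfg = trainConfig(), nBits = 2048L) {
  stopifnot(is(arch, "LayeredArchitecture"))
  vnn <- buildVNN(arch, initRange = cfg$initRange,
                  seed = .deriveSeed(cfg$seed, "vnn-init"))
  ann <- buildDrugANN(nBits, cfg$annSizes, initRange = cfg$initRange,
                      seed = .deriveSeed(cfg$seed, "ann-init"))
  kroot <- arch@termNeurons[[arch@root]]
  h3 <- cfg$annSizes[3L]
  hh <- cfg$headHidden
  head <- .withSeed(.deriveSeed(cfg$seed, "head-init"), {
    list(params = list(
           hW = matrix(.uinit(hh * (kroot + h3), cfg$initRange),
                       hh, kroot + h3),
           hb = .uinit(hh, cfg$initRange),
           hg = rep(1, hh), hbe = rep(0, hh),
           oW = .uinit(hh, cfg$initRange),
           ob = .uinit(1, cfg$initRange)),
         buffers = list(hrm = rep(0, hh), hrv = rep(1, hh)))
  })
  new("DrugVNNModel",
      arch = arch, annSizes = as.integer(cfg$annSizes),
      nBits = as.integer(nBits),
      params = c(vnn$params, ann$params, head$params),
      buffers = c(vnn$buffers, ann$buffers, head$buffers),
      config = unclass(cfg),
      history = data.frame(),
      hash = arch@ontologyHash)
}

#' Fuse the two branch embeddings into a scalar prediction
#'
#' Concatenates the root genotype embedding with the drug embedding, passes
#' the result through the fusion head's tanh+BN hidden layer and a final
#' linear map. Row i of each embedding matrix must come from the same
#' cell/drug pair.
#'
#' @param model a [DrugVNNModel-class].
#' @param rootEmbedding samples x k(root) matrix (or vector for one sample).
#' @param drugEmbedding samples x h3 matrix (or vector).
#' @param mode \code{"eval"} or \code{"train"}.
#' @return numeric vector of predictions.
#' @export
combineEmbeddings <- function(model, rootEmbedding, drugEmbedding,
                              mode = c("eval", "train")) {
  mode <- match.arg(mode)
  if (is.null(dim(rootEmbedding))) {
    rootEmbedding <- matrix(rootEmbedding, nrow = 1L)
  }
  if (is.null(dim(drugEmbedding))) {
    drugEmbedding <- matrix(drugEmbedding, nrow = 1L)
  }
  C <- cbind(rootEmbedding, drugEmbedding)
  p <- model@params; b <- model@buffers
  h <- .blockForward(C, p$hW, p$hb, p$hg, p$hbe, b$hrm, b$hrv, mode)
  unname(drop(h$out %*% p$oW) + p$ob)
}

#' Joint training objective
#'
#' Mean squared error of the final prediction, plus \code{alpha} times the
#' sum over non-root terms of the MSE of that term's auxiliary prediction,
#' plus \code{lambda} times the summed squared subsystem weights.
#'
#' @param pred final predictions, one per sample.
#' @param y observed responses.
#' @param aux named list (term -> per-sample auxiliary predictions) for the
#'   non-root terms; may be empty.
#' @param alpha,lambda loss weights.
#' @param weights list of subsystem weight matrices entering the L2 term;
#'   may be empty.
#' @return scalar loss.
#' @export
objectiveLoss <- function(pred, y, aux = list(), alpha = 0, lambda = 0,
                          weights = list()) {
  if (length(pred) != length(y)) {
    stop("pred and y lengths differ", call. = FALSE)
  }
  main <- mean((pred - y)^2)
  if (!is.finite(main)) stop("non-finite main prediction loss", call. = FALSE)
  auxSum <- 0
  for (t in names(aux)) {
    m <- mean((aux[[t]] - y)^2)
    if (!is.finite(m)) {
      stop("non-finite auxiliary loss for term ", t, call. = FALSE)
    }
    auxSum <- auxSum + m
  }
  l2 <- if (length(weights)) sum(vapply(weights, function(W) sum(W * W), 0)) else 0
  main + alpha * auxSum + lambda * l2
}

## ---- internal full forward / backward --------------------------------------

## Forward over a batch of pairs. cellX/fpX contain only the entities used by
## the batch; pairCell/pairDrug index into their rows.
.forwardFull <- function(params, buffers, arch, pairCell, pairDrug,
                         cellX, fpX, headHidden, mode, withCache = FALSE) {
  vnn <- .vnnForwardEngine(params, buffers, arch, cellX, mode, withCache)
  ann <- .annForwardEngine(params, vnn$buffers, 3L, fpX, mode, withCache)
  buffers <- ann$buffers
  root <- arch@root
  C <- cbind(vnn$states[[root]][pairCell, , drop = FALSE],
             ann$emb[pairDrug, , drop = FALSE])
  hd <- .blockForward(C, params$hW, params$hb, params$hg, params$hbe,
                      buffers$hrm, buffers$hrv, mode)
  buffers$hrm <- hd$rm; buffers$hrv <- hd$rv
  pred <- drop(hd$out %*% params$oW) + params$ob
  list(pred = pred, vnn = vnn, ann = ann, headOut = hd$out,
       headCache = if (withCache) hd$cache else NULL, buffers = buffers)
}

## Gradients of the joint objective for one batch.
.backwardFull <- function(params, arch, fw, pairCell, pairDrug,
                          nCell, nDrug, y, alpha, lambda,
                          scope = c("joint", "head")) {
  scope <- match.arg(scope)
  n <- length(y)
  grads <- list()
  dpred <- 2 * (fw$pred - y) / n
  grads$oW <- drop(t(fw$headOut) %*% dpred)
  grads$ob <- sum(dpred)
  dHeadOut <- outer(dpred, params$oW)
  hb <- .blockBackward(dHeadOut, fw$headCache, params$hW)
  grads$hW <- hb$dW; grads$hb <- hb$db
  grads$hg <- hb$dgamma; grads$hbe <- hb$dbeta
  if (scope == "head") return(grads)
  kroot <- arch@termNeurons[[arch@root]]
  dRootPairs <- hb$dX[, seq_len(kroot), drop = FALSE]
  dDrugPairs <- hb$dX[, -seq_len(kroot), drop = FALSE]
  ## drug branch
  dEmb <- .aggregateRows(dDrugPairs, pairDrug, nDrug)
  grads <- c(grads, .annBackwardEngine(params, 3L, fw$ann$caches, dEmb))
  ## auxiliary heads (non-root terms)
  dStates <- list()
  dStates[[arch@root]] <- .aggregateRows(dRootPairs, pairCell, nCell)
  if (alpha > 0) {
    for (t in setdiff(arch@termOrder, arch@root)) {
      auxPair <- fw$vnn$aux[[t]][pairCell]
      dAuxPair <- 2 * alpha * (auxPair - y) / n
      dAuxCell <- .aggregateVec(dAuxPair, pairCell, nCell)
      st <- fw$vnn$states[[t]]
      grads[[paste0("aW.", t)]] <- drop(t(st) %*% dAuxCell)
      grads[[paste0("ab.", t)]] <- sum(dAuxCell)
      dStates[[t]] <- outer(dAuxCell, params[[paste0("aW.", t)]])
    }
  }
  c(grads, .vnnBackwardEngine(params, arch, fw$vnn$caches, fw$vnn$states,
                              dStates, lambda))
}

## VNN-only objective (two-stage pretraining): root auxiliary head is the
## main predictor, other terms weighted by alpha.
.backwardVNNOnly <- function(params, arch, vnn, pairCell, nCell, y,
                             alpha, lambda) {
  n <- length(y)
  grads <- list()
  dStates <- list()
  for (t in arch@termOrder) {
    wgt <- if (t == arch@root) 1 else alpha
    if (wgt == 0) next
    auxPair <- vnn$aux[[t]][pairCell]
    dAuxPair <- 2 * wgt * (auxPair - y) / n
    dAuxCell <- .aggregateVec(dAuxPair, pairCell, nCell)
    st <- vnn$states[[t]]
    grads[[paste0("aW.", t)]] <- drop(t(st) %*% dAuxCell)
    grads[[paste0("ab.", t)]] <- sum(dAuxCell)
    dStates[[t]] <- outer(dAuxCell, params[[paste0("aW.", t)]])
  }
  c(grads, .vnnBackwardEngine(params, arch, vnn$caches, vnn$states,
                              dStates, lambda))
}

.backwardANNOnly <- function(params, ann, pairDrug, nDrug, y) {
  n <- length(y)
  predDrug <- drop(ann$emb %*% params$annHW) + params$annHb
  pred <- predDrug[pairDrug]
  dpred <- 2 * (pred - y) / n
  dPerDrug <- .aggregateVec(dpred, pairDrug, nDrug)
  grads <- list(annHW = drop(t(ann$emb) %*% dPerDrug),
                annHb = sum(dPerDrug))
  dEmb <- outer(dPerDrug, params$annHW)
  c(grads, .annBackwardEngine(params, 3L, ann$caches, dEmb))
}

## ---- training --------------------------------------------------------------

.pairIndices <- function(data) {
  pc <- match(data@triples$cell_id, data@cellIds)
  pd <- match(data@triples$drug_id, data@drugIds)
  if (anyNA(pc) || anyNA(pd)) {
    bad <- unique(c(data@triples$cell_id[is.na(pc)],
                    data@triples$drug_id[is.na(pd)]))
    stop("response triples reference unknown ids: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  list(cell = pc, drug = pd, y = data@triples$auc)
}

## Restrict a batch to the entities it touches and remap indices.
.batchView <- function(pairCell, pairDrug, cellX, fpX) {
  uc <- sort(unique(pairCell))
  ud <- sort(unique(pairDrug))
  list(cellX = cellX[uc, , drop = FALSE],
       fpX = fpX[ud, , drop = FALSE],
       pairCell = match(pairCell, uc),
       pairDrug = match(pairDrug, ud),
       nCell = length(uc), nDrug = length(ud))
}

.vnnWeightList <- function(params, arch) {
  w <- lapply(arch@termOrder, function(t) params[[paste0("W.", t)]])
  names(w) <- arch@termOrder
  w
}

## Evaluation-mode objective on a set of pairs.
.evalObjective <- function(params, buffers, arch, idx, pairCell, pairDrug, y,
                           cellX, fpX, alpha, lambda) {
  bv <- .batchView(pairCell[idx], pairDrug[idx], cellX, fpX)
  fw <- .forwardFull(params, buffers, arch, bv$pairCell, bv$pairDrug,
                     bv$cellX, bv$fpX, NULL, "eval")
  aux <- lapply(fw$vnn$aux, function(a) a[bv$pairCell])
  aux <- aux[setdiff(arch@termOrder, arch@root)]
  list(loss = objectiveLoss(fw$pred, y[idx], aux, alpha, lambda,
                            .vnnWeightList(params, arch)),
       mse = mean((fw$pred - y[idx])^2))
}

#' Train the two-branch model
#'
#' Minimizes the joint objective (main MSE + alpha x auxiliary subsystem
#' MSEs + lambda x L2 on subsystem weights) with Adam over shuffled
#' minibatches. A fraction of pairs is held out for epoch selection; the
#' parameters of the best-validation epoch are retained. Within a minibatch,
#' batch-norm statistics of the genotype branch are computed over the
#' distinct cell lines present (and over distinct drugs for the drug
#' branch); the fusion head normalizes over pairs.
#'
#' With \code{cfg$twoStage = TRUE} the branches are first pre-trained
#' separately (the VNN against its root auxiliary head, the ANN through a
#' branch-only linear head), then the fusion head alone is fine-tuned.
#'
#' Everything random — initialization, the validation split, batch
#' shuffling — derives from \code{cfg$seed}; identical seeds give identical
#' histories and parameters.
#'
#' @param data a [DrugResponseData-class].
#' @param arch a [LayeredArchitecture-class] (gene index must match).
#' @param cfg a [trainConfig()].
#' @param verbose print per-epoch losses to stderr.
#' @return a trained [DrugVNNModel-class]; slot \code{history} holds
#'   per-epoch train/validation losses.
#' @export
trainDrugVNN <- function(data, arch, cfg = trainConfig(), verbose = FALSE) {
  stopifnot(is(data, "DrugResponseData"), is(arch, "LayeredArchitecture"))
  if (!identical(data@geneIndex, arch@geneIndex)) {
    stop("dataset gene index does not match the architecture", call. = FALSE)
  }
  if (nrow(data@triples) == 0L) stop("empty dataset", call. = FALSE)
  if (cfg$strictGrid && !any(abs(cfg$lr - cfg$lrGrid) < 1e-15)) {
    stop(sprintf("lr %g is not in the grid {%s}", cfg$lr,
                 paste(cfg$lrGrid, collapse = ", ")), call. = FALSE)
  }
  model <- newDrugVNN(arch, cfg, nBits = ncol(data@fpMatrix))
  pi <- .pairIndices(data)
  n <- length(pi$y)
  nVal <- floor(cfg$valFraction * n)
  valIdx <- if (nVal >= 1L) {
    .withSeed(.deriveSeed(cfg$seed, "val-split"), sample(n, nVal))
  } else integer(0)
  trainIdx <- setdiff(seq_len(n), valIdx)
  params <- model@params
  buffers <- model@buffers
  adam <- .adamInit(params)
  batch <- min(cfg$batchSize, length(trainIdx))
  hist <- vector("list", cfg$epochs)
  best <- list(metric = Inf, params = params, buffers = buffers, epoch = 0L)

  stages <- if (isTRUE(cfg$twoStage)) {
    n1 <- ceiling(cfg$epochs / 2)
    list(list(scope = "branches", epochs = n1),
         list(scope = "head", epochs = cfg$epochs - n1))
  } else {
    list(list(scope = "joint", epochs = cfg$epochs))
  }

  epochGlobal <- 0L
  for (stage in stages) {
    for (ep in seq_len(stage$epochs)) {
      epochGlobal <- epochGlobal + 1L
      ord <- .withSeed(.deriveSeed(cfg$seed, paste0("shuffle-", epochGlobal)),
                       sample(trainIdx))
      nBatch <- ceiling(length(ord) / batch)
      bLoss <- numeric(nBatch)
      for (bi in seq_len(nBatch)) {
        take <- ord[((bi - 1L) * batch + 1L):min(bi * batch, length(ord))]
        bv <- .batchView(pi$cell[take], pi$drug[take], data@cellX,
                         data@fpMatrix)
        yb <- pi$y[take]
        if (stage$scope == "branches") {
          vnn <- .vnnForwardEngine(params, buffers, arch, bv$cellX, "train",
                                   withCache = TRUE)
          buffers <- vnn$buffers
          gV <- .backwardVNNOnly(params, arch, vnn, bv$pairCell, bv$nCell,
                                 yb, cfg$alpha, cfg$lambda)
          ann <- .annForwardEngine(params, buffers, 3L, bv$fpX, "train",
                                   withCache = TRUE)
          buffers <- ann$buffers
          gA <- .backwardANNOnly(params, ann, bv$pairDrug, bv$nDrug, yb)
          up <- .adamStep(params, c(gV, gA), adam, cfg$lr)
          rootAux <- vnn$aux[[arch@root]][bv$pairCell]
          bLoss[bi] <- mean((rootAux - yb)^2)
        } else {
          fw <- .forwardFull(params, buffers, arch, bv$pairCell, bv$pairDrug,
                             bv$cellX, bv$fpX, cfg$headHidden, "train",
                             withCache = TRUE)
          buffers <- fw$buffers
          g <- .backwardFull(params, arch, fw, bv$pairCell, bv$pairDrug,
                             bv$nCell, bv$nDrug, yb, cfg$alpha, cfg$lambda,
                             scope = if (stage$scope == "head") "head"
                                     else "joint")
          up <- .adamStep(params, g, adam, cfg$lr)
          aux <- lapply(fw$vnn$aux, function(a) a[bv$pairCell])
          aux <- aux[setdiff(arch@termOrder, arch@root)]
          bLoss[bi] <- objectiveLoss(fw$pred, yb, aux, cfg$alpha, cfg$lambda,
                                     .vnnWeightList(params, arch))
        }
        params <- up$params
        adam <- up$state
      }
      val <- if (length(valIdx)) {
        .evalObjective(params, buffers, arch, valIdx, pi$cell, pi$drug, pi$y,
                       data@cellX, data@fpMatrix, cfg$alpha, cfg$lambda)
      } else list(loss = NA_real_, mse = NA_real_)
      trLoss <- mean(bLoss)
      metric <- if (length(valIdx)) val$mse else trLoss
      if (metric < best$metric && stage$scope != "branches") {
        best <- list(metric = metric, params = params, buffers = buffers,
                     epoch = epochGlobal)
      }
      hist[[epochGlobal]] <- data.frame(
        epoch = epochGlobal, stage = stage$scope, trainLoss = trLoss,
        valLoss = val$loss, valMSE = val$mse)
      if (verbose) {
        message(sprintf("epoch %3d [%s] train %.5f val %.5f",
                        epochGlobal, stage$scope, trLoss, val$loss))
      }
    }
  }
  if (!is.finite(best$metric)) {
    best <- list(metric = NA_real_, params = params, buffers = buffers,
                 epoch = epochGlobal)
  }
  model@params <- best$params
  model@buffers <- best$buffers
  model@history <- do.call(rbind, hist[seq_len(epochGlobal)])
  model@config <- c(unclass(cfg), list(bestEpoch = best$epoch))
  model
}

## ---- prediction ------------------------------------------------------------

#' Predict dose-response AUC for cell/drug pairs
#'
#' Runs both branches and the fusion head in eval mode (batch norm uses
#' stored running statistics). Predictions are not clipped to \[0, 1\];
#' out-of-range values are reported as-is.
#'
#' @param object a trained [DrugVNNModel-class].
#' @param data a [DrugResponseData-class] holding the features.
#' @param pairs optional data.frame(cell_id, drug_id); defaults to the
#'   dataset's triples.
#' @param ... unused.
#' @return data.frame(cell_id, drug_id, predicted_auc).
#' @export
setMethod("predict", "DrugVNNModel", function(object, data, pairs = NULL, ...) {
  stopifnot(is(data, "DrugResponseData"))
  if (object@hash != object@arch@ontologyHash) {
    stop("checkpoint hash does not match its architecture", call. = FALSE)
  }
  if (!identical(data@geneIndex, object@arch@geneIndex)) {
    stop("dataset gene index does not match the model", call. = FALSE)
  }
  if (is.null(pairs)) pairs <- data@triples[, c("cell_id", "drug_id")]
  pc <- match(pairs$cell_id, data@cellIds)
  pd <- match(pairs$drug_id, data@drugIds)
  if (anyNA(pc) || anyNA(pd)) {
    bad <- unique(c(pairs$cell_id[is.na(pc)], pairs$drug_id[is.na(pd)]))
    stop("unknown cell/drug ids: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  bv <- .batchView(pc, pd, data@cellX, data@fpMatrix)
  fw <- .forwardFull(object@params, object@buffers, object@arch,
                     bv$pairCell, bv$pairDrug, bv$cellX, bv$fpX,
                     NULL, "eval")
  data.frame(cell_id = pairs$cell_id, drug_id = pairs$drug_id,
             predicted_auc = fw$pred, stringsAsFactors = FALSE)
})

## ---- evaluation ------------------------------------------------------------

#' Regression metrics between predictions and observations
#'
#' @param pred predicted AUC values (or a prediction data.frame from
#'   [predict()], aligned to \code{truth}).
#' @param truth observed AUC values.
#' @param metrics which of pearson, mse, mae, rmse, r2 to compute.
#' @return named numeric vector.
#' @export
evaluatePredictions <- function(pred, truth,
                                metrics = c("pearson", "mse", "mae",
                                            "rmse", "r2")) {
  if (is.data.frame(pred)) pred <- pred$predicted_auc
  metrics <- match.arg(metrics, several.ok = TRUE)
  if (length(pred) != length(truth)) {
    stop("pred and truth lengths differ", call. = FALSE)
  }
  out <- numeric(0)
  if ("pearson" %in% metrics) {
    if (length(pred) < 2L) {
      stop("pearson correlation needs at least 2 samples", call. = FALSE)
    }
    out["pearson"] <- .safeCor(pred, truth)
  }
  err <- pred - truth
  if ("mse" %in% metrics) out["mse"] <- mean(err^2)
  if ("mae" %in% metrics) out["mae"] <- mean(abs(err))
  if ("rmse" %in% metrics) out["rmse"] <- sqrt(mean(err^2))
  if ("r2" %in% metrics) {
    ss <- sum((truth - mean(truth))^2)
    out["r2"] <- 1 - sum(err^2) / ss
  }
  out[metrics]
}

## ---- cross-validation ------------------------------------------------------

#' Seeded disjoint fold assignment by pair
#'
#' @param n number of pairs.
#' @param k number of folds (2 <= k <= n).
#' @param seed RNG seed.
#' @return integer vector of fold labels 1..k covering all pairs.
#' @export
foldAssignment <- function(n, k, seed = 1L) {
  if (k < 2L) stop("k must be >= 2", call. = FALSE)
  if (k > n) stop("k exceeds the number of samples", call. = FALSE)
  .withSeed(seed, sample(rep_len(seq_len(k), n)))
}

#' k-fold cross-validated performance
#'
#' Trains one model per fold on the remaining pairs and evaluates on the held
#' fold. Fold assignment is by pair and derived from \code{cfg$seed}.
#'
#' @param data a [DrugResponseData-class].
#' @param arch a [LayeredArchitecture-class].
#' @param cfg a [trainConfig()].
#' @param k number of folds (default \code{cfg$cvFoldsEval}).
#' @return list with \code{perFold} (data.frame of metrics per fold) and
#'   \code{mean} (averaged metrics).
#' @export
crossValidate <- function(data, arch, cfg = trainConfig(), k = NULL) {
  if (is.null(k)) k <- cfg$cvFoldsEval
  n <- nrow(data@triples)
  folds <- foldAssignment(n, k, .deriveSeed(cfg$seed, "cv-folds"))
  rows <- vector("list", k)
  for (f in seq_len(k)) {
    tr <- data
    tr@triples <- data@triples[folds != f, , drop = FALSE]
    te <- data@triples[folds == f, , drop = FALSE]
    m <- trainDrugVNN(tr, arch, cfg)
    pr <- predict(m, data, pairs = te[, c("cell_id", "drug_id")])
    met <- evaluatePredictions(pr$predicted_auc, te$auc)
    rows[[f]] <- data.frame(fold = f, t(met))
  }
  perFold <- do.call(rbind, rows)
  list(perFold = perFold, mean = colMeans(perFold[, -1L, drop = FALSE]))
}

#' Choose the L2 factor by cross-validation
#'
#' Runs k-fold cross-validation (default 4 folds) for every lambda in the
#' grid and returns the grid argmin of the mean validation MSE.
#'
#' @param data,arch,cfg as in [crossValidate()].
#' @param grid candidate lambda values (default \code{cfg$lambdaGrid}).
#' @param k folds (default \code{cfg$cvFoldsLambda}).
#' @return list with \code{best} (the selected lambda) and \code{table}
#'   (lambda vs mean validation MSE).
#' @export
tuneLambda <- function(data, arch, cfg = trainConfig(), grid = NULL,
                       k = NULL) {
  if (is.null(grid)) grid <- cfg$lambdaGrid
  if (is.null(k)) k <- cfg$cvFoldsLambda
  mse <- vapply(grid, function(l) {
    cfgL <- cfg; cfgL$lambda <- l
    crossValidate(data, arch, cfgL, k = k)$mean[["mse"]]
  }, 0)
  list(best = grid[which.min(mse)],
       table = data.frame(lambda = grid, mse = mse))
}

#' Pick the Adam learning rate by grid search
#'
#' Trains once per grid value and selects the rate with the lowest
#' best-epoch validation MSE.
#'
#' @param data,arch,cfg as in [trainDrugVNN()].
#' @param grid candidate rates (default \code{cfg$lrGrid}).
#' @return list with \code{best} and \code{table}.
#' @export
tuneLearningRate <- function(data, arch, cfg = trainConfig(), grid = NULL) {
  if (is.null(grid)) grid <- cfg$lrGrid
  mse <- vapply(grid, function(lr) {
    cfgL <- cfg; cfgL$lr <- lr
    m <- trainDrugVNN(data, arch, cfgL)
    min(m@history$valMSE, na.rm = TRUE)
  }, 0)
  list(best = grid[which.min(mse)],
       table = data.frame(lr = grid, valMSE = mse))
}

## ---- checkpointing ---------------------------------------------------------

#' Save / load a model checkpoint
#'
#' The checkpoint bundles the compiled architecture (including the ontology
#' hash and gene index), configuration, parameters and batch-norm buffers.
#' Loading verifies the stored hash against the architecture it was compiled
#' from, so a checkpoint can never silently be applied to a different
#' hierarchy.
#'
#' @param model a [DrugVNNModel-class].
#' @param path file path.
#' @return \code{saveCheckpoint}: \code{path}, invisibly;
#'   \code{loadCheckpoint}: the model.
#' @export
saveCheckpoint <- function(model, path) {
  stopifnot(is(model, "DrugVNNModel"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveCheckpoint
#' @export
loadCheckpoint <- function(path) {
  model <- readRDS(path)
  if (!is(model, "DrugVNNModel")) {
    stop("not a model checkpoint: ", path, call. = FALSE)
  }
  if (model@hash != model@arch@ontologyHash) {
    stop("checkpoint ontology hash mismatch: the stored parameters were ",
         "trained against a different hierarchy", call. = FALSE)
  }
  model
}

## ---- baseline hook ---------------------------------------------------------

#' Ridge baseline on the flat feature table
#'
#' Plumbing hook: fits a single ridge regression of AUC on the concatenated
#' fused genotype and fingerprint features of each pair, with a train/test
#' split. Serves as a generic linear reference point for the structured
#' model, not as a reproduction of any published comparison.
#'
#' @param data a [DrugResponseData-class].
#' @param testFraction held-out fraction.
#' @param ridge L2 penalty.
#' @param seed split seed.
#' @return list with \code{metrics} on the held-out split and \code{nTrain},
#'   \code{nTest}.
#' @export
fitLinearBaseline <- function(data, testFraction = 0.2, ridge = 1,
                              seed = 1L) {
  pi <- .pairIndices(data)
  X <- cbind(data@cellX[pi$cell, , drop = FALSE],
             data@fpMatrix[pi$drug, , drop = FALSE])
  n <- nrow(X)
  te <- .withSeed(seed, sample(n, max(1L, floor(testFraction * n))))
  tr <- setdiff(seq_len(n), te)
  Xa <- cbind(1, X[tr, , drop = FALSE])
  A <- crossprod(Xa) + diag(c(1e-8, rep(ridge, ncol(X))))
  beta <- solve(A, crossprod(Xa, pi$y[tr]))
  pred <- drop(cbind(1, X[te, , drop = FALSE]) %*% beta)
  list(metrics = evaluatePredictions(pred, pi$y[te]),
       nTrain = length(tr), nTest = length(te))
}
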