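## Drug branch: feed-forward network over Morgan fingerprints.

#' Instantiate the drug fingerprint branch
#'
#' Three hidden layers (affine -> tanh -> batch norm each); the last layer's
#' output is the drug-structure embedding. Weights and biases are drawn
#' uniformly from (-initRange, +initRange) under the seed.
#'
#' @param nBits fingerprint input width.
#' @param sizes hidden layer widths (exactly three).
#' @param initRange,seed initialization parameters.
#' @return list with \code{params} and \code{buffers} (entries
#'   \code{annW.l}, \code{annb.l}, \code{anng.l}, \code{annbe.l},
#'   \code{annrm.l}, \code{annrv.l} for layer l, plus the branch-only linear
#'   head \code{annHW}/\code{annHb} used in two-stage pretraining).
#' @export
buildDrugANN <- function(nBits = 2048L, sizes = c(100L, 50L, 6L),
                         initRange = 0.01, seed = 1L) {
  if (length(sizes) != 3L) {
    stop("the drug branch has exactly three hidden layers; got ",
         length(sizes), call. = FALSE)
  }
  dims <- c(nBits, sizes)
  .withSeed(seed, {
    params <- list()
    buffers <- list()
    for (l in 1:3) {
      params[[paste0("annW.", l)]] <-
        matrix(.uinit(dims[l + 1L] * dims[l], initRange), dims[l + 1L], dims[l])
      params[[paste0("annb.", l)]] <- .uinit(dims[l + 1L], initRange)
      params[[paste0("anng.", l)]] <- rep(1, dims[l + 1L])
      params[[paste0("annbe.", l)]] <- rep(0, dims[l + 1L])
      buffers[[paste0("annrm.", l)]] <- rep(0, dims[l + 1L])
      buffers[[paste0("annrv.", l)]] <- rep(1, dims[l + 1L])
    }
    params$annHW <- .uinit(sizes[3L], initRange)
    params$annHb <- .uinit(1, initRange)
    list(params = params, buffers = buffers)
  })
}

#' Forward pass of the drug branch
#'
#' @param model a [DrugVNNModel-class].
#' @param fp fingerprint bit vector, [DrugFingerprint-class], or matrix of
#'   fingerprints in rows.
#' @param mode \code{"eval"} or \code{"train"}.
#' @return drug embedding: numeric vector of length h3, or a matrix for
#'   matrix input.
#' @export
annForward <- function(model, fp, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  stopifnot(is(model, "DrugVNNModel"))
  if (is(fp, "DrugFingerprint")) fp <- fp@bits
  vec <- is.null(dim(fp))
  X <- if (vec) matrix(fp, nrow = 1L) else as.matrix(fp)
  if (ncol(X) != model@nBits) {
    stop(sprintf("fingerprint width %d does not match model input %d",
                 ncol(X), model@nBits), call. = FALSE)
  }
  emb <- .annForwardEngine(model@params, model@buffers, 3L, X, mode)$emb
  if (vec) drop(emb) else emb
}
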