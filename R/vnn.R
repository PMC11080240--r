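## Public surface of the ontology-shaped branch.

#' Instantiate the subsystem blocks of a visible neural network
#'
#' Creates one block per ontology term: a weight matrix k(t) x input_width,
#' a bias, post-tanh batch-norm parameters (gamma = 1, beta = 0, running mean
#' 0 / variance 1) and an auxiliary linear head k(t) -> 1. All weights and
#' biases are drawn uniformly from (-initRange, +initRange) under the given
#' seed, in a fixed term order, so identical seeds give identical parameters.
#'
#' @param arch a [LayeredArchitecture-class].
#' @param initRange half-width of the uniform initialization interval.
#' @param seed RNG seed.
#' @return list with elements \code{params} and \code{buffers} (named lists
#'   of arrays; entries \code{W.<term>}, \code{b.<term>}, \code{g.<term>}
#'   (gamma), \code{be.<term>} (beta), \code{aW.<term>}, \code{ab.<term>},
#'   and running stats \code{rm./rv.<term>}).
#' @export
buildVNN <- function(arch, initRange = 0.01, seed = 1L) {
  stopifnot(is(arch, "LayeredArchitecture"))
  widths <- termInputWidth(arch)
  .withSeed(seed, {
    params <- list()
    buffers <- list()
    for (t in arch@termOrder) {
      k <- arch@termNeurons[[t]]
      w <- widths[[t]]
      params[[paste0("W.", t)]] <- matrix(.uinit(k * w, initRange), k, w)
      params[[paste0("b.", t)]] <- .uinit(k, initRange)
      params[[paste0("g.", t)]] <- rep(1, k)
      params[[paste0("be.", t)]] <- rep(0, k)
      params[[paste0("aW.", t)]] <- .uinit(k, initRange)
      params[[paste0("ab.", t)]] <- .uinit(1, initRange)
      buffers[[paste0("rm.", t)]] <- rep(0, k)
      buffers[[paste0("rv.", t)]] <- rep(1, k)
    }
    list(params = params, buffers = buffers)
  })
}

#' Number of trainable parameters
#'
#' For the VNN component this is the closed form
#' sum over terms of \code{k*(input width) + k + 2k + (k+1)}
#' (weights, bias, batch-norm affine, auxiliary head).
#'
#' @param x a [DrugVNNModel-class], or a \code{params} list.
#' @param component \code{"all"}, \code{"vnn"}, \code{"ann"} or
#'   \code{"head"}.
#' @return integer count.
#' @export
parameterCount <- function(x, component = c("all", "vnn", "ann", "head")) {
  component <- match.arg(component)
  params <- if (is(x, "DrugVNNModel")) x@params else x
  nm <- names(params)
  keep <- switch(component,
    all = rep(TRUE, length(nm)),
    vnn = grepl("^(W|b|g|be|aW|ab)\\.", nm) & !grepl("^ann", nm),
    ann = grepl("^ann", nm),
    head = nm %in% c("hW", "hb", "hg", "hbe", "oW", "ob"))
  sum(vapply(params[keep], length, 0L))
}

#' Extract one subsystem block from a model
#'
#' @param model a [DrugVNNModel-class].
#' @param term term id.
#' @return list with the block's weights, batch-norm parameters, running
#'   statistics and auxiliary head.
#' @export
getSubsystemBlock <- function(model, term) {
  stopifnot(is(model, "DrugVNNModel"))
  if (!(term %in% model@arch@termOrder)) {
    stop("unknown term: ", term, call. = FALSE)
  }
  list(term = term,
       W = model@params[[paste0("W.", term)]],
       b = model@params[[paste0("b.", term)]],
       gamma = model@params[[paste0("g.", term)]],
       beta = model@params[[paste0("be.", term)]],
       auxW = model@params[[paste0("aW.", term)]],
       auxB = model@params[[paste0("ab.", term)]],
       runningMean = model@buffers[[paste0("rm.", term)]],
       runningVar = model@buffers[[paste0("rv.", term)]])
}

#' Evaluate a single subsystem block
#'
#' Computes \code{BatchNorm(tanh(W v + b))} for one term. In eval mode batch
#' norm uses the stored running statistics; in train mode it uses batch
#' statistics (falling back to running statistics for single-row input).
#'
#' @param v input vector (length = block input width) or matrix of rows.
#' @param block a block as returned by [getSubsystemBlock()].
#' @param mode \code{"eval"} or \code{"train"}.
#' @return activation vector (or matrix for matrix input).
#' @export
subsystemForward <- function(v, block, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  vec <- is.null(dim(v))
  X <- if (vec) matrix(v, nrow = 1L) else as.matrix(v)
  if (ncol(X) != ncol(block$W)) {
    stop(sprintf("input width %d does not match term '%s' (expects %d)",
                 ncol(X), block$term, ncol(block$W)), call. = FALSE)
  }
  out <- .blockForward(X, block$W, block$b, block$gamma, block$beta,
                       block$runningMean, block$runningVar, mode)$out
  if (vec) drop(out) else out
}

#' Forward pass of the ontology branch
#'
#' Evaluates every subsystem block in topological order: each term's input
#' concatenates its children's activation blocks (lexicographic child order)
#' followed by its directly annotated genes' fused values, then applies
#' \code{BatchNorm(tanh(W v + b))} and the term's auxiliary linear head. By
#' construction a term's state can only depend on genes annotated within its
#' descendant closure.
#'
#' @param model a [DrugVNNModel-class].
#' @param cellX fused genotype matrix (samples x gene features) aligned to
#'   the architecture's gene index.
#' @param mode \code{"eval"} (running batch-norm statistics; default) or
#'   \code{"train"}.
#' @return list with \code{rootEmbedding} (samples x k(root)), \code{states}
#'   (per-term activation matrices) and \code{auxPredictions} (per-term
#'   per-sample scalars).
#' @export
vnnForward <- function(model, cellX, mode = c("eval", "train")) {
  mode <- match.arg(mode)
  stopifnot(is(model, "DrugVNNModel"))
  arch <- model@arch
  wanted <- length(arch@geneIndex) * arch@geneChannelWidth
  if (is.null(dim(cellX))) cellX <- matrix(cellX, nrow = 1L)
  if (ncol(cellX) != wanted) {
    stop(sprintf("cellX has %d columns; architecture expects %d (G=%d x %d)",
                 ncol(cellX), wanted, length(arch@geneIndex),
                 arch@geneChannelWidth), call. = FALSE)
  }
  fw <- .vnnForwardEngine(model@params, model@buffers, arch, cellX, mode)
  list(rootEmbedding = fw$states[[arch@root]],
       states = fw$states,
       auxPredictions = fw$aux)
}
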