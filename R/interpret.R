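## Model interpretation: RLIPP subsystem importance, ranked tables,
## 2-D embeddings of cells and drugs, subsystem state export.

## Ridge predictor used for all RLIPP fits; a tiny penalty keeps collinear
## neuron states solvable (plain least squares is the penalty -> 0 limit).
.ridgeFit <- function(X, y, ridge = 1e-6) {
  Xa <- cbind(1, X)
  A <- crossprod(Xa) + diag(c(1e-12, rep(ridge, ncol(X))))
  drop(solve(A, crossprod(Xa, y)))
}

## In-sample or out-of-fold predictions of y from X. Folds are assigned by
## group (cell line) when groups are given: neuron states are cell-level
## features, so pair-level folds would leak each cell's signal between train
## and test and let chance combinations of unrelated states appear
## predictive.
.ridgePredict <- function(X, y, heldOut, folds, ridge, seed, groups = NULL) {
  X <- as.matrix(X)
  if (!heldOut) {
    beta <- .ridgeFit(X, y, ridge)
    return(drop(cbind(1, X) %*% beta))
  }
  fa <- if (is.null(groups)) {
    foldAssignment(length(y), folds, seed)
  } else {
    ug <- sort(unique(groups))
    foldAssignment(length(ug), folds, seed)[match(groups, ug)]
  }
  pred <- numeric(length(y))
  for (f in seq_len(folds)) {
    te <- fa == f
    beta <- .ridgeFit(X[!te, , drop = FALSE], y[!te], ridge)
    pred[te] <- drop(cbind(1, X[te, , drop = FALSE]) %*% beta)
  }
  pred
}

#' RLIPP from precomputed neuron states
#'
#' Core of the RLIPP score, decoupled from the model so that exported state
#' tables can be re-scored: fits a linear predictor of the observed response
#' from the parent term's neuron states (correlation P2) and one from the
#' children's states (correlation P1), and returns \code{(P2 - P1) / P1} —
#' the relative improvement the parent adds over what its children already
#' know. By default the fits are evaluated out-of-fold to avoid trivially
#' inflated correlations; \code{heldOut = FALSE} gives the plain in-sample
#' reading.
#'
#' The score ratio is only meaningful when the child-based correlation P1 is
#' positive and distinguishable from zero: near-zero P1 turns sampling noise
#' into arbitrarily large ratios. By default terms whose P1 fails a one-sided
#' significance test at \code{sigLevel} are flagged \code{undefined} (NA
#' score) rather than silently dominating the ranking; \code{sigLevel = 0}
#' disables the guard (only an exact P1 of 0 is then flagged).
#'
#' @param parentStates samples x k matrix of the parent term's neurons.
#' @param childStates named list of samples x k matrices, one per child.
#' @param y observed responses.
#' @param heldOut use out-of-fold predictions.
#' @param folds fold count for held-out fits.
#' @param ridge linear-fit penalty.
#' @param seed fold-assignment seed.
#' @param groups optional grouping vector (one entry per sample, e.g. the
#'   cell line of each pair); held-out folds are assigned by group so that
#'   repeated measures of one cell line never straddle a fold boundary.
#' @param aggregation \code{"concat"} (default): P1 from one linear model
#'   over the concatenated child states; \code{"mean"}: one model per child,
#'   per-sample predictions averaged before correlating.
#' @param sigLevel significance level of the P1 guard (0 disables).
#' @return one-row data.frame(P1, P2, rlipp, n_children, undefined); an
#'   undefined score is NA, never an infinity.
#' @export
rlippFromStates <- function(parentStates, childStates, y, heldOut = TRUE,
                            folds = 5L, ridge = 1e-6, seed = 1L,
                            groups = NULL,
                            aggregation = c("concat", "mean"),
                            sigLevel = 0.05) {
  aggregation <- match.arg(aggregation)
  if (!length(childStates)) stop("no children", call. = FALSE)
  if (length(y) < 3L) stop("need at least 3 samples", call. = FALSE)
  p2pred <- .ridgePredict(parentStates, y, heldOut, folds, ridge, seed,
                          groups)
  P2 <- .safeCor(p2pred, y)
  if (aggregation == "concat") {
    p1pred <- .ridgePredict(do.call(cbind, unname(childStates)), y,
                            heldOut, folds, ridge, seed, groups)
    P1 <- .safeCor(p1pred, y)
  } else {
    childPred <- vapply(childStates, function(S) {
      .ridgePredict(S, y, heldOut, folds, ridge, seed, groups)
    }, numeric(length(y)))
    P1 <- .safeCor(rowMeans(childPred), y)
  }
  undef <- is.na(P1) || is.na(P2) || abs(P1) < 1e-12
  if (!undef && sigLevel > 0) {
    n <- length(y)
    tcrit <- stats::qt(1 - sigLevel, n - 2L)
    rcrit <- tcrit / sqrt(n - 2L + tcrit^2)
    if (P1 <= rcrit) undef <- TRUE
  }
  data.frame(P1 = P1, P2 = P2,
             rlipp = if (undef) NA_real_ else (P2 - P1) / P1,
             n_children = length(childStates),
             undefined = undef)
}

#' RLIPP score of one subsystem
#'
#' Evaluates how much the parent term's neuron states improve on its
#' children's states at predicting the observed AUC, optionally restricted
#' to a single drug (as in per-drug pathway analyses).
#'
#' @param model a trained [DrugVNNModel-class].
#' @param data a [DrugResponseData-class].
#' @param term parent term id (must have at least one child term).
#' @param drugFilter optional drug id (or vector of ids) restricting the
#'   pairs; see [responsiveDrugs()] for the usual selection.
#' @param heldOut,folds,ridge,seed,aggregation,sigLevel see
#'   [rlippFromStates()].
#' @return one-row data.frame(term, P1, P2, rlipp, n_children, undefined).
#' @export
rlippScore <- function(model, data, term, drugFilter = NULL, heldOut = TRUE,
                       folds = 5L, ridge = 1e-6, seed = 1L,
                       aggregation = c("concat", "mean"), sigLevel = 0.05) {
  aggregation <- match.arg(aggregation)
  stopifnot(is(model, "DrugVNNModel"))
  arch <- model@arch
  if (!(term %in% arch@termOrder)) stop("unknown term: ", term, call. = FALSE)
  kids <- arch@termChildren[[term]]
  if (!length(kids)) {
    stop(sprintf("term '%s' has no children", term), call. = FALSE)
  }
  sel <- .rlippSamples(data, drugFilter)
  states <- vnnForward(model, data@cellX, mode = "eval")$states
  res <- rlippFromStates(states[[term]][sel$cell, , drop = FALSE],
                         lapply(states[kids], function(S) {
                           S[sel$cell, , drop = FALSE]
                         }),
                         sel$y, heldOut = heldOut, folds = folds,
                         ridge = ridge, seed = seed, groups = sel$cell,
                         aggregation = aggregation, sigLevel = sigLevel)
  cbind(data.frame(term = term, stringsAsFactors = FALSE), res)
}

.rlippSamples <- function(data, drugFilter) {
  tr <- data@triples
  if (!is.null(drugFilter)) {
    bad <- setdiff(drugFilter, data@drugIds)
    if (length(bad)) {
      stop("unknown drug id: ", paste(bad, collapse = ", "), call. = FALSE)
    }
    tr <- tr[tr$drug_id %in% drugFilter, , drop = FALSE]
  }
  if (nrow(tr) < 3L) {
    stop("need at least 3 samples for RLIPP", call. = FALSE)
  }
  list(cell = match(tr$cell_id, data@cellIds), y = tr$auc)
}

#' Drugs with above-average response variance
#'
#' Subsystem-importance analyses are run against drugs whose response
#' actually varies across cell lines (a flat response carries no genotype
#' signal to attribute): per-drug pathway analyses traditionally pick a
#' responsive compound by hand. This helper returns the drugs whose
#' per-drug AUC variance exceeds the mean of the per-drug variances.
#'
#' @param data a [DrugResponseData-class].
#' @param minPairs drugs with fewer observed pairs are skipped.
#' @return character vector of drug ids.
#' @export
responsiveDrugs <- function(data, minPairs = 10L) {
  tr <- data@triples
  cnt <- table(tr$drug_id)
  keep <- names(cnt)[cnt >= minPairs]
  v <- tapply(tr$auc[tr$drug_id %in% keep], tr$drug_id[tr$drug_id %in% keep],
              stats::var)
  sort(names(v)[v > mean(v)])
}

#' RLIPP scores for every scoreable subsystem
#'
#' Computes [rlippScore()] for every term with at least one child term,
#' sharing one forward pass and one fold assignment.
#'
#' @inheritParams rlippScore
#' @return data.frame, one row per scored term.
#' @export
rlippTable <- function(model, data, drugFilter = NULL, heldOut = TRUE,
                       folds = 5L, ridge = 1e-6, seed = 1L,
                       aggregation = c("concat", "mean"), sigLevel = 0.05) {
  aggregation <- match.arg(aggregation)
  stopifnot(is(model, "DrugVNNModel"))
  arch <- model@arch
  sel <- .rlippSamples(data, drugFilter)
  states <- vnnForward(model, data@cellX, mode = "eval")$states
  scoreable <- arch@termOrder[vapply(arch@termChildren[arch@termOrder],
                                     length, 0L) > 0L]
  rows <- lapply(scoreable, function(t) {
    res <- rlippFromStates(
      states[[t]][sel$cell, , drop = FALSE],
      lapply(states[arch@termChildren[[t]]], function(S) {
        S[sel$cell, , drop = FALSE]
      }),
      sel$y, heldOut = heldOut, folds = folds, ridge = ridge, seed = seed,
      groups = sel$cell, aggregation = aggregation, sigLevel = sigLevel)
    cbind(data.frame(term = t, stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank subsystems by RLIPP
#'
#' Orders scored terms by decreasing RLIPP (ties broken lexicographically by
#' term id; undefined scores sink to the bottom) and flags the top
#' \code{ceiling(topFraction * n)} terms.
#'
#' @param results data.frame from [rlippTable()] (needs \code{term} and
#'   \code{rlipp} columns).
#' @param topFraction fraction of terms to flag (default 0.10).
#' @return the table ordered, with dense \code{rank} and logical \code{top}
#'   columns added.
#' @export
rankSubsystems <- function(results, topFraction = 0.10) {
  if (!nrow(results)) stop("no scored terms", call. = FALSE)
  key <- results$rlipp
  ord <- order(-key, results$term, na.last = TRUE)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  nTop <- ceiling(topFraction * nrow(out))
  out$top <- out$rank <= nTop & !is.na(out$rlipp)
  rownames(out) <- NULL
  out
}

#' Read / write RLIPP tables
#'
#' TSV with header: term, P1, P2, rlipp, n_children, undefined (and, when
#' ranked, rank and top).
#'
#' @param path TSV path.
#' @return data.frame of scores.
#' @export
readRlipp <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE)
}

#' @rdname readRlipp
#' @param results data.frame from [rlippTable()] or [rankSubsystems()].
#' @export
writeRlipp <- function(results, path) {
  utils::write.table(results, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Two-component projection of entity states
#'
#' Mean-centered principal-component projection used for the 2-D genotype
#' and drug-structure embedding maps. Deterministic up to sign; the sign of
#' each component is fixed so that its largest-magnitude loading is
#' positive.
#'
#' @param states entities x features matrix (n >= 3, d >= 2).
#' @param ids optional entity ids (default rownames).
#' @param nComponents number of components (default 2).
#' @return object of class \code{Embedding2D}: list with \code{ids},
#'   \code{coordinates} (n x nComponents), \code{varExplained} and
#'   \code{rotation}.
#' @export
embedEntities <- function(states, ids = rownames(states), nComponents = 2L) {
  states <- as.matrix(states)
  if (nrow(states) < 3L) stop("need at least 3 entities", call. = FALSE)
  if (ncol(states) < 2L) stop("need at least 2 features", call. = FALSE)
  if (all(apply(states, 2L, stats::sd) == 0)) {
    stop("rank-0 state matrix: no variance to project", call. = FALSE)
  }
  pc <- stats::prcomp(states, center = TRUE, scale. = FALSE)
  nc <- min(nComponents, ncol(pc$rotation))
  rot <- pc$rotation[, seq_len(nc), drop = FALSE]
  sco <- pc$x[, seq_len(nc), drop = FALSE]
  for (j in seq_len(nc)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(ids = ids, coordinates = sco,
                 varExplained = ve[seq_len(nc)], rotation = rot),
            class = "Embedding2D")
}

#' @export
print.Embedding2D <- function(x, ...) {
  cat(sprintf("Embedding2D: %d entities, %d components (%.1f%% / %.1f%% var)\n",
              nrow(x$coordinates), ncol(x$coordinates),
              100 * x$varExplained[1],
              100 * ifelse(length(x$varExplained) > 1, x$varExplained[2], 0)))
  invisible(x)
}

#' Genotype / drug embedding maps of a trained model
#'
#' \code{cellEmbeddings} projects the root subsystem states of every cell
#' line; \code{drugEmbeddings} projects the drug-branch embeddings of every
#' drug.
#'
#' @param model a trained [DrugVNNModel-class].
#' @param data a [DrugResponseData-class].
#' @param nComponents number of components.
#' @return an \code{Embedding2D} (see [embedEntities()]).
#' @export
cellEmbeddings <- function(model, data, nComponents = 2L) {
  root <- vnnForward(model, data@cellX, mode = "eval")$rootEmbedding
  rownames(root) <- data@cellIds
  embedEntities(root, nComponents = nComponents)
}

#' @rdname cellEmbeddings
#' @export
drugEmbeddings <- function(model, data, nComponents = 2L) {
  emb <- annForward(model, data@fpMatrix, mode = "eval")
  rownames(emb) <- data@drugIds
  embedEntities(emb, nComponents = nComponents)
}

#' Export per-sample subsystem states
#'
#' Writes (or returns) a table of each requested term's neuron values and
#' auxiliary prediction for every cell line, for downstream
#' sensitivity/resistance plots.
#'
#' @param model a trained [DrugVNNModel-class].
#' @param data a [DrugResponseData-class].
#' @param terms term ids to export (default: all).
#' @param path optional TSV output path.
#' @return data.frame: \code{cell_id}, then \code{<term>.n<j>} neuron
#'   columns and \code{<term>.aux} per requested term.
#' @export
subsystemStateExport <- function(model, data, terms = NULL, path = NULL) {
  stopifnot(is(model, "DrugVNNModel"))
  arch <- model@arch
  if (is.null(terms)) terms <- arch@termOrder
  bad <- setdiff(terms, arch@termOrder)
  if (length(bad)) {
    stop("unknown term ids: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  fw <- vnnForward(model, data@cellX, mode = "eval")
  cols <- list(data.frame(cell_id = data@cellIds, stringsAsFactors = FALSE))
  for (t in terms) {
    S <- fw$states[[t]]
    colnames(S) <- sprintf("%s.n%d", t, seq_len(ncol(S)))
    df <- as.data.frame(S)
    df[[sprintf("%s.aux", t)]] <- fw$auxPredictions[[t]]
    cols[[length(cols) + 1L]] <- df
  }
  out <- do.call(cbind, cols)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
  }
  out
}
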