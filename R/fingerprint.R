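## Morgan (circular, ECFP-style) fingerprints over SMILES.
##
## SMILES parsing, kekulization and ring perception are delegated to
## ChemmineR/ChemmineOB; the iterative neighborhood hashing and folding are
## implemented here. Bit positions are deterministic for a given
## SMILES/radius/nBits but, like any folded fingerprint, are specific to this
## implementation's atom invariants and hash.

## default valences of the organic subset, for implicit-H counting
.DEFAULT_VALENCE <- c(H = 1, B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4,
                      P = 3, S = 2, Cl = 1, Br = 1, I = 1)

.ATOMIC_NUMBER <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Na = 11,
                    Mg = 12, Si = 14, P = 15, S = 16, Cl = 17, K = 19,
                    Ca = 20, Fe = 26, Zn = 30, Se = 34, Br = 35, I = 53)

## legacy MDL charge codes as written in SDF atom blocks
.MDL_CHARGE <- c(0, 3, 2, 1, 0, -1, -2, -3)

#' Morgan fingerprint of a SMILES string
#'
#' Computes a folded circular-substructure fingerprint: every atom starts
#' from a hashed invariant tuple (atomic number, heavy degree, implicit H
#' count, formal charge, ring membership) and is iteratively re-hashed with
#' its neighbors' identifiers and bond orders up to \code{radius} rounds; all
#' identifiers are folded modulo \code{nBits} into a binary vector. The
#' result is deterministic for identical \code{smiles}/\code{radius}/
#' \code{nBits}.
#'
#' @param smiles SMILES string of the molecule.
#' @param radius circular neighborhood radius (default 2, ECFP4-like).
#' @param nBits folded fingerprint length (default 2048).
#' @param drugId optional identifier stored on the result.
#' @return a [DrugFingerprint-class].
#' @examples
#' \donttest{
#' fp <- morganFingerprint("CC(=O)Oc1ccccc1C(=O)O", drugId = "aspirin")
#' sum(fpBits(fp))
#' }
#' @export
morganFingerprint <- function(smiles, radius = 2L, nBits = 2048L,
                              drugId = NA_character_) {
  if (!is.character(smiles) || length(smiles) != 1L || !nzchar(smiles)) {
    stop("'smiles' must be a single nonempty string", call. = FALSE)
  }
  if (nBits <= 0L) stop("'nBits' must be positive", call. = FALSE)
  if (radius < 0L) stop("'radius' must be >= 0", call. = FALSE)
  mol <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)[[1]]),
    error = function(e) NULL)
  ab <- if (is.null(mol)) NULL else tryCatch(ChemmineR::atomblock(mol),
                                             error = function(e) NULL)
  if (is.null(ab) || nrow(ab) == 0L) {
    stop(sprintf("unparseable SMILES: '%s'", smiles), call. = FALSE)
  }
  elem <- sub("_.*$", "", rownames(ab))
  nAtom <- nrow(ab)
  charge <- rep(0L, nAtom)
  if ("C6" %in% colnames(ab)) {
    code <- ab[, "C6"]
    ok <- code >= 0 & code <= 7
    charge[ok] <- .MDL_CHARGE[code[ok] + 1L]
  }
  bb <- tryCatch(ChemmineR::bondblock(mol), error = function(e) NULL)
  nb <- vector("list", nAtom)          # neighbor atom indices
  bo <- vector("list", nAtom)          # corresponding bond orders
  if (!is.null(bb) && nrow(bb) > 0L && ncol(bb) >= 3L) {
    for (i in seq_len(nrow(bb))) {
      a <- bb[i, 1L]; b <- bb[i, 2L]; o <- bb[i, 3L]
      if (a < 1L || b < 1L || a > nAtom || b > nAtom) next
      nb[[a]] <- c(nb[[a]], b); bo[[a]] <- c(bo[[a]], o)
      nb[[b]] <- c(nb[[b]], a); bo[[b]] <- c(bo[[b]], o)
    }
  }
  inRing <- rep(0L, nAtom)
  ringAtoms <- tryCatch(
    unique(unlist(ChemmineR::rings(mol, type = "all"))),
    error = function(e) character(0))
  if (length(ringAtoms)) inRing[match(ringAtoms, rownames(ab))] <- 1L
  degree <- vapply(nb, length, 0L)
  orderSum <- vapply(bo, function(o) if (length(o)) sum(pmin(o, 3)) else 0, 0)
  defv <- .DEFAULT_VALENCE[elem]
  defv[is.na(defv)] <- 0
  hcount <- pmax(0, defv + charge - orderSum)
  anum <- .ATOMIC_NUMBER[elem]
  anum[is.na(anum)] <- 0

  ids <- vapply(seq_len(nAtom), function(a) {
    .hash32(c(anum[a], degree[a], hcount[a], charge[a], inRing[a]))
  }, 0)
  features <- ids
  if (radius >= 1L) {
    for (r in seq_len(radius)) {
      newIds <- vapply(seq_len(nAtom), function(a) {
        ## isolated atoms have no growing environment; their id is final
        if (!length(nb[[a]])) return(ids[a])
        pairs <- cbind(bo[[a]], ids[nb[[a]]])
        pairs <- pairs[order(pairs[, 1L], pairs[, 2L]), , drop = FALSE]
        .hash32(c(r, ids[a], as.vector(t(pairs))))
      }, 0)
      ids <- newIds
      features <- c(features, ids)
    }
  }
  bits <- integer(nBits)
  bits[(unique(features) %% nBits) + 1L] <- 1L
  new("DrugFingerprint", drugId = as.character(drugId), smiles = smiles,
      bits = bits, radius = as.integer(radius), nBits = as.integer(nBits))
}

#' Read a drug table
#'
#' Reads a headerless \code{drug_id<TAB>structure} TSV. The structure column
#' is either a SMILES string or, for synthetic cohorts, a literal 0/1
#' bitstring of length \code{nBits} (auto-detected); bitstrings are taken as
#' the fingerprint directly, SMILES are encoded with [morganFingerprint()].
#'
#' @param path TSV path.
#' @param radius,nBits fingerprint parameters for SMILES rows.
#' @return data.frame with columns \code{drug_id}, \code{structure}.
#' @export
readDrugTable <- function(path, radius = 2L, nBits = 2048L) {
  df <- utils::read.table(path, sep = "\t", header = FALSE, quote = "",
                          comment.char = "", stringsAsFactors = FALSE,
                          col.names = c("drug_id", "structure"),
                          colClasses = "character")
  if (anyDuplicated(df$drug_id)) {
    stop("duplicate drug ids in ", path, call. = FALSE)
  }
  df
}

#' @rdname readDrugTable
#' @param drugs data.frame as returned by \code{readDrugTable}.
#' @export
writeDrugTable <- function(drugs, path) {
  utils::write.table(drugs[, c("drug_id", "structure")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.isBitstring <- function(s) {
  nchar(s) >= 32L & grepl("^[01]+$", s)
}

#' Fingerprint matrix for a drug table
#'
#' @param drugs data.frame with \code{drug_id} and \code{structure} columns
#'   (SMILES or bitstrings, see [readDrugTable()]).
#' @param radius,nBits fingerprint parameters.
#' @return binary matrix, drugs x nBits, rownames = drug ids.
#' @export
drugFingerprintMatrix <- function(drugs, radius = 2L, nBits = 2048L) {
  fp <- matrix(0L, nrow = nrow(drugs), ncol = nBits,
               dimnames = list(drugs$drug_id, NULL))
  for (i in seq_len(nrow(drugs))) {
    s <- drugs$structure[i]
    if (.isBitstring(s)) {
      if (nchar(s) != nBits) {
        stop(sprintf("drug '%s': bitstring length %d, expected %d",
                     drugs$drug_id[i], nchar(s), nBits), call. = FALSE)
      }
      fp[i, ] <- as.integer(strsplit(s, "")[[1]])
    } else {
      fp[i, ] <- morganFingerprint(s, radius = radius, nBits = nBits,
                                   drugId = drugs$drug_id[i])@bits
    }
  }
  fp
}
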