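## Genotype encoding: normalization, imputation, Gray coding, channel fusion.

#' Per-gene min-max normalization
#'
#' Scales each gene (column) of a cells x genes matrix to \[0, 1\] by
#' \code{(x - min) / (max - min)}. Constant columns map to 0, keeping the
#' output in range without NaN.
#'
#' @param m numeric matrix, cells in rows, genes in columns.
#' @return matrix of the same shape with values in \[0, 1\].
#' @examples
#' minmaxNormalize(cbind(g1 = c(2, 4, 6), g2 = c(5, 5, 5)))
#' @export
minmaxNormalize <- function(m) {
  m <- .asNumericMatrix(m)
  if (nrow(m) < 1L) stop("matrix must have at least one row", call. = FALSE)
  lo <- apply(m, 2L, min)
  hi <- apply(m, 2L, max)
  rng <- hi - lo
  out <- sweep(m, 2L, lo, "-")
  const <- rng == 0
  rng[const] <- 1
  out <- sweep(out, 2L, rng, "/")
  out[, const] <- 0
  out
}

.asNumericMatrix <- function(m) {
  if (is.data.frame(m)) m <- as.matrix(m)
  if (!is.numeric(m)) {
    idx <- which(!vapply(as.vector(m), is.numeric, TRUE))[1]
    rc <- arrayInd(idx, dim(m))
    stop(sprintf("non-numeric entry at cell row %d, gene column %d (%s)",
                 rc[1], rc[2],
                 if (!is.null(colnames(m))) colnames(m)[rc[2]] else "unnamed"),
         call. = FALSE)
  }
  m
}

#' Mean imputation of missing genotype entries
#'
#' Replaces each missing entry by the mean of the observed values of the same
#' gene across cell lines. A gene with no observed value at all cannot be
#' imputed and raises an error naming it.
#'
#' @param m numeric matrix with possible \code{NA}s, cells x genes.
#' @return complete matrix; observed entries are untouched.
#' @export
imputeMissing <- function(m) {
  m <- .asNumericMatrix(m)
  nObs <- colSums(!is.na(m))
  if (any(nObs == 0L)) {
    g <- which(nObs == 0L)[1]
    stop(sprintf("gene column %d (%s) is fully missing and cannot be imputed",
                 g, if (!is.null(colnames(m))) colnames(m)[g] else "unnamed"),
         call. = FALSE)
  }
  mu <- unname(colMeans(m, na.rm = TRUE))
  idx <- which(is.na(m), arr.ind = TRUE)
  if (nrow(idx)) m[idx] <- mu[idx[, 2L]]
  m
}

#' Reflected Gray transform of a bit vector
#'
#' Treats the vector as an ordered bit word and applies the standard
#' binary-to-Gray transform: \code{out[1] = in[1]},
#' \code{out[i] = xor(in[i], in[i-1])}. Length-preserving and bijective;
#' [grayDecode()] inverts it. Applied (optionally) to the one-hot mutation
#' vector before fusion.
#'
#' @param bits 0/1 vector.
#' @return 0/1 integer vector of the same length.
#' @examples
#' grayEncode(c(1, 0, 1, 1))        # 1 1 1 0
#' grayDecode(grayEncode(c(1, 0, 1, 1)))
#' @export
grayEncode <- function(bits) {
  .assertBinaryVector(bits, "bits")
  b <- as.integer(bits)
  as.integer(bitwXor(b, c(0L, b[-length(b)])))
}

#' @rdname grayEncode
#' @export
grayDecode <- function(bits) {
  .assertBinaryVector(bits, "bits")
  as.integer(cumsum(as.integer(bits)) %% 2L)
}

#' Fuse the three genotype channels into the VNN input
#'
#' \code{mean} mode superposes the channels without changing dimensions: the
#' element-wise mean of mutation, expression and CNV, one value per gene.
#' \code{stack} mode keeps the three channels side by side, giving each gene
#' an input width of 3.
#'
#' Vector and matrix (cells x genes) inputs are both supported. In stack mode
#' the per-gene channel triplets are interleaved gene-by-gene
#' (g1.mut, g1.expr, g1.cnv, g2.mut, ...), matching the wiring order used by
#' the compiled architecture.
#'
#' @param mut,expr,cnv aligned vectors or matrices over the same gene index.
#' @param mode \code{"mean"} or \code{"stack"}.
#' @return fused vector/matrix; width G in mean mode, 3G in stack mode.
#' @export
fuseGenotypes <- function(mut, expr, cnv, mode = c("mean", "stack")) {
  mode <- match.arg(mode)
  vec <- is.null(dim(mut))
  toM <- function(x) if (is.null(dim(x))) matrix(x, nrow = 1L) else as.matrix(x)
  m <- toM(mut); e <- toM(expr); c <- toM(cnv)
  if (!all(dim(m) == dim(e)) || !all(dim(m) == dim(c))) {
    stop(sprintf("genotype channels disagree in size: %s vs %s vs %s genes",
                 ncol(m), ncol(e), ncol(c)), call. = FALSE)
  }
  if (mode == "mean") {
    out <- (m + e + c) / 3
  } else {
    G <- ncol(m)
    out <- matrix(0, nrow = nrow(m), ncol = 3L * G)
    out[, seq(1L, 3L * G, by = 3L)] <- m
    out[, seq(2L, 3L * G, by = 3L)] <- e
    out[, seq(3L, 3L * G, by = 3L)] <- c
    if (!is.null(colnames(m))) {
      colnames(out) <- paste(rep(colnames(m), each = 3L),
                             c("mut", "expr", "cnv"), sep = ".")
    }
  }
  if (vec) out[1L, ] else out
}
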