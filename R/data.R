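## Dataset assembly: align genotype channels, drugs and triples to a gene
## index and fuse them into model-ready matrices.

#' Assemble an aligned response dataset
#'
#' Aligns the three genotype channels to the gene index, imputes missing
#' entries per gene ([imputeMissing()]), min-max normalizes the continuous
#' channels ([minmaxNormalize()]; mutation calls are kept binary), optionally
#' Gray-encodes each cell's mutation vector, fuses the channels
#' ([fuseGenotypes()]) and encodes the drug table into a fingerprint matrix.
#' A channel supplied as \code{NULL} (a cohort lacking that assay) is
#' substituted by the element-wise mean of the available channels, with a
#' loud message.
#'
#' @param mutation,expression,cnv cells x genes matrices (rownames = cell
#'   ids, colnames = gene ids); any may be \code{NULL}, not all.
#' @param drugs drug table data.frame (see [readDrugTable()]).
#' @param triples response data.frame(cell_id, drug_id, auc).
#' @param geneIndex ordered gene vocabulary (e.g. from the architecture).
#' @param fusion \code{"mean"} or \code{"stack"}.
#' @param gray Gray-encode mutation bits before fusion.
#' @param radius,nBits fingerprint parameters.
#' @return a [DrugResponseData-class].
#' @export
assembleDataset <- function(mutation, expression, cnv, drugs, triples,
                            geneIndex, fusion = c("mean", "stack"),
                            gray = FALSE, radius = 2L, nBits = 2048L) {
  fusion <- match.arg(fusion)
  chans <- list(mutation = mutation, expression = expression, cnv = cnv)
  have <- !vapply(chans, is.null, TRUE)
  if (!any(have)) stop("at least one genotype channel required", call. = FALSE)
  cellIds <- rownames(chans[[which(have)[1]]])
  align <- function(m, name) {
    missing <- setdiff(geneIndex, colnames(m))
    if (length(missing)) {
      stop(sprintf("%s matrix lacks %d genes of the index (first: %s)",
                   name, length(missing), missing[1]), call. = FALSE)
    }
    if (!identical(rownames(m), cellIds)) {
      m <- m[cellIds, , drop = FALSE]
    }
    imputeMissing(m[, geneIndex, drop = FALSE])
  }
  for (nm in names(chans)[have]) chans[[nm]] <- align(chans[[nm]], nm)
  ## normalize continuous channels per gene; mutations stay binary 0/1
  for (nm in intersect(c("expression", "cnv"), names(chans)[have])) {
    chans[[nm]] <- minmaxNormalize(chans[[nm]])
  }
  if (any(!have)) {
    avail <- chans[have]
    fill <- Reduce(`+`, avail) / length(avail)
    for (nm in names(chans)[!have]) {
      message("genotype channel '", nm, "' missing: substituting the ",
              "per-gene mean of the available channels")
      chans[[nm]] <- fill
    }
  }
  mut <- chans$mutation
  if (gray) {
    mut <- t(apply(mut, 1L, grayEncode))
    dimnames(mut) <- dimnames(chans$mutation)
  }
  cellX <- fuseGenotypes(mut, chans$expression, chans$cnv, mode = fusion)
  rownames(cellX) <- cellIds
  fpM <- drugFingerprintMatrix(drugs, radius = radius, nBits = nBits)
  badC <- setdiff(triples$cell_id, cellIds)
  badD <- setdiff(triples$drug_id, rownames(fpM))
  if (length(badC) || length(badD)) {
    stop("triples reference unknown ids: ",
         paste(c(badC, badD), collapse = ", "), call. = FALSE)
  }
  out <- triples$auc < 0 | triples$auc > 1
  if (any(out)) {
    warning(sprintf("%d AUC values outside [0, 1]", sum(out)), call. = FALSE)
  }
  new("DrugResponseData",
      cellIds = cellIds, drugIds = rownames(fpM), geneIndex = geneIndex,
      cellX = cellX, channels = chans, fpMatrix = fpM,
      triples = triples, fusion = fusion, gray = gray)
}

#' Load a cohort directory
#'
#' Reads the standard file layout written by [simulateCohort()] (and
#' expected from real cohorts): \code{ontology.txt}, \code{mutation.csv},
#' \code{expression.csv}, \code{cnv.csv}, \code{drugs.tsv},
#' \code{triples.tsv}, and assembles the dataset against the ontology's gene
#' index.
#'
#' @param dir cohort directory.
#' @param fusion,gray,radius,nBits see [assembleDataset()].
#' @param neuronRule,geneChannelWidth see [layerArchitecture()];
#'   \code{geneChannelWidth} defaults to 1 for mean fusion, 3 for stack.
#' @return list with \code{ontology}, \code{arch}, \code{data}.
#' @export
readCohort <- function(dir, fusion = c("mean", "stack"), gray = FALSE,
                       radius = 2L, nBits = 2048L,
                       neuronRule = list(fixed = 6L),
                       geneChannelWidth = NULL) {
  fusion <- match.arg(fusion)
  if (is.null(geneChannelWidth)) {
    geneChannelWidth <- if (fusion == "stack") 3L else 1L
  }
  ont <- loadOntology(file.path(dir, "ontology.txt"))
  arch <- layerArchitecture(ont, neuronRule = neuronRule,
                            geneChannelWidth = geneChannelWidth)
  triples <- readResponseTriples(file.path(dir, "triples.tsv"))
  drugs <- readDrugTable(file.path(dir, "drugs.tsv"))
  readOpt <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) readGenotypeMatrix(p) else NULL
  }
  data <- assembleDataset(readOpt("mutation.csv"), readOpt("expression.csv"),
                          readOpt("cnv.csv"), drugs, triples,
                          geneIndex = geneIndex(arch), fusion = fusion,
                          gray = gray, radius = radius, nBits = nBits)
  list(ontology = ont, arch = arch, data = data)
}
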