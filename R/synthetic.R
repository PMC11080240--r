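## Synthetic study cohorts: toy ontology + genotypes + drugs + responses with
## a planted gene-set x drug-bit interaction, so the full pipeline is
## testable without any external download.

#' Build a synthetic cohort specification
#'
#' Defaults describe the desk-scale study cohort: 30 terms (depth <= 6,
#' mirroring typical compiled hierarchies), 100 genes, 200 cell lines, 25
#' drugs, 2,000 response pairs. Mutations are Bernoulli(0.1); expression and
#' copy number are Uniform(0, 1); fingerprints average 81 set bits. The
#' response law is
#' \code{AUC = clip(c0 - c1 * mean(fused genotype over the planted term's
#' descendant genes) * drug[plantedBit] + N(0, noiseSd), 0, 1)},
#' a multiplicative gene-set x drug-bit interaction: both branches are
#' needed to fit it. The planted bit is set in half the drugs (background
#' bit rates are adjusted so the popcount average stays 81); a bit at the
#' background 81/2048 rate would be present in about one drug in 25 and
#' carry no learnable signal at this scale.
#'
#' @param nTerms,maxDepth,nGenes,nCells,nDrugs,nPairs,nBits cohort sizes.
#' @param plantedTerm planted term id; \code{NA} auto-selects a term with at
#'   least one child and a descendant gene count near \code{nGenes / 10}.
#' @param plantedBit planted fingerprint bit; \code{NA} auto-selects.
#' @param c0 baseline AUC (no-effect level).
#' @param c1 effect size of the planted interaction.
#' @param noiseSd gaussian noise SD.
#' @param mutRate per-gene mutation probability.
#' @param meanBitsOn target mean fingerprint popcount.
#' @param seed RNG seed; all generated files are byte-identical for an
#'   identical spec.
#' @return a [SimSpec-class].
#' @export
simSpec <- function(nTerms = 30L, maxDepth = 6L, nGenes = 100L,
                    nCells = 200L, nDrugs = 25L, nPairs = 2000L,
                    nBits = 2048L, plantedTerm = NA_character_,
                    plantedBit = NA_integer_, c0 = 0.9, c1 = 1.0,
                    noiseSd = 0.05, mutRate = 0.1, meanBitsOn = 81,
                    seed = 1L) {
  if (nTerms >= 2L && maxDepth < 2L) {
    stop("infeasible spec: depth 1 cannot hold more than one term",
         call. = FALSE)
  }
  if (noiseSd < 0) stop("noiseSd must be >= 0", call. = FALSE)
  new("SimSpec",
      nTerms = as.integer(nTerms), maxDepth = as.integer(maxDepth),
      nGenes = as.integer(nGenes), nCells = as.integer(nCells),
      nDrugs = as.integer(nDrugs), nPairs = as.integer(nPairs),
      nBits = as.integer(nBits),
      plantedTerm = as.character(plantedTerm),
      plantedBit = as.integer(plantedBit),
      c0 = c0, c1 = c1, noiseSd = noiseSd, mutRate = mutRate,
      meanBitsOn = meanBitsOn, seed = as.integer(seed))
}

#' Generate a random toy ontology
#'
#' Seeded random DAG with a unique root and depth at most
#' \code{spec@maxDepth}: each new term attaches under an existing term (one
#' level deeper), with a 25% chance of a second parent at a strictly
#' shallower level, so multi-parent wiring is exercised. Every leaf receives
#' at least one directly annotated gene and remaining genes are spread over
#' all terms, so every term has annotated genes in its descendant closure.
#'
#' @param spec a [SimSpec-class].
#' @return a validated [Ontology-class].
#' @export
makeToyOntology <- function(spec) {
  stopifnot(is(spec, "SimSpec"))
  n <- spec@nTerms
  if (n < 2L) stop("need at least 2 terms", call. = FALSE)
  .withSeed(.deriveSeed(spec@seed, "ontology"), {
    terms <- sprintf("T%03d", seq_len(n))
    root <- terms[1L]
    level <- c(1L, rep(NA_integer_, n - 1L))
    child <- character(0); parent <- character(0)
    for (i in 2:n) {
      eligible <- which(!is.na(level[1:(i - 1L)]) &
                          level[1:(i - 1L)] < spec@maxDepth)
      p <- eligible[sample.int(length(eligible), 1L)]
      level[i] <- level[p] + 1L
      child <- c(child, terms[i]); parent <- c(parent, terms[p])
      shallower <- which(level[1:(i - 1L)] < level[i])
      shallower <- setdiff(shallower, p)
      if (length(shallower) && stats::runif(1) < 0.25) {
        p2 <- shallower[sample.int(length(shallower), 1L)]
        child <- c(child, terms[i]); parent <- c(parent, terms[p2])
      }
    }
    edges <- data.frame(child = child, parent = parent,
                        stringsAsFactors = FALSE)
    leaves <- setdiff(terms, unique(parent))
    genes <- sprintf("g%03d", seq_len(spec@nGenes))
    if (length(genes) < length(leaves)) {
      stop(sprintf("infeasible spec: %d leaves but only %d genes",
                   length(leaves), length(genes)), call. = FALSE)
    }
    shuffled <- sample(genes)
    annTerm <- character(spec@nGenes)
    annTerm[seq_along(leaves)] <- leaves
    ## internal terms whose children are all leaves also get a few direct
    ## genes each (GO-like hierarchies annotate internal terms directly; it
    ## also gives planted mechanisms a well-defined emergence point)
    leafParents <- sort(unique(parent[child %in% leaves]))
    leafParents <- leafParents[vapply(leafParents, function(p) {
      all(child[parent == p] %in% leaves)
    }, TRUE)]
    used <- length(leaves)
    lpSlots <- rep(leafParents, 3L)
    nlp <- min(length(lpSlots), spec@nGenes - used)
    if (nlp > 0L) annTerm[used + seq_len(nlp)] <- lpSlots[seq_len(nlp)]
    used <- used + nlp
    if (used < spec@nGenes) {
      rest <- (used + 1L):spec@nGenes
      annTerm[rest] <- terms[sample.int(n, length(rest), replace = TRUE)]
    }
    ann <- split(annTerm, shuffled)
    o <- .newOntology(terms, edges, ann)
    validObject(o)
    o
  })
}

## Deterministic choice of the planted term. The mechanism must EMERGE at
## the planted term for subsystem-importance recovery to be well-posed:
## a term carrying no direct annotations is indistinguishable from the
## union of its children. Preferred candidates are therefore non-root terms
## whose children are all leaves and which carry direct annotations of
## their own; among them, the descendant gene count closest to nGenes / 10
## wins (ties: more direct genes, then lexicographic id). Falls back to any
## term with children, then any non-root term.
.choosePlantedTerm <- function(spec, o) {
  if (!is.na(spec@plantedTerm)) {
    if (!(spec@plantedTerm %in% o@terms)) {
      stop("planted term not in ontology: ", spec@plantedTerm, call. = FALSE)
    }
    return(spec@plantedTerm)
  }
  desc <- .descendantGenes(o@terms, o@edges, o@annotations)
  direct <- stats::setNames(integer(length(o@terms)), o@terms)
  for (g in names(o@annotations)) {
    for (t in o@annotations[[g]]) direct[t] <- direct[t] + 1L
  }
  childOf <- .childMap(o@terms, o@edges)
  nChildren <- vapply(childOf, length, 0L)
  leaves <- o@terms[nChildren == 0L]
  allLeafKids <- vapply(o@terms, function(t) {
    length(childOf[[t]]) > 0L && all(childOf[[t]] %in% leaves)
  }, TRUE)
  sizes <- vapply(desc, length, 0L)
  share <- ifelse(sizes > 0L, direct / sizes, 0)
  ## both the emergence (direct genes, driving the score's numerator) and
  ## the child signal (genes below, its denominator) must be detectable;
  ## a direct-annotation share around one half to three quarters keeps the
  ## emergence ratio well above sampling noise while the children stay
  ## significantly predictive
  ok <- allLeafKids & direct > 0L & (sizes - direct) >= 2L &
    o@terms != o@root
  cand <- o@terms[ok & share >= 0.45 & share <= 0.8]
  if (!length(cand)) cand <- o@terms[ok & share >= 0.2]
  if (!length(cand)) {
    cand <- o@terms[allLeafKids & direct > 0L & o@terms != o@root]
  }
  if (!length(cand)) cand <- o@terms[nChildren > 0L & o@terms != o@root]
  if (!length(cand)) cand <- setdiff(o@terms, o@root)
  target <- spec@nGenes / 10
  cand[order(abs(sizes[cand] - target), -direct[cand], cand)][1L]
}

#' Simulate a complete cohort to disk
#'
#' Writes every file the rest of the pipeline consumes: the ontology
#' (canonical tab dialect), the three genotype CSVs, the drug table (0/1
#' fingerprint bitstrings), the response triples and the 0-based index
#' files. Identical specs produce byte-identical files.
#'
#' @param spec a [SimSpec-class].
#' @param dir output directory (created if needed).
#' @param ontology optional pre-built [Ontology-class]; by default
#'   [makeToyOntology()] is used.
#' @return invisible list: \code{dir}, \code{ontology}, \code{plantedTerm},
#'   \code{plantedBit}, \code{plantedGenes}, and the file paths.
#' @export
simulateCohort <- function(spec, dir, ontology = NULL) {
  stopifnot(is(spec, "SimSpec"))
  if (is.null(ontology)) ontology <- makeToyOntology(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plantedTerm <- .choosePlantedTerm(spec, ontology)
  desc <- .descendantGenes(ontology@terms, ontology@edges,
                           ontology@annotations)
  plantedGenes <- desc[[plantedTerm]]
  genes <- ontology@genes
  cells <- sprintf("C%04d", seq_len(spec@nCells))
  drugIds <- sprintf("D%03d", seq_len(spec@nDrugs))

  sim <- .withSeed(.deriveSeed(spec@seed, "cohort"), {
    G <- spec@nGenes
    mut <- matrix(stats::rbinom(spec@nCells * G, 1L, spec@mutRate),
                  spec@nCells, G, dimnames = list(cells, genes))
    expr <- matrix(round(stats::runif(spec@nCells * G), 6L),
                   spec@nCells, G, dimnames = list(cells, genes))
    cnv <- matrix(round(stats::runif(spec@nCells * G), 6L),
                  spec@nCells, G, dimnames = list(cells, genes))
    plantedBit <- if (is.na(spec@plantedBit)) {
      sample.int(spec@nBits, 1L)
    } else spec@plantedBit
    pBg <- min(1, max(0, (spec@meanBitsOn - 0.5) / (spec@nBits - 1L)))
    fp <- matrix(stats::rbinom(spec@nDrugs * spec@nBits, 1L, pBg),
                 spec@nDrugs, spec@nBits, dimnames = list(drugIds, NULL))
    fp[, plantedBit] <- stats::rbinom(spec@nDrugs, 1L, 0.5)
    total <- spec@nCells * spec@nDrugs
    if (spec@nPairs > total) {
      stop("nPairs exceeds the number of distinct cell x drug pairs",
           call. = FALSE)
    }
    take <- sample.int(total, spec@nPairs)
    pairCell <- ((take - 1L) %% spec@nCells) + 1L
    pairDrug <- ((take - 1L) %/% spec@nCells) + 1L
    fused <- (mut + expr + cnv) / 3
    M <- rowMeans(fused[, plantedGenes, drop = FALSE])
    auc <- spec@c0 - spec@c1 * M[pairCell] * fp[cbind(pairDrug, plantedBit)]
    if (spec@noiseSd > 0) {
      auc <- auc + stats::rnorm(spec@nPairs, 0, spec@noiseSd)
    }
    auc <- round(pmin(1, pmax(0, auc)), 6L)
    list(mut = mut, expr = expr, cnv = cnv, fp = fp,
         plantedBit = plantedBit,
         triples = data.frame(cell_id = cells[pairCell],
                              drug_id = drugIds[pairDrug],
                              auc = auc, stringsAsFactors = FALSE))
  })

  paths <- list(
    ontology = file.path(dir, "ontology.txt"),
    mutation = file.path(dir, "mutation.csv"),
    expression = file.path(dir, "expression.csv"),
    cnv = file.path(dir, "cnv.csv"),
    drugs = file.path(dir, "drugs.tsv"),
    triples = file.path(dir, "triples.tsv"),
    gene2ind = file.path(dir, "gene2ind.txt"),
    cell2ind = file.path(dir, "cell2ind.txt"),
    drug2ind = file.path(dir, "drug2ind.txt"))
  writeOntology(ontology, paths$ontology)
  writeGenotypeMatrix(sim$mut, paths$mutation)
  writeGenotypeMatrix(sim$expr, paths$expression)
  writeGenotypeMatrix(sim$cnv, paths$cnv)
  writeDrugTable(data.frame(
    drug_id = drugIds,
    structure = apply(sim$fp, 1L, paste, collapse = ""),
    stringsAsFactors = FALSE), paths$drugs)
  writeResponseTriples(sim$triples, paths$triples)
  writeIndexFile(genes, paths$gene2ind)
  writeIndexFile(cells, paths$cell2ind)
  writeIndexFile(drugIds, paths$drug2ind)
  invisible(c(list(dir = dir, ontology = ontology,
                   plantedTerm = plantedTerm,
                   plantedBit = sim$plantedBit,
                   plantedGenes = plantedGenes), paths))
}
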