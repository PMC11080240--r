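## Shared fixtures and independent oracles for the test suite.

## Write an ontology file from (parent, child, relation) rows.
writeOntoFile <- function(rows) {
  f <- tempfile(fileext = ".txt")
  writeLines(vapply(rows, function(r) paste(r, collapse = "\t"), ""), f)
  f
}

## chain root -> A -> B, genes g1 on B, g2 on A, g3 on root
chainOntology <- function() {
  loadOntology(writeOntoFile(list(
    c("root", "A", "default"),
    c("A", "B", "default"),
    c("B", "g1", "gene"),
    c("A", "g2", "gene"),
    c("root", "g3", "gene"))))
}

## diamond A -> {B, C} -> D (A root), genes on D and B
diamondOntology <- function() {
  loadOntology(writeOntoFile(list(
    c("A", "B", "default"),
    c("A", "C", "default"),
    c("B", "D", "default"),
    c("C", "D", "default"),
    c("D", "g1", "gene"),
    c("B", "g2", "gene"),
    c("A", "g3", "gene"),
    c("C", "g4", "gene"))))
}

## Independent longest-path oracle: exhaustive DFS over all root-to-leaf
## paths, counting terms on the path.
bruteDepth <- function(o) {
  edges <- ontoEdges(o)
  kids <- function(t) sort(edges$child[edges$parent == t])
  dfs <- function(t) {
    ch <- kids(t)
    if (!length(ch)) return(1L)
    1L + max(vapply(ch, dfs, 0L))
  }
  dfs(ontoRoot(o))
}

## Independent topological-order check: every edge's child strictly before
## its parent.
isValidTopo <- function(ord, o) {
  pos <- stats::setNames(seq_along(ord), ord)
  edges <- ontoEdges(o)
  all(pos[edges$child] < pos[edges$parent])
}

## Independent descendant-annotation oracle by DFS reachability.
bruteDescGenes <- function(o, term) {
  edges <- ontoEdges(o)
  ann <- ontoAnnotations(o)
  reach <- term
  repeat {
    more <- unique(edges$child[edges$parent %in% reach])
    more <- setdiff(more, reach)
    if (!length(more)) break
    reach <- c(reach, more)
  }
  sort(unique(names(ann)[vapply(ann, function(ts) any(ts %in% reach), TRUE)]))
}

## Small simulated cohort on disk, cached per (seed, size) for reuse.
.cohortCache <- new.env(parent = emptyenv())
devCohort <- function(seed = 1L, nTerms = 12L, nGenes = 30L, nCells = 40L,
                      nDrugs = 8L, nPairs = 150L, nBits = 64L) {
  key <- paste(seed, nTerms, nGenes, nCells, nDrugs, nPairs, nBits, sep = "-")
  if (!is.null(.cohortCache[[key]])) return(.cohortCache[[key]])
  sp <- simSpec(nTerms = nTerms, nGenes = nGenes, nCells = nCells,
                nDrugs = nDrugs, nPairs = nPairs, nBits = nBits,
                meanBitsOn = max(4, round(nBits * 81 / 2048)), seed = seed)
  dir <- file.path(tempdir(), paste0("fixture-", key))
  info <- simulateCohort(sp, dir)
  co <- readCohort(dir, nBits = nBits)
  out <- list(spec = sp, info = info, ontology = co$ontology,
              arch = co$arch, data = co$data, dir = dir)
  .cohortCache[[key]] <- out
  out
}

## Tiny training configuration for fast model tests.
fastConfig <- function(epochs = 15L, ...) {
  trainConfig(epochs = epochs, annSizes = c(16L, 8L, 4L), headHidden = 4L,
              batchSize = 64L, lr = 0.01, seed = 5L, ...)
}
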