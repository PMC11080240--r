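test_that("tab dialect parsing builds terms, edges and annotations", {
  f <- writeOntoFile(list(
    c("root", "A", "default"),
    c("root", "B", "default"),
    c("A", "g1", "gene")))
  o <- loadOntology(f)
  expect_setequal(ontoTerms(o), c("root", "A", "B"))
  expect_equal(nrow(ontoEdges(o)), 2L)
  expect_equal(ontoAnnotations(o), list(g1 = "A"))
  expect_equal(ontoRoot(o), "root")
})

test_that("degenerate inputs are rejected with informative errors", {
  cyc <- writeOntoFile(list(c("A", "B", "default"), c("B", "A", "default")))
  expect_error(loadOntology(cyc), "not a DAG")
  two <- writeOntoFile(list(c("r1", "A", "default"), c("r2", "A", "default"),
                            c("A", "g1", "gene")))
  expect_error(loadOntology(two), "exactly one root")
  badrow <- tempfile()
  writeLines(c("root\tA\tdefault", "brokenline"), badrow)
  expect_error(loadOntology(badrow), "line 2")
  badrel <- writeOntoFile(list(c("root", "A", "wat")))
  expect_error(loadOntology(badrel), "relation")
  expect_error(loadOntology(tempfile()), "does not exist")
})

test_that("diamond DAG yields 4 terms with depth 3 (exhaustive DFS oracle)", {
  o <- diamondOntology()
  expect_length(ontoTerms(o), 4L)
  arch <- layerArchitecture(o, neuronRule = list(fixed = 2))
  expect_equal(archDepth(arch), bruteDepth(o))
  expect_equal(archDepth(arch), 3L)
})

test_that("ontology round-trips through write and re-load", {
  o <- diamondOntology()
  f <- tempfile()
  writeOntology(o, f)
  o2 <- loadOntology(f)
  expect_equal(ontoTerms(o2), ontoTerms(o))
  expect_equal(ontoEdges(o2), ontoEdges(o))
  expect_equal(ontoAnnotations(o2), ontoAnnotations(o))
  ## a second write is byte-identical
  f2 <- tempfile()
  writeOntology(o2, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("minimal OBO input is read with separate annotations", {
  obo <- tempfile(fileext = ".obo")
  writeLines(c("format-version: 1.2", "", "[Term]", "id: GO:1", "",
               "[Term]", "id: GO:2", "is_a: GO:1 ! parent", "",
               "[Term]", "id: GO:3", "is_a: GO:1"), obo)
  ann <- tempfile()
  writeLines(c("GO:2\tgeneA", "GO:3\tgeneB"), ann)
  o <- loadOntology(obo, dialect = "obo", annotationPath = ann)
  expect_setequal(ontoTerms(o), c("GO:1", "GO:2", "GO:3"))
  expect_equal(ontoRoot(o), "GO:1")
  expect_error(loadOntology(obo, dialect = "obo"), "annotation")
})

test_that("pruning restricts annotations and drops uncovered subtrees", {
  o <- chainOntology()
  ## keep everything: identical ontology
  same <- pruneToGenes(o, c("g1", "g2", "g3"))
  expect_equal(ontoTerms(same), ontoTerms(o))
  expect_equal(ontoEdges(same), ontoEdges(o))
  expect_equal(ontoAnnotations(same), ontoAnnotations(o))
  ## only the deepest gene: all three terms still covered through B
  deep <- pruneToGenes(o, "g1")
  expect_setequal(ontoTerms(deep), c("root", "A", "B"))
  ## dropping the leaf gene removes the leaf term only
  noleaf <- pruneToGenes(o, c("g2", "g3"))
  expect_setequal(ontoTerms(noleaf), c("root", "A"))
  expect_error(pruneToGenes(o, "absent"), "no annotated genes")
  expect_error(pruneToGenes(o, character(0)), "nonempty")
})

test_that("pruning a multi-parent DAG matches the reachability oracle", {
  o <- diamondOntology()
  keep <- c("g1", "g3")        # genes on D and A; B and C stay covered via D
  p <- pruneToGenes(o, keep)
  survivors <- ontoTerms(p)
  oracle <- Filter(function(t) {
    length(intersect(bruteDescGenes(o, t), keep)) > 0
  }, ontoTerms(o))
  expect_setequal(survivors, oracle)
  ## surviving terms keep their original wiring (ancestors of survivors
  ## always survive under the union rule, so edges are preserved)
  e <- ontoEdges(o)
  keepEdge <- e$child %in% survivors & e$parent %in% survivors
  expect_equal(ontoEdges(p), e[keepEdge, , drop = FALSE],
               ignore_attr = TRUE)
  ## descendant-coverage invariant holds after pruning
  for (t in survivors) {
    expect_gt(length(bruteDescGenes(p, t)), 0)
  }
})

test_that("layer plan orders children before parents with fixed neurons", {
  o <- chainOntology()
  arch <- layerArchitecture(o, neuronRule = list(fixed = 2))
  expect_length(termOrder(arch), 3L)
  expect_true(all(termNeurons(arch) == 2L))
  expect_equal(archDepth(arch), 3L)
  d <- diamondOntology()
  archd <- layerArchitecture(d, neuronRule = list(fixed = 2))
  pos <- stats::setNames(seq_along(termOrder(archd)), termOrder(archd))
  expect_lt(pos["D"], min(pos["B"], pos["C"]))
  expect_lt(max(pos["B"], pos["C"]), pos["A"])
})

test_that("proportional neuron rule follows ceil(frac * descendant genes)", {
  rows <- list(c("root", "A", "default"))
  rows <- c(rows, lapply(sprintf("g%03d", 1:100), function(g) {
    c("A", g, "gene")
  }))
  rows <- c(rows, list(c("root", "g200", "gene")))
  o <- loadOntology(writeOntoFile(rows))
  arch <- layerArchitecture(o, neuronRule = list(proportional = c(20, 0.3)))
  expect_equal(unname(termNeurons(arch)[["A"]]), 30L)          # ceil(.3*100)
  expect_equal(unname(termNeurons(arch)[["root"]]), 31L)       # ceil(.3*101)
  small <- layerArchitecture(chainOntology(),
                             neuronRule = list(proportional = c(20, 0.3)))
  expect_true(all(termNeurons(small) == 20L))                  # floor at minK
})

test_that("compilation refuses ontologies with uncovered terms", {
  f <- writeOntoFile(list(c("root", "A", "default"),
                          c("root", "B", "default"),
                          c("A", "g1", "gene")))
  o <- loadOntology(f)
  expect_error(layerArchitecture(o), "descendant closure")
})

test_that("random DAGs: topological order and depth match brute oracles", {
  for (i in 1:150) {
    sp <- simSpec(nTerms = 4L + (i %% 7L), maxDepth = 2L + (i %% 4L),
                  nGenes = 20L, seed = 1000L + i)
    o <- makeToyOntology(sp)
    arch <- layerArchitecture(o, neuronRule = list(fixed = 1))
    expect_true(isValidTopo(termOrder(arch), o))
    expect_equal(archDepth(arch), bruteDepth(o))
  }
})

test_that("term input widths follow children plus direct genes", {
  o <- diamondOntology()
  arch <- layerArchitecture(o, neuronRule = list(fixed = 3))
  w <- termInputWidth(arch)
  ## D: no children, 1 gene; B: child D (3) + 1 gene; A: B+C (6) + 1 gene
  expect_equal(unname(w[c("D", "B", "A")]), c(1L, 4L, 7L))
  arch3 <- layerArchitecture(o, neuronRule = list(fixed = 3),
                             geneChannelWidth = 3L)
  expect_equal(unname(termInputWidth(arch3)[["D"]]), 3L)
})
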