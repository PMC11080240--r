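test_that("parameter count matches the closed-form block sum", {
  o <- chainOntology()
  arch <- layerArchitecture(o, neuronRule = list(fixed = 2))
  vnn <- buildVNN(arch, seed = 1)
  ## independent enumeration: k*w + k (bias) + 2k (BN affine) + (k+1) (head)
  w <- termInputWidth(arch)
  k <- termNeurons(arch)
  expected <- sum(k * w + k + 2 * k + (k + 1))
  expect_equal(parameterCount(vnn$params, "vnn"), expected)
  expect_equal(expected, 41L)   # 2 blocks of width 3, 1 of width 1, k = 2
})

test_that("initialization is seeded, bounded and degenerate at range 0", {
  o <- diamondOntology()
  arch <- layerArchitecture(o, neuronRule = list(fixed = 3))
  a <- buildVNN(arch, initRange = 0.01, seed = 42)
  b <- buildVNN(arch, initRange = 0.01, seed = 42)
  expect_identical(a, b)
  c <- buildVNN(arch, initRange = 0.01, seed = 43)
  expect_false(identical(a$params, c$params))
  for (t in termOrder(arch)) {
    W <- a$params[[paste0("W.", t)]]
    expect_true(all(abs(W) <= 0.01))
  }
  z <- buildVNN(arch, initRange = 0, seed = 1)
  expect_true(all(z$params[["W.A"]] == 0))
  expect_true(all(z$params[["b.A"]] == 0))
})

test_that("subsystem block computes BatchNorm(tanh(Wv + b))", {
  o <- chainOntology()
  arch <- layerArchitecture(o, neuronRule = list(fixed = 1))
  cfg <- trainConfig(annSizes = c(4L, 3L, 2L), headHidden = 2L, seed = 1)
  m <- newDrugVNN(arch, cfg, nBits = 16L)
  ## leaf B sees exactly its one annotated gene
  m@params[["W.B"]] <- matrix(0.5)
  m@params[["b.B"]] <- 0
  m@params[["g.B"]] <- 1; m@params[["be.B"]] <- 0
  blk <- getSubsystemBlock(m, "B")
  got <- subsystemForward(1, blk)
  expect_equal(got, tanh(0.5) / sqrt(1 + 1e-5), tolerance = 1e-12)
  expect_equal(got, 0.46212, tolerance = 1e-4)
  ## zero weights with identity BN give a zero activation
  m@params[["W.B"]][] <- 0
  expect_equal(subsystemForward(1, getSubsystemBlock(m, "B")), 0)
  expect_error(subsystemForward(c(1, 2), blk), "width")
})

test_that("single-term network reduces to one block plus head (hand oracle)", {
  f <- writeOntoFile(list(c("root", "g1", "gene"), c("root", "g2", "gene"),
                          c("root", "g3", "gene")))
  o <- loadOntology(f)
  arch <- layerArchitecture(o, neuronRule = list(fixed = 2))
  cfg <- trainConfig(annSizes = c(4L, 3L, 2L), headHidden = 2L, seed = 3)
  m <- newDrugVNN(arch, cfg, nBits = 8L)
  W <- matrix(c(0.2, -0.1, 0.4, 0, 0.3, 0.5), 2, 3)
  b <- c(0.05, -0.05)
  aW <- c(0.7, -0.2); ab <- 0.1
  m@params[["W.root"]] <- W; m@params[["b.root"]] <- b
  m@params[["g.root"]] <- c(1, 1); m@params[["be.root"]] <- c(0, 0)
  m@params[["aW.root"]] <- aW; m@params[["ab.root"]] <- ab
  x <- c(0.3, 0.9, 0.1)
  fw <- vnnForward(m, x, mode = "eval")
  expected <- tanh(drop(W %*% x) + b) / sqrt(1 + 1e-5)
  expect_equal(drop(fw$rootEmbedding), expected, tolerance = 1e-10)
  expect_equal(fw$auxPredictions[["root"]],
               sum(expected * aW) + ab, tolerance = 1e-10)
})

test_that("gene perturbations cannot reach terms outside their closure", {
  o <- chainOntology()   # genes: g1 on B (leaf), g2 on A, g3 on root
  arch <- layerArchitecture(o, neuronRule = list(fixed = 2))
  cfg <- trainConfig(annSizes = c(4L, 3L, 2L), headHidden = 2L, seed = 7)
  m <- newDrugVNN(arch, cfg, nBits = 8L)
  x <- matrix(runif(3), 1, dimnames = list(NULL, geneIndex(arch)))
  base <- vnnForward(m, x, mode = "eval")$states
  x2 <- x; x2[, "g3"] <- x2[, "g3"] + 0.5     # root-only gene
  pert <- vnnForward(m, x2, mode = "eval")$states
  expect_identical(pert[["B"]], base[["B"]])
  expect_identical(pert[["A"]], base[["A"]])
  expect_false(identical(pert[["root"]], base[["root"]]))
})

test_that("evaluation is invariant to the topological order used", {
  o <- diamondOntology()
  arch <- layerArchitecture(o, neuronRule = list(fixed = 2))
  expect_equal(termOrder(arch), c("D", "B", "C", "A"))
  cfg <- trainConfig(annSizes = c(4L, 3L, 2L), headHidden = 2L, seed = 11)
  m <- newDrugVNN(arch, cfg, nBits = 8L)
  x <- matrix(runif(8), 2, 4, dimnames = list(NULL, geneIndex(arch)))
  ref <- vnnForward(m, x, mode = "eval")
  arch2 <- arch
  arch2@termOrder <- c("D", "C", "B", "A")    # another valid order
  validObject(arch2)
  m2 <- m; m2@arch <- arch2
  alt <- vnnForward(m2, x, mode = "eval")
  for (t in ontoTerms(o)) {
    expect_equal(alt$states[[t]], ref$states[[t]], tolerance = 1e-12)
  }
})

test_that("batched forward returns one state row per sample everywhere", {
  co <- devCohort(seed = 2)
  cfg <- fastConfig()
  m <- newDrugVNN(co$arch, cfg, nBits = 64L)
  X <- co$data@cellX[1:7, , drop = FALSE]
  fw <- vnnForward(m, X, mode = "eval")
  for (t in termOrder(co$arch)) {
    expect_equal(nrow(fw$states[[t]]), 7L)
    expect_length(fw$auxPredictions[[t]], 7L)
  }
  expect_error(vnnForward(m, X[, -1, drop = FALSE]), "columns")
})
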