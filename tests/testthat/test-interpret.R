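test_that("rlipp follows (P2 - P1) / P1 with identical states scoring zero", {
  set.seed(21)
  S <- matrix(rnorm(60), 20, 3)
  y <- S[, 1] * 0.5 + rnorm(20, sd = 0.1)
  res <- rlippFromStates(S, list(c1 = S), y, heldOut = FALSE)
  expect_equal(res$P1, res$P2)
  expect_equal(res$rlipp, 0)
  expect_equal(res$rlipp, (res$P2 - res$P1) / res$P1)
  ## parent strictly better than an uninformative child
  noise <- matrix(rnorm(60), 20, 3)
  res2 <- rlippFromStates(S, list(c1 = noise), y, heldOut = FALSE,
                          sigLevel = 0)
  expect_gt(res2$P2, res2$P1)
  expect_gt(res2$rlipp, 0)
})

test_that("degenerate rlipp inputs are flagged, not infinite", {
  set.seed(22)
  y <- rnorm(20)
  flat <- matrix(0, 20, 2)
  res <- rlippFromStates(matrix(rnorm(40), 20), list(c1 = flat), y,
                         heldOut = FALSE, sigLevel = 0)
  expect_true(res$undefined)
  expect_true(is.na(res$rlipp))
  expect_error(rlippFromStates(flat, list(), y), "no children")
  expect_error(rlippFromStates(flat[1:2, ], list(c1 = flat[1:2, ]),
                               y[1:2]), "3 samples")
})

test_that("antisymmetry: swapping parent and child roles negates the gap", {
  set.seed(23)
  P <- matrix(rnorm(90), 30, 3)
  C <- matrix(rnorm(90), 30, 3)
  y <- P[, 1] + C[, 1] + rnorm(30, sd = 0.2)
  a <- rlippFromStates(P, list(c = C), y, heldOut = FALSE, sigLevel = 0)
  b <- rlippFromStates(C, list(c = P), y, heldOut = FALSE, sigLevel = 0)
  expect_equal(a$P1, b$P2)
  expect_equal(a$P2, b$P1)
  expect_equal(a$rlipp * a$P1, -(b$rlipp * b$P1), tolerance = 1e-12)
})

test_that("rlippScore demands children and known terms", {
  co <- devCohort(seed = 8)
  cfg <- fastConfig(epochs = 5L)
  m <- trainDrugVNN(co$data, co$arch, cfg)
  leaf <- termOrder(co$arch)[1]
  expect_error(rlippScore(m, co$data, leaf), "no children")
  expect_error(rlippScore(m, co$data, "NOPE"), "unknown term")
  expect_error(rlippScore(m, co$data, ontoRoot(co$ontology),
                          drugFilter = "NOPE"), "unknown drug")
  root <- ontoRoot(co$ontology)
  row <- rlippScore(m, co$data, root, sigLevel = 0)
  expect_equal(row$term, root)
  expect_equal(row$n_children,
               length(co$arch@termChildren[[root]]))
})

test_that("ranking is dense, tie-broken lexicographically, top-flagged", {
  res <- data.frame(term = sprintf("T%02d", 1:20),
                    rlipp = rep(0.5, 20))
  rk <- rankSubsystems(res, topFraction = 0.10)
  expect_equal(rk$rank, 1:20)
  expect_equal(sum(rk$top), 2L)                 # ceiling(0.1 * 20)
  expect_equal(rk$term, sort(res$term))         # all-equal: lexicographic
  set.seed(24)
  res2 <- data.frame(term = sprintf("T%02d", 1:15), rlipp = rnorm(15))
  res2$rlipp[c(4, 9)] <- NA                     # undefined scores sink
  rk2 <- rankSubsystems(res2, topFraction = 0.2)
  oracle <- res2[order(-res2$rlipp, res2$term, na.last = TRUE), "term"]
  expect_equal(rk2$term, oracle)
  expect_equal(rk2$term[rk2$top], oracle[1:3])
  expect_error(rankSubsystems(res2[0, ]), "no scored")
})

test_that("2-D embedding captures collinear points in one component", {
  t <- seq(0, 1, length.out = 10)
  line <- cbind(1 + 2 * t, 3 - t)
  emb <- embedEntities(line)
  expect_equal(emb$varExplained[1], 1)
  expect_equal(unname(emb$varExplained[2]), 0, tolerance = 1e-12)
})

test_that("rotations change scores but not explained variance", {
  set.seed(25)
  X <- matrix(rnorm(40), 20, 2) %*% diag(c(3, 1))
  th <- 0.7
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  e1 <- embedEntities(X)
  e2 <- embedEntities(X %*% R)
  expect_equal(e2$varExplained, e1$varExplained, tolerance = 1e-10)
  ## scores agree up to the rotation (signs already fixed by the rule)
  expect_equal(abs(stats::cor(e1$coordinates[, 1], e2$coordinates[, 1])), 1,
               tolerance = 1e-8)
})

test_that("square of points splits variance evenly with fixed signs", {
  sq <- rbind(c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  emb <- embedEntities(sq)
  expect_equal(emb$varExplained, c(0.5, 0.5), ignore_attr = TRUE)
  for (j in 1:2) {
    i <- which.max(abs(emb$rotation[, j]))
    expect_gte(emb$rotation[i, j], 0)
  }
  expect_error(embedEntities(matrix(0, 5, 3)), "rank-0")
  expect_error(embedEntities(sq[1:2, ]), "3 entities")
})

test_that("reconstruction error never increases with more components", {
  set.seed(26)
  X <- matrix(rnorm(50), 10, 5)
  errs <- vapply(1:4, function(k) {
    e <- embedEntities(X, nComponents = k)
    ctr <- colMeans(X)
    Xhat <- e$coordinates %*% t(e$rotation)
    Xhat <- sweep(Xhat, 2, ctr, "+")
    sum((X - Xhat)^2)
  }, 0)
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("cell and drug embeddings cover every entity", {
  co <- devCohort(seed = 8)
  cfg <- fastConfig(epochs = 5L)
  m <- trainDrugVNN(co$data, co$arch, cfg)
  ce <- cellEmbeddings(m, co$data)
  expect_equal(nrow(ce$coordinates), length(co$data@cellIds))
  de <- drugEmbeddings(m, co$data)
  expect_equal(nrow(de$coordinates), length(co$data@drugIds))
  expect_equal(ce$ids, co$data@cellIds)
})

test_that("state export mirrors the forward pass and re-scores identically", {
  co <- devCohort(seed = 8)
  cfg <- fastConfig(epochs = 5L)
  m <- trainDrugVNN(co$data, co$arch, cfg)
  root <- ontoRoot(co$ontology)
  kids <- co$arch@termChildren[[root]]
  tab <- subsystemStateExport(m, co$data, c(root, kids))
  expect_equal(nrow(tab), length(co$data@cellIds))
  fw <- vnnForward(m, co$data@cellX)
  k <- termNeurons(co$arch)[[root]]
  expect_equal(as.matrix(tab[, sprintf("%s.n%d", root, 1:k)]),
               fw$states[[root]], ignore_attr = TRUE)
  expect_equal(tab[[paste0(root, ".aux")]], fw$auxPredictions[[root]],
               ignore_attr = TRUE)
  expect_error(subsystemStateExport(m, co$data, "NOPE"), "unknown term")
  ## round trip through TSV and recompute rlipp from reloaded states
  f <- tempfile(fileext = ".tsv")
  subsystemStateExport(m, co$data, c(root, kids), path = f)
  back <- utils::read.table(f, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE)
  sel <- match(co$data@triples$cell_id, back$cell_id)
  y <- co$data@triples$auc
  pS <- as.matrix(back[sel, sprintf("%s.n%d", root, 1:k)])
  cS <- lapply(kids, function(c) {
    as.matrix(back[sel, sprintf("%s.n%d", c, seq_len(termNeurons(co$arch)[[c]]))])
  })
  names(cS) <- kids
  reloaded <- rlippFromStates(pS, cS, y, sigLevel = 0,
                              groups = co$data@triples$cell_id)
  direct <- rlippScore(m, co$data, root, sigLevel = 0)
  expect_equal(reloaded$P1, direct$P1, tolerance = 1e-8)
  expect_equal(reloaded$P2, direct$P2, tolerance = 1e-8)
  expect_equal(reloaded$rlipp, direct$rlipp, tolerance = 1e-6)
})
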