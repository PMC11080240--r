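test_that("fusion head reduces to its bias for zero embeddings and weights", {
  co <- devCohort(seed = 3)
  cfg <- fastConfig()
  m <- newDrugVNN(co$arch, cfg, nBits = 64L)
  m@params$hW[] <- 0; m@params$hb[] <- 0
  m@params$oW[] <- 0; m@params$ob <- 0.42
  kroot <- termNeurons(co$arch)[[co$arch@root]]
  pred <- combineEmbeddings(m, rep(0, kroot), rep(0, 4))
  expect_equal(pred, 0.42)
})

test_that("fusion head with fixed weights matches manual arithmetic", {
  f <- writeOntoFile(list(c("root", "g1", "gene")))
  o <- loadOntology(f)
  arch <- layerArchitecture(o, neuronRule = list(fixed = 2))
  cfg <- trainConfig(annSizes = c(3L, 3L, 2L), headHidden = 2L, seed = 2)
  m <- newDrugVNN(arch, cfg, nBits = 4L)
  hW <- matrix(c(0.3, -0.2, 0.1, 0.4, -0.5, 0.2, 0, 0.6), 2, 4)
  hb <- c(0.1, -0.1); oW <- c(0.8, -0.3); ob <- 0.05
  m@params$hW <- hW; m@params$hb <- hb
  m@params$hg <- c(1, 1); m@params$hbe <- c(0, 0)
  m@params$oW <- oW; m@params$ob <- ob
  rootEmb <- c(0.5, -0.2); drugEmb <- c(0.3, 0.1)
  x <- c(rootEmb, drugEmb)
  hidden <- tanh(drop(hW %*% x) + hb) / sqrt(1 + 1e-5)
  expect_equal(combineEmbeddings(m, rootEmb, drugEmb),
               sum(hidden * oW) + ob, tolerance = 1e-12)
})

test_that("objective reduces to MSE and adds weighted aux and L2 terms", {
  expect_equal(objectiveLoss(0.5, 0.7), 0.04)
  expect_equal(objectiveLoss(c(1, 0), c(0, 1)), 1)
  ## alpha = 1, two aux terms with MSE 0.01 and 0.03, main 0.04
  got <- objectiveLoss(0.5, 0.7,
                       aux = list(t1 = 0.6, t2 = 0.7 - sqrt(0.03)),
                       alpha = 1)
  expect_equal(got, 0.04 + 0.01 + 0.03)
  ## lambda sums squared weights
  W <- list(matrix(c(1, 2), 1))
  expect_equal(objectiveLoss(0, 0, alpha = 0, lambda = 0.1, weights = W), 0.5)
  expect_error(objectiveLoss(NaN, 0), "non-finite")
  expect_error(objectiveLoss(0.5, 0.5, aux = list(bad = NaN), alpha = 1),
               "term bad")
})

test_that("objective with alpha = lambda = 0 equals the evaluation MSE", {
  co <- devCohort(seed = 3)
  cfg <- fastConfig()
  m <- trainDrugVNN(co$data, co$arch, cfg)
  pr <- predict(m, co$data)
  y <- co$data@triples$auc
  expect_equal(objectiveLoss(pr$predicted_auc, y),
               unname(evaluatePredictions(pr$predicted_auc, y, "mse")))
})

test_that("training reduces the loss on a small planted cohort", {
  co <- devCohort(seed = 4)
  cfg <- fastConfig(epochs = 20L)
  m <- trainDrugVNN(co$data, co$arch, cfg)
  h <- m@history
  expect_equal(nrow(h), 20L)
  expect_lt(mean(h$trainLoss[16:20]), mean(h$trainLoss[1:5]))
  expect_true(all(is.finite(h$trainLoss)))
})

test_that("identical seeds give bit-identical training runs", {
  co <- devCohort(seed = 5)
  cfg <- fastConfig(epochs = 8L)
  m1 <- trainDrugVNN(co$data, co$arch, cfg)
  m2 <- trainDrugVNN(co$data, co$arch, cfg)
  expect_identical(m1@history, m2@history)
  expect_identical(m1@params, m2@params)
  cfg2 <- fastConfig(epochs = 8L); cfg2$seed <- 99L
  m3 <- trainDrugVNN(co$data, co$arch, cfg2)
  expect_false(identical(m1@params, m3@params))
})

test_that("learning-rate grid is enforced only under strictGrid", {
  expect_error(trainConfig(lr = 0.5, strictGrid = TRUE), "grid")
  expect_silent(trainConfig(lr = 0.5))
  expect_error(trainConfig(alpha = -1), "alpha")
  expect_error(trainConfig(lambda = -1), "lambda")
})

test_that("prediction is order-equivariant and consistent for duplicates", {
  co <- devCohort(seed = 5)
  cfg <- fastConfig(epochs = 8L)
  m <- trainDrugVNN(co$data, co$arch, cfg)
  pairs <- co$data@triples[1:10, c("cell_id", "drug_id")]
  p1 <- predict(m, co$data, pairs = pairs)
  perm <- sample(10)
  p2 <- predict(m, co$data, pairs = pairs[perm, ])
  expect_equal(p2$predicted_auc, p1$predicted_auc[perm], tolerance = 1e-12)
  dup <- predict(m, co$data, pairs = pairs[c(1, 1), ])
  expect_lt(abs(dup$predicted_auc[1] - dup$predicted_auc[2]), 1e-7)
  bad <- data.frame(cell_id = "nope", drug_id = pairs$drug_id[1])
  expect_error(predict(m, co$data, pairs = bad), "nope")
})

test_that("metric definitions are standard", {
  expect_equal(
    evaluatePredictions(c(0.1, 0.5, 0.9), c(0.1, 0.5, 0.9)),
    c(pearson = 1, mse = 0, mae = 0, rmse = 0, r2 = 1))
  expect_equal(unname(evaluatePredictions(c(0, 1), c(1, 0), "pearson")), -1)
  expect_equal(unname(evaluatePredictions(0.5, 0.7, "mse")), 0.04)
  expect_error(evaluatePredictions(1, 1, "pearson"), "2 samples")
})

test_that("fold assignment is seeded, disjoint and covering", {
  f <- foldAssignment(100, 10, seed = 3)
  expect_equal(sort(unique(f)), 1:10)
  expect_true(all(table(f) == 10))
  expect_identical(f, foldAssignment(100, 10, seed = 3))
  expect_false(identical(f, foldAssignment(100, 10, seed = 4)))
  expect_error(foldAssignment(10, 1), ">= 2")
  expect_error(foldAssignment(5, 6), "exceeds")
})

test_that("lambda tuning returns the grid argmin of validation MSE", {
  ## purely genotype-driven response: the subsystem weights must carry the
  ## signal, so collapsing them with a huge L2 factor must lose on
  ## validation MSE and the near-zero penalty wins
  co <- devCohort(seed = 6)
  dat <- co$data
  pg <- match(co$info$plantedGenes, geneIndex(dat))
  ci <- match(dat@triples$cell_id, dat@cellIds)
  dat@triples$auc <- round(pmin(1, pmax(0,
    rowMeans(dat@cellX[ci, pg, drop = FALSE]) * 1.5 + 0.2)), 6)
  cfg <- fastConfig(epochs = 25L)
  tl <- tuneLambda(dat, co$arch, cfg, grid = c(1e-6, 25), k = 3L)
  expect_equal(tl$best, 1e-6)
  expect_equal(tl$table$lambda, c(1e-6, 25))
  expect_true(all(is.finite(tl$table$mse)))
  expect_lt(tl$table$mse[1], tl$table$mse[2])
})

test_that("analytic gradients match finite differences of the objective", {
  sp <- simSpec(nTerms = 5, nGenes = 8, nCells = 6, nDrugs = 3, nPairs = 10,
                nBits = 16, seed = 31)
  o <- makeToyOntology(sp)
  arch <- layerArchitecture(o, neuronRule = list(fixed = 2))
  cfg <- trainConfig(annSizes = c(5L, 4L, 3L), headHidden = 3L, seed = 9,
                     alpha = 0.4, lambda = 1e-3)
  m <- newDrugVNN(arch, cfg, nBits = 16L)
  set.seed(13)
  cellX <- matrix(runif(6 * length(geneIndex(arch))), 6)
  fpX <- matrix(rbinom(3 * 16, 1, 0.3), 3)
  pc <- sample(6, 10, TRUE); pd <- sample(3, 10, TRUE); y <- runif(10)
  params <- m@params; buffers <- m@buffers
  lossOf <- function(p) {
    fw <- DrugVNN:::.forwardFull(p, buffers, arch, pc, pd, cellX, fpX,
                                 3L, "train")
    aux <- lapply(fw$vnn$aux, function(a) a[pc])
    aux <- aux[setdiff(termOrder(arch), ontoRoot(o))]
    objectiveLoss(fw$pred, y, aux, cfg$alpha, cfg$lambda,
                  DrugVNN:::.vnnWeightList(p, arch))
  }
  fw <- DrugVNN:::.forwardFull(params, buffers, arch, pc, pd, cellX, fpX,
                               3L, "train", withCache = TRUE)
  g <- DrugVNN:::.backwardFull(params, arch, fw, pc, pd, 6L, 3L, y,
                               cfg$alpha, cfg$lambda)
  h <- 1e-5
  set.seed(17)
  for (nm in sample(names(g), 12)) {
    i <- sample(length(params[[nm]]), 1)
    pp <- params; pp[[nm]][i] <- pp[[nm]][i] + h
    pm <- params; pm[[nm]][i] <- pm[[nm]][i] - h
    fd <- (lossOf(pp) - lossOf(pm)) / (2 * h)
    expect_equal(g[[nm]][i], fd, tolerance = 1e-4)
  }
})

test_that("checkpoints round-trip and reject tampered ontology hashes", {
  co <- devCohort(seed = 5)
  cfg <- fastConfig(epochs = 5L)
  m <- trainDrugVNN(co$data, co$arch, cfg)
  f <- tempfile(fileext = ".rds")
  saveCheckpoint(m, f)
  m2 <- loadCheckpoint(f)
  expect_identical(m2@params, m@params)
  expect_equal(predict(m2, co$data)$predicted_auc,
               predict(m, co$data)$predicted_auc, tolerance = 1e-12)
  bad <- m; bad@hash <- "0"
  f2 <- tempfile(fileext = ".rds")
  saveRDS(bad, f2)
  expect_error(loadCheckpoint(f2), "hash")
  f3 <- tempfile(fileext = ".rds")
  saveRDS(list(), f3)
  expect_error(loadCheckpoint(f3), "not a model")
})

test_that("two-stage training runs both phases and remains seeded", {
  co <- devCohort(seed = 6)
  cfg <- fastConfig(epochs = 8L, twoStage = TRUE)
  m <- trainDrugVNN(co$data, co$arch, cfg)
  expect_setequal(unique(m@history$stage), c("branches", "head"))
  m2 <- trainDrugVNN(co$data, co$arch, cfg)
  expect_identical(m@history, m2@history)
})

test_that("ridge baseline hook fits and reports standard metrics", {
  co <- devCohort(seed = 6)
  bl <- fitLinearBaseline(co$data, seed = 2)
  expect_named(bl$metrics, c("pearson", "mse", "mae", "rmse", "r2"))
  expect_true(all(is.finite(bl$metrics)))
  expect_equal(bl$nTrain + bl$nTest, nrow(co$data@triples))
})

test_that("cross-validation covers the dataset with per-fold metrics", {
  co <- devCohort(seed = 7, nPairs = 90L)
  cfg <- fastConfig(epochs = 5L)
  cv <- crossValidate(co$data, co$arch, cfg, k = 3L)
  expect_equal(nrow(cv$perFold), 3L)
  expect_true(all(is.finite(cv$perFold$mse)))
  expect_named(cv$mean, c("pearson", "mse", "mae", "rmse", "r2"))
})
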