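test_that("gate fusion is a convex combination that saturates correctly", {
  set.seed(1)
  cl <- tinyNormalizedCloud(40)
  cfg <- tinyConfig()
  params <- pps$ggeStageParams(3L, 4L, cfg, seed = 1)
  out <- ggeForward(cl, coords(cl), params, cfg)
  expect_equal(dim(out$fused), c(40L, 4L))
  lo <- pmin(out$euclidean, out$hyperbolic)
  hi <- pmax(out$euclidean, out$hyperbolic)
  expect_true(all(out$fused >= lo - 1e-9 & out$fused <= hi + 1e-9))

  pOpen <- params; pOpen$gateb <- rep(50, 4)    # g -> 1: Euclidean channel
  outE <- ggeForward(cl, coords(cl), pOpen, cfg)
  expect_equal(outE$fused, outE$euclidean, tolerance = 1e-12)
  pShut <- params; pShut$gateb <- rep(-50, 4)   # g -> 0: hyperbolic channel
  outH <- ggeForward(cl, coords(cl), pShut, cfg)
  expect_equal(outH$fused, outH$hyperbolic, tolerance = 1e-12)
})

test_that("GGE-P coarsens by the pooling rate and clips K on tiny stages", {
  cl <- tinyNormalizedCloud(256)
  cfg <- tinyConfig()
  params <- pps$ggeStageParams(3L, 4L, cfg, seed = 2)
  out <- ggePForward(cl, coords(cl), params, cfg, seed = 0)
  expect_equal(npoints(out$cloud), 64L)
  expect_equal(dim(out$features), c(64L, 4L))
  # rate = N collapses to a single point
  cfgN <- tinyConfig(poolingRate = 256L)
  single <- ggePForward(cl, coords(cl), params, cfgN, seed = 0)
  expect_equal(npoints(single$cloud), 1L)
  # K clipped with a warning when the stage is smaller than K
  small <- tinyNormalizedCloud(6)
  cfgBig <- tinyConfig(K = 10L)
  expect_warning(ggePForward(small, coords(small), params, cfgBig, seed = 0),
                 "clipped")
})

test_that("the full forward produces the stage cascade and N x p scores", {
  cl <- tinyNormalizedCloud(256, seed = 3)
  cfg <- tinyConfig()
  params <- segNetInit(cfg, seed = 1)
  out <- segNetForward(cl, params, cfg, seed = 0)
  expect_equal(dim(out$scores), c(256L, 2L))
  expect_equal(out$stageSizes, c(256L, 256L, 64L, 16L, 4L))
  expect_equal(ncol(out$embedding), sum(cfg$stageDims))
  # deterministic given fixed weights and seed
  out2 <- segNetForward(cl, params, cfg, seed = 0)
  expect_identical(out$scores, out2$scores)
})

test_that("scores are equivariant to permutations of the input points", {
  cl <- tinyNormalizedCloud(200, seed = 4)
  cfg <- tinyConfig()
  params <- segNetInit(cfg, seed = 5)
  base <- segNetForward(cl, params, cfg, seed = 0)$scores
  set.seed(6)
  perm <- sample(200)
  clP <- cl[perm]
  permScores <- segNetForward(clP, params, cfg, seed = 0)$scores
  expect_equal(permScores, base[perm, ], tolerance = 1e-8)
})

test_that("loss components match their closed forms and mix correctly", {
  # perfect one-hot prediction -> ~0; uniform over 2 classes -> ln 2
  hard <- cbind(c(30, -30, 30), c(-30, 30, -30))
  expect_lt(crossEntropyLoss(hard, c(0L, 1L, 0L)), 1e-10)
  expect_equal(crossEntropyLoss(matrix(0, 4, 2), c(0L, 1L, 0L, 1L)), log(2))
  # 5 x 3 random instance vs naive loop
  set.seed(8)
  sc <- matrix(rnorm(15), 5, 3)
  lab <- sample(0:2, 5, replace = TRUE)
  loop <- 0
  for (i in 1:5) {
    p <- exp(sc[i, ]) / sum(exp(sc[i, ]))
    loop <- loop - log(p[lab[i] + 1])
  }
  expect_equal(crossEntropyLoss(sc, lab), loop / 5, tolerance = 1e-9)

  # triplet margin arithmetic on hand-set embeddings (both class-0 points
  # coincide, so every sampled triplet evaluates identically)
  lab3 <- c(0L, 0L, 1L)
  cfgT <- lossConfig(0.9, 0.1, margin = 0.2, tripletsPerBatch = 64L)
  emb <- rbind(c(0, 0), c(0, 0), c(3, 0))     # d+ = 0, d- = 9: satisfied
  expect_equal(tripletLoss(emb, lab3, cfgT, seed = 1), 0)
  embEq <- rbind(c(0, 0), c(0, 0), c(0, 0))   # d+ = d-: exactly the margin
  expect_equal(tripletLoss(embEq, lab3, cfgT, seed = 1), 0.2)
  expect_warning(single <- tripletLoss(emb, c(0L, 0L, 0L), cfgT, seed = 1),
                 "single-class")
  expect_equal(single, 0)
  # hand-evaluated active hinge: d+ = 0, d- = 0.09 -> 0.2 - 0.09
  embBad <- rbind(c(0, 0), c(0, 0), c(0.3, 0))
  expect_equal(tripletLoss(embBad, lab3, cfgT, seed = 1), 0.11,
               tolerance = 1e-12)

  # combined loss mixing
  expect_error(lossConfig(0.5, 0.4), "must equal 1")
  sc2 <- matrix(rnorm(6), 3, 2)
  ce <- crossEntropyLoss(sc2, lab3 %% 2)
  tr <- tripletLoss(embBad, lab3, lossConfig(0.5, 0.5), seed = 2)
  expect_equal(combinedLoss(sc2, embBad, lab3 %% 2, lossConfig(1, 0), seed = 2), ce)
  both <- combinedLoss(sc2, embBad, lab3 %% 2, lossConfig(0.5, 0.5), seed = 2)
  expect_equal(both, 0.5 * ce + 0.5 * tr, tolerance = 1e-12)
  expect_true(both >= min(ce, tr) && both <= max(ce, tr))
})

test_that("the cosine schedule hits its endpoints", {
  opt <- optConfig(epochs = 200L)
  expect_equal(cosineLr(0, opt), 0.1)
  expect_equal(cosineLr(199, opt), 0.001)
  mid <- cosineLr(100, opt)
  expect_true(mid < 0.1 && mid > 0.001)
})

test_that("training reduces the loss and respects early-stopping contracts", {
  set.seed(12)
  mkPlant <- function(s) {
    pl <- generatePlant(syntheticPlantSpec(seed = s, pointsTotal = 128L,
                                           nLeaves = 3L))
    normalizePoints(pl$cloud)$cloud
  }
  train <- lapply(1:4, mkPlant)
  cfg <- tinyConfig(K = 6L)
  opt <- optConfig(epochs = 6L, batchSize = 2L, lrMax = 0.05, lrMin = 0.01,
                   patience = 10L, seed = 1L)
  model <- suppressWarnings(trainModel(train, cfg = cfg, opt = opt))
  h <- model$history
  expect_equal(nrow(h), 6L)
  expect_lt(min(h$trainLoss), h$trainLoss[1])
  expect_true(all(is.finite(h$trainLoss)))

  # patience on a stagnant monitor stops after `patience` epochs (pure CE
  # loss so the monitor is exactly constant under frozen weights)
  optP <- optConfig(epochs = 30L, batchSize = 2L, lrMax = 1e-12, lrMin = 1e-13,
                    patience = 3L, seed = 1L)
  frozen <- suppressWarnings(trainModel(train, cfg = cfg,
                                        loss = lossConfig(1, 0), opt = optP))
  expect_lte(frozen$epochsRun, 5L)

  # prediction fills labels in {0, 1} deterministically, coordinates intact
  pred <- predictLabels(train[[1]], model, seed = 0)
  expect_true(all(semanticLabels(pred) %in% 0:1))
  expect_identical(coords(pred), coords(train[[1]]))
  pred2 <- predictLabels(train[[1]], model, seed = 0)
  expect_identical(semanticLabels(pred), semanticLabels(pred2))

  # checkpoints round-trip
  f <- withr::local_tempfile(fileext = ".rds")
  saveModel(model, f)
  back <- loadModel(f)
  expect_equal(back$params, model$params)
  expect_error(trainModel(list(), cfg = cfg), "empty")
  expect_error(trainModel(list(pointCloud(diag(3)))), "labelled, normalized")
})
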