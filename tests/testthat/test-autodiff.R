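# finite-difference validation of the hand-written backward passes

fdCheck <- function(fn, x, tol = 1e-6) {
  wrapped <- pps$adLeaf(x)
  pps$adTapeStart()
  loss <- fn(wrapped)
  pps$adBackward(loss)
  pps$adTapeStop()
  ana <- wrapped$grad
  num <- pps$numericGradient(function(xx) pps$adVal(fn(xx)), x)
  expect_equal(ana, num, tolerance = tol)
}

test_that("fused op gradients match finite differences", {
  set.seed(1)
  W <- matrix(rnorm(12), 4, 3)
  fdCheck(function(x) pps$adCrossEntropy(pps$adMatmul(x, W), c(0L, 2L, 1L)),
          matrix(rnorm(12), 3, 4))
  fdCheck(function(x) pps$adCrossEntropy(
    pps$adLinear(x, W, c(0.1, -0.2, 0.3)), c(1L, 0L)),
    matrix(rnorm(8), 2, 4))
  fdCheck(function(x) pps$adCrossEntropy(pps$adLeakyRelu(x, 0.2), c(0L, 1L)),
          matrix(rnorm(6), 2, 3))
  fdCheck(function(x) pps$adCrossEntropy(
    pps$adLayerNorm(x, c(1.2, 0.8, 1), c(0, 0.1, -0.1)), c(2L, 0L)),
    matrix(rnorm(6), 2, 3))
  fdCheck(function(x) pps$adCrossEntropy(pps$adExpmap0(x, 1.3), c(0L, 1L)),
          matrix(rnorm(6, sd = 0.5), 2, 3))
  fdCheck(function(x) pps$adCrossEntropy(
    pps$adLogmap0(pps$adBallProject(x, 2), 2), c(1L, 0L)),
    matrix(rnorm(6, sd = 2), 2, 3), tol = 1e-5)
  fdCheck(function(x) pps$adCrossEntropy(pps$adSigmoid(x), c(0L, 1L)),
          matrix(rnorm(6), 2, 3))
  # softmax pooling over K = 3 neighbours
  fdCheck(function(x) pps$adCrossEntropy(pps$adSoftmaxPool(x, 3L), c(1L, 0L)),
          matrix(rnorm(12), 6, 2))
  # kernel responses against a fixed spatial encoding
  dx <- matrix(rnorm(18), 3, 6)
  fdCheck(function(x) pps$adCrossEntropy(
    pps$adKernelResponse(dx, x, 2L, 0.2), c(0L, 1L, 1L)),
    matrix(rnorm(36), 3, 12))
  # gather / scatter and max pooling
  fdCheck(function(x) pps$adCrossEntropy(
    pps$adGatherRows(x, c(2L, 1L, 2L)), c(0L, 1L, 0L)),
    matrix(rnorm(4), 2, 2))
  idxMat <- rbind(c(1L, 2L, 0L), c(3L, 4L, 2L))
  fdCheck(function(x) pps$adCrossEntropy(
    pps$adMaxPoolGroup(x, idxMat), c(0L, 1L)),
    matrix(rnorm(8), 4, 2))
})

test_that("attention gradients match finite differences for all arguments", {
  set.seed(2)
  B <- 3; T <- 4; M <- 4; H <- 2
  Q0 <- matrix(rnorm(B * M), B, M)
  K0 <- matrix(rnorm(B * T * M), B * T, M)
  V0 <- matrix(rnorm(B * T * M), B * T, M)
  lab <- c(0L, 1L, 1L)
  fdCheck(function(x) pps$adCrossEntropy(
    pps$adAttention(x, K0, V0, T, H), lab), Q0)
  fdCheck(function(x) pps$adCrossEntropy(
    pps$adAttention(Q0, x, V0, T, H), lab), K0)
  fdCheck(function(x) pps$adCrossEntropy(
    pps$adAttention(Q0, K0, x, T, H), lab), V0)
})

test_that("triplet hinge gradients match finite differences", {
  set.seed(3)
  emb <- matrix(rnorm(12), 6, 2)
  fdCheck(function(x) pps$adTripletHinge(x, c(1L, 3L), c(2L, 4L), c(5L, 6L),
                                         0.5), emb)
})

test_that("the full network gradient matches finite differences", {
  set.seed(42)
  N <- 24
  cl <- pointCloud(matrix(runif(N * 3, -1, 1), N, 3),
                   semanticLabels = sample(0:1, N, replace = TRUE),
                   normalized = TRUE)
  cfg <- tinyConfig()
  prep <- suppressWarnings(pps$prepareCloud(cl, cfg, 0))
  params <- segNetInit(cfg, seed = 3)
  lc <- lossConfig(0.8, 0.2, tripletsPerBatch = 16L)
  lossOf <- function(P) {
    out <- pps$segNetForwardCore(prep, P, cfg, seed = 7)
    pps$adVal(combinedLoss(out$scores, out$embedding, prep$labels, lc, seed = 5))
  }
  wrapped <- pps$paramsWrap(params)
  pps$adTapeStart()
  out <- pps$segNetForwardCore(prep, wrapped, cfg, seed = 7)
  loss <- combinedLoss(out$scores, out$embedding, prep$labels, lc, seed = 5)
  pps$adBackward(loss)
  pps$adTapeStop()
  grads <- pps$paramsGradTree(wrapped)
  getL <- function(tree, path) { for (k in path) tree <- tree[[k]]; tree }
  setL <- function(tree, path, val) {
    if (length(path) == 1) { tree[[path[[1]]]] <- val; return(tree) }
    tree[[path[[1]]]] <- setL(tree[[path[[1]]]], path[-1], val)
    tree
  }
  paths <- list(
    list("stages", 1L, "euc", "kW1"),
    list("stages", 2L, "hyp", "inW"),
    list("stages", 3L, "hyp", "layers", 1L, "ring", "Wq"),
    list("stages", 4L, "hyp", "layers", 1L, "planet", "Wo"),
    list("stages", 5L, "gateW"),
    list("head", "W2")
  )
  for (pth in paths) {
    ana <- getL(grads, pth)
    x0 <- getL(params, pth)
    sub <- sample(length(x0), min(4, length(x0)))
    fd <- vapply(sub, function(i) {
      eps <- 1e-5
      xp <- x0; xp[i] <- xp[i] + eps
      xm <- x0; xm[i] <- xm[i] - eps
      (lossOf(setL(params, pth, xp)) - lossOf(setL(params, pth, xm))) / (2 * eps)
    }, numeric(1))
    expect_equal(ana[sub], fd, tolerance = 1e-3,
                 info = paste(unlist(pth), collapse = "."))
  }
})
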