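#' Architecture configuration of the segmentation network
#'
#' Two full-resolution geometric graph encoder (GGE) stages followed by three
#' GGE-P stages (GGE + farthest-point-sampling graph pooling), a decoder that
#' interpolates all five stage outputs back to full resolution, and a shared
#' per-point MLP head.
#'
#' @param numClasses number of semantic classes `p` (2 for stem/leaf).
#' @param K neighbourhood size of the kd-tree KNN graphs (default 20).
#' @param stageDims feature widths of the five stages.
#' @param poolingRate farthest-point sampling rate of the GGE-P stages.
#' @param hgsLayers,hgsHeads star-transformer depth and head count of the
#'   hyperbolic channel.
#' @param lambda residual scale of the hyperbolic channel.
#' @param curvature positive `c` parameterizing the Poincaré ball of
#'   curvature `-c` (fixed, not learned).
#' @param edgeProb ring-edge inclusion probability of the star graphs
#'   (1 = deterministic full ring).
#' @param headDims hidden widths of the segmentation head (then `numClasses`).
#' @param leakySlope LeakyReLU negative slope used throughout.
#' @return a `GGEConfig` list.
#' @export
ggeConfig <- function(numClasses = 2L, K = 20L,
                      stageDims = c(32L, 32L, 64L, 128L, 256L),
                      poolingRate = 4L, hgsLayers = 2L, hgsHeads = 4L,
                      lambda = 1, curvature = 1, edgeProb = 1,
                      headDims = c(512L, 256L), leakySlope = 0.2) {
  stopIfNot(length(stageDims) == 5L, "the architecture has 2 GGE + 3 GGE-P stages")
  stopIfNot(poolingRate >= 2L, "poolingRate must be at least 2")
  stopIfNot(numClasses >= 2L, "numClasses must be at least 2")
  stopIfNot(all(stageDims %% hgsHeads == 0L), "hgsHeads must divide every stage width")
  structure(list(
    numClasses = as.integer(numClasses), K = as.integer(K),
    stageDims = as.integer(stageDims), poolingRate = as.integer(poolingRate),
    hgsLayers = as.integer(hgsLayers), hgsHeads = as.integer(hgsHeads),
    lambda = lambda, curvature = curvature, edgeProb = edgeProb,
    headDims = as.integer(headDims), leakySlope = leakySlope
  ), class = "GGEConfig")
}

# parameters of one GGE stage (both channels + gate)
ggeStageParams <- function(inputDim, M, cfg, seed = 0L) {
  withSeed(seed, list(
    euc = adaptiveKernelParams(inputDim, M, seed = NULL),
    hyp = hyperbolicChannelParams(inputDim, M, heads = cfg$hgsHeads,
                                  L = cfg$hgsLayers, seed = NULL),
    gateW = glorot(2L * M, M),
    gateb = numeric(M)
  ))
}

#' Initialize the full parameter set of the segmentation network
#'
#' @param cfg a [ggeConfig()].
#' @param seed seed for all weight initializations.
#' @return nested parameter list (`stages`, `head`).
#' @export
segNetInit <- function(cfg, seed = 0L) {
  dims <- cfg$stageDims
  inDims <- c(3L, dims[1:4])
  stages <- lapply(seq_len(5L), function(s)
    ggeStageParams(inDims[s], dims[s], cfg, seed = childSeed(seed, s)))
  catDim <- sum(dims)
  h1 <- cfg$headDims[1L]; h2 <- cfg$headDims[2L]
  head <- withSeed(childSeed(seed, 99L), list(
    W1 = glorot(catDim, h1), b1 = numeric(h1),
    W2 = glorot(h1, h2), b2 = numeric(h2),
    W3 = glorot(h2, cfg$numClasses), b3 = numeric(cfg$numClasses)
  ))
  list(stages = stages, head = head)
}

# one GGE block: dual-channel encoding + gate fusion.
# coords plain N x 3; features N x d (node or plain); edgeIdx N x K.
ggeBlock <- function(coords, features, edgeIdx, stagePar, cfg, seed = 0L) {
  fe <- euclideanChannelForward(coords, features, edgeIdx, stagePar$euc,
                                cfg$leakySlope)
  fht <- hyperbolicChannelForward(features, edgeIdx, stagePar$hyp,
                                  heads = cfg$hgsHeads, L = cfg$hgsLayers,
                                  lambda = cfg$lambda,
                                  curvature = cfg$curvature,
                                  edgeProb = cfg$edgeProb, seed = seed)
  g <- adSigmoid(adLinear(adConcatCols(fe, fht), stagePar$gateW, stagePar$gateb))
  adAdd(adMul(g, fe), adMul(adSub(1, g), fht))
}

#' Forward pass of a single GGE block
#'
#' Computes the Euclidean channel feature `f^e`, the hyperbolic channel
#' feature mapped back to the tangent space `f^{h'}`, and their gated fusion
#' `g * f^e + (1 - g) * f^{h'}` with `g = sigmoid(W [f^e; f^{h'}])`.
#'
#' @param cloud a normalized [PointCloud-class] (or N x 3 matrix).
#' @param features N x d per-point feature matrix (use the coordinates for
#'   the first stage).
#' @param params stage parameters from [ggeStageParams()] (internally) or a
#'   full [segNetInit()] stage entry.
#' @param cfg a [ggeConfig()].
#' @param seed seed for stochastic star-graph edges (unused at
#'   `edgeProb = 1`).
#' @return list with `fused`, `euclidean`, `hyperbolic` (each N x M).
#' @export
ggeForward <- function(cloud, features, params, cfg = ggeConfig(), seed = 0L) {
  p <- if (is(cloud, "PointCloud")) cloud@points else as.matrix(cloud)
  features <- as.matrix(features)
  stopIfNot(nrow(features) == nrow(p), "features misaligned with cloud")
  K <- min(cfg$K, nrow(p) - 1L)
  graph <- kdtreeKnn(p, K)
  fe <- euclideanChannelForward(p, features, graph$neighborIndices,
                                params$euc, cfg$leakySlope)
  fht <- hyperbolicChannelForward(features, graph$neighborIndices, params$hyp,
                                  heads = cfg$hgsHeads, L = cfg$hgsLayers,
                                  lambda = cfg$lambda,
                                  curvature = cfg$curvature,
                                  edgeProb = cfg$edgeProb, seed = seed)
  g <- adSigmoid(adLinear(adConcatCols(fe, fht), params$gateW, params$gateb))
  fused <- adAdd(adMul(g, fe), adMul(adSub(1, g), fht))
  list(fused = adVal(fused), euclidean = adVal(fe), hyperbolic = adVal(fht))
}

#' Forward pass of a GGE-P stage (GGE + graph pooling)
#'
#' Runs [ggeForward()], then farthest-point sampling at the configured rate,
#' then neighbourhood max pooling of the fused features onto the sampled
#' points.
#'
#' @inheritParams ggeForward
#' @param seed seed for farthest point sampling.
#' @return list with `cloud` (coarsened [PointCloud-class]), `features`
#'   (pooled matrix), and `sampled` (kept indices).
#' @export
ggePForward <- function(cloud, features, params, cfg = ggeConfig(), seed = 0L) {
  p <- if (is(cloud, "PointCloud")) cloud@points else as.matrix(cloud)
  n <- nrow(p)
  stopIfNot(n >= cfg$poolingRate, "cloud smaller than the pooling rate")
  K <- cfg$K
  if (K >= n) {
    K <- n - 1L
    warning("K clipped to N - 1 = ", K, " on a small stage", call. = FALSE)
  }
  out <- ggeForward(cloud, features, params,
                    modifyListSafe(cfg, list(K = K)), seed)
  graph <- kdtreeKnn(p, K)
  sampled <- farthestPointSampling(p, cfg$poolingRate, seed)
  pooled <- neighborhoodMaxPool(out$fused, graph, sampled)
  coarse <- if (is(cloud, "PointCloud")) cloud[sampled] else pointCloud(p[sampled, , drop = FALSE])
  list(cloud = coarse, features = pooled, sampled = sampled)
}

modifyListSafe <- function(cfg, upd) {
  out <- unclass(cfg)
  out[names(upd)] <- upd
  class(out) <- class(cfg)
  out
}

# precomputed per-cloud structures that depend only on coordinates:
# KNN graphs and FPS/pooling/interpolation at every level
prepareCloud <- function(cloud, cfg, seed = 0L) {
  p <- if (is(cloud, "PointCloud")) cloud@points else as.matrix(cloud)
  labels <- if (is(cloud, "PointCloud")) semanticLabels(cloud) else NULL
  lvl <- list(p)
  graphs <- list()
  pools <- list()
  fpsIdx <- list()
  for (level in 1:3) {
    cur <- lvl[[level]]
    stopIfNot(nrow(cur) >= 2L,
              "cloud too small for three graph pooling stages")
    K <- min(cfg$K, nrow(cur) - 1L)
    if (K < cfg$K)
      warning("K clipped to N - 1 = ", K, " at pooling level ", level,
              call. = FALSE)
    g <- kdtreeKnn(cur, K)
    sampled <- farthestPointSampling(cur, cfg$poolingRate,
                                     childSeed(seed, level))
    graphs[[level]] <- g
    fpsIdx[[level]] <- sampled
    pools[[level]] <- cbind(sampled, g$neighborIndices[sampled, , drop = FALSE])
    lvl[[level + 1L]] <- cur[sampled, , drop = FALSE]
  }
  interp <- lapply(2:4, function(level) idwWeights(lvl[[level]], p))
  list(coords = lvl, graphs = graphs, pools = pools, fps = fpsIdx,
       interp = interp, labels = labels, N = nrow(p))
}

# core forward on a prepared cloud; P may hold plain matrices (inference) or
# adLeaf nodes (training). Returns scores and the pre-head embedding.
segNetForwardCore <- function(prep, P, cfg, seed = 0L) {
  slope <- cfg$leakySlope
  x0 <- prep$coords[[1L]]
  g0 <- prep$graphs[[1L]]$neighborIndices
  s1 <- ggeBlock(x0, x0, g0, P$stages[[1L]], cfg, childSeed(seed, 11L))
  s2 <- ggeBlock(x0, s1, g0, P$stages[[2L]], cfg, childSeed(seed, 12L))
  e3 <- ggeBlock(x0, s2, g0, P$stages[[3L]], cfg, childSeed(seed, 13L))
  s3 <- adMaxPoolGroup(e3, prep$pools[[1L]])
  x1 <- prep$coords[[2L]]
  e4 <- ggeBlock(x1, s3, prep$graphs[[2L]]$neighborIndices, P$stages[[4L]],
                 cfg, childSeed(seed, 14L))
  s4 <- adMaxPoolGroup(e4, prep$pools[[2L]])
  x2 <- prep$coords[[3L]]
  e5 <- ggeBlock(x2, s4, prep$graphs[[3L]]$neighborIndices, P$stages[[5L]],
                 cfg, childSeed(seed, 15L))
  s5 <- adMaxPoolGroup(e5, prep$pools[[3L]])
  emb <- adConcatCols(s1, s2,
                      adSpmm(prep$interp[[1L]], s3),
                      adSpmm(prep$interp[[2L]], s4),
                      adSpmm(prep$interp[[3L]], s5))
  h <- adLeakyRelu(adLinear(emb, P$head$W1, P$head$b1), slope)
  h <- adLeakyRelu(adLinear(h, P$head$W2, P$head$b2), slope)
  scores <- adLinear(h, P$head$W3, P$head$b3)
  list(scores = scores, embedding = emb,
       stageSizes = c(prep$N, prep$N, nrow(prep$coords[[2L]]),
                      nrow(prep$coords[[3L]]), nrow(prep$coords[[4L]])))
}

#' Full forward pass of the segmentation network
#'
#' Two full-resolution GGE stages, three GGE-P stages (each coarsening the
#' cloud by the pooling rate), inverse-distance interpolation of every stage
#' output back to N points, concatenation, and the shared MLP head.
#'
#' @param cloud a normalized [PointCloud-class].
#' @param params parameters from [segNetInit()] or a trained model's
#'   `$params`.
#' @param cfg the matching [ggeConfig()].
#' @param seed seed for farthest point sampling (and stochastic star edges).
#' @return list with `scores` (N x numClasses unnormalized class scores),
#'   `embedding` (N x sum(stageDims) pre-head features), and `stageSizes`
#'   (point counts seen by the five stages).
#' @export
segNetForward <- function(cloud, params, cfg = ggeConfig(), seed = 0L) {
  stopIfNot(is(cloud, "PointCloud"), "cloud must be a PointCloud")
  stopIfNot(isNormalized(cloud), "cloud must be normalized (see normalizePoints)")
  if (npoints(cloud) < 64L * cfg$K)
    warning("N < 64 * K: the deepest pooling stages see very few points",
            call. = FALSE)
  prep <- prepareCloud(cloud, cfg, seed)
  out <- segNetForwardCore(prep, params, cfg, seed)
  out$scores <- adVal(out$scores)
  out$embedding <- adVal(out$embedding)
  out
}

## ---- parameter tree helpers ------------------------------------------------

# apply f to every double-typed leaf of a nested parameter list
mapParams <- function(x, f) {
  if (is.list(x)) return(lapply(x, mapParams, f = f))
  if (is.double(x)) return(f(x))
  x
}

# apply f(leafA, leafB) across two parallel parameter trees
mapParams2 <- function(a, b, f) {
  if (is.list(a)) return(mapply(mapParams2, a, b, MoreArgs = list(f = f),
                                SIMPLIFY = FALSE))
  if (is.double(a)) return(f(a, b))
  a
}

paramsWrap <- function(params) mapParams(params, adLeaf)

# extract accumulated gradients from a wrapped tree (zeros when untouched)
paramsGradTree <- function(wrapped) {
  extract <- function(x) {
    if (is.list(x)) return(lapply(x, extract))
    if (isNode(x)) {
      g <- x$grad
      if (is.null(g)) g <- x$value * 0
      return(g)
    }
    x
  }
  extract(wrapped)
}

paramsSumSq <- function(tree) {
  tot <- 0
  walk <- function(x) {
    if (is.list(x)) { for (e in x) walk(e) }
    else if (is.double(x)) tot <<- tot + sum(x * x)
  }
  walk(tree)
  tot
}
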