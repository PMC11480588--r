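#' Exponential map onto the Poincaré ball at the origin
#'
#' Projects Euclidean (tangent) features into the Poincaré ball of curvature
#' `-c`: `exp_0^c(f) = tanh(sqrt(c) ||f||) f / (sqrt(c) ||f||)`, with 0
#' mapping to 0. Output is strictly inside the ball of radius `1/sqrt(c)`.
#'
#' @param f numeric vector or matrix (rows are mapped independently).
#' @param c positive curvature parameter of the ball of curvature `-c`.
#' @return mapped vector/matrix of the same shape.
#' @examples
#' expmap0(c(1, 0, 0), c = 1)  # (tanh(1), 0, 0)
#' @export
expmap0 <- function(f, c = 1) {
  stopIfNot(is.finite(c) && c > 0, "curvature parameter c must be positive")
  vec <- is.null(dim(f))
  m <- if (vec) matrix(f, nrow = 1L) else as.matrix(f)
  stopIfNot(all(is.finite(m)), "expmap0 requires finite input")
  out <- adExpmap0(m, c)
  if (vec) as.numeric(out) else out
}

#' Logarithmic map from the Poincaré ball back to the tangent space
#'
#' Inverse of [expmap0()]: `log_0^c(h) = artanh(sqrt(c) ||h||) h /
#' (sqrt(c) ||h||)`. Errors if a row lies on or outside the ball.
#'
#' @param h numeric vector or matrix of ball coordinates.
#' @param c positive curvature parameter.
#' @return tangent-space vector/matrix of the same shape.
#' @export
logmap0 <- function(h, c = 1) {
  stopIfNot(is.finite(c) && c > 0, "curvature parameter c must be positive")
  vec <- is.null(dim(h))
  m <- if (vec) matrix(h, nrow = 1L) else as.matrix(h)
  out <- adLogmap0(m, c)
  if (vec) as.numeric(out) else out
}

#' Build the star graph of one point
#'
#' The centre ("planet") is connected to all K neighbours, which form a ring
#' in ascending-distance order with cyclic adjacency. Ring edges are kept
#' independently with probability `edgeProb` (a dropped edge leaves a zero
#' context slot in the encoder); `edgeProb = 1` gives the deterministic full
#' ring.
#'
#' @param graph a `NeighborGraph` from [kdtreeKnn()].
#' @param center index of the planet point.
#' @param edgeProb ring-edge inclusion probability in `[0, 1]`.
#' @param seed seed for the Bernoulli draws.
#' @return a `StarGraph`: list with `planet`, `ring` (ordered neighbour
#'   indices), `ringEdges` (logical K; entry k is the edge ring k -> k+1,
#'   cyclically), and `edgeProb`.
#' @export
buildStarGraph <- function(graph, center, edgeProb = 1, seed = 0L) {
  stopIfNot(edgeProb >= 0 && edgeProb <= 1, "edgeProb must lie in [0, 1]")
  ring <- graph$neighborIndices[center, ]
  K <- length(ring)
  ringEdges <- if (edgeProb >= 1) rep(TRUE, K)
    else withSeed(seed, runif(K) < edgeProb)
  structure(list(planet = center, ring = ring, ringEdges = ringEdges,
                 edgeProb = edgeProb),
            class = "StarGraph")
}

#' Parameters of the hyperbolic geometric structure (HGS) encoder
#'
#' Per layer: multi-head scaled dot-product attention (separate Q/K/V and
#' output projections for the ring update and the planet update) with
#' post-attention ReLU and layer normalization.
#'
#' @param M feature width; must be divisible by `heads`.
#' @param heads attention head count.
#' @param L number of stacked layers.
#' @param seed seed for Glorot-uniform initialization.
#' @return nested list of parameter matrices.
#' @export
hgsParams <- function(M, heads = 4L, L = 2L, seed = 0L) {
  stopIfNot(M %% heads == 0L, "heads must divide M")
  mkAtt <- function() list(
    Wq = glorot(M, M), Wk = glorot(M, M), Wv = glorot(M, M), Wo = glorot(M, M),
    lnG = rep(1, M), lnB = numeric(M)
  )
  withSeed(seed, list(
    layers = lapply(seq_len(L), function(l) list(ring = mkAtt(), planet = mkAtt())),
    M = as.integer(M), heads = as.integer(heads), L = as.integer(L)
  ))
}

#' State of the HGS encoder
#'
#' @param ring K x M matrix of ring (neighbour) embeddings.
#' @param planet length-M planet embedding.
#' @param heads attention head count (must divide M).
#' @param lambda residual scale applied to the final planet embedding.
#' @param curvature positive curvature parameter of the ball.
#' @return an `HGSState` list.
#' @export
hgsState <- function(ring, planet, heads = 4L, lambda = 1, curvature = 1) {
  ring <- as.matrix(ring)
  stopIfNot(ncol(ring) %% heads == 0L, "heads must divide the feature width")
  stopIfNot(lambda >= 0, "lambda must be non-negative")
  structure(list(ring = ring, planet = as.numeric(planet),
                 heads = as.integer(heads), lambda = lambda,
                 curvature = curvature),
            class = "HGSState")
}

# one ring + planet update on batched embeddings.
# ringH: (N*K) x M (neighbour index fastest), S: N x M.
# maskPrev/maskNext: optional logical (N*K) marking *kept* cyclic ring edges.
hgsLayerApply <- function(ringH, S, N, K, layerPar, heads, maskPrev = NULL,
                          maskNext = NULL) {
  r <- seq_len(N * K)
  i <- (r - 1L) %/% K + 1L
  k <- (r - 1L) %% K + 1L
  km1 <- (i - 1L) * K + ifelse(k == 1L, K, k - 1L)
  kp1 <- (i - 1L) * K + ifelse(k == K, 1L, k + 1L)
  cidx <- as.vector(rbind(km1, r, kp1, N * K + i))  # 4 context slots, slot fastest
  ctx <- adGatherRows2(ringH, S, cidx)
  if (!is.null(maskPrev)) {
    keep <- rep(1, length(cidx))
    keep[seq(1L, by = 4L, length.out = N * K)] <- as.numeric(maskPrev)
    keep[seq(3L, by = 4L, length.out = N * K)] <- as.numeric(maskNext)
    ctx <- adMul(ctx, matrix(keep, nrow = length(keep),
                             ncol = ncol(adVal(ctx))))
  }
  rp <- layerPar$ring
  att <- adMatmul(adAttention(adMatmul(ringH, rp$Wq), adMatmul(ctx, rp$Wk),
                              adMatmul(ctx, rp$Wv), 4L, heads), rp$Wo)
  ringNew <- adLayerNorm(adRelu(att), rp$lnG, rp$lnB)

  cidx2 <- as.vector(rbind(seq_len(N), N + matrix(r, nrow = K)))
  ctx2 <- adGatherRows2(S, ringNew, cidx2)
  pp <- layerPar$planet
  att2 <- adMatmul(adAttention(adMatmul(S, pp$Wq), adMatmul(ctx2, pp$Wk),
                               adMatmul(ctx2, pp$Wv), K + 1L, heads), pp$Wo)
  SNew <- adLayerNorm(adRelu(att2), pp$lnG, pp$lnB)
  list(ring = ringNew, planet = SNew)
}

#' One HGS layer on a single star graph
#'
#' Updates every ring embedding from its cyclic context (previous, self, next
#' ring neighbours plus the planet) via multi-head attention, then updates
#' the planet from its own embedding and the refreshed ring.
#'
#' @param state an [hgsState()].
#' @param star a `StarGraph` from [buildStarGraph()] (its `ringEdges` mask
#'   zeroes dropped context slots).
#' @param params an [hgsParams()] parameter set.
#' @param layer which layer's parameters to apply.
#' @return the updated `HGSState`.
#' @export
hgsLayer <- function(state, star, params, layer = 1L) {
  stopIfNot(inherits(state, "HGSState"), "state must be an HGSState")
  K <- nrow(state$ring)
  M <- ncol(state$ring)
  stopIfNot(params$M == M, "parameter width does not match the state")
  stopIfNot(params$heads == state$heads, "head count mismatch")
  kIdx <- seq_len(K)
  prevEdge <- star$ringEdges[ifelse(kIdx == 1L, K, kIdx - 1L)]  # edge (k-1, k)
  nextEdge <- star$ringEdges                                     # edge (k, k+1)
  useMask <- !all(star$ringEdges)
  upd <- hgsLayerApply(state$ring, matrix(state$planet, nrow = 1L), 1L, K,
                       params$layers[[layer]], state$heads,
                       maskPrev = if (useMask) prevEdge else NULL,
                       maskNext = if (useMask) nextEdge else NULL)
  state$ring <- adVal(upd$ring)
  state$planet <- as.numeric(adVal(upd$planet))
  state
}

#' Full HGS encoding of a single star graph
#'
#' Applies `L` [hgsLayer()] updates to ring/planet embeddings that already
#' live on the Poincaré ball (map them with [expmap0()] upstream), then adds
#' the residual `lambda * s^L` to the planet's input embedding and projects
#' back inside the ball.
#'
#' @param ringInit K x M matrix of initial ring embeddings (ball coordinates).
#' @param planetInit length-M initial planet embedding (ball coordinates).
#' @param params an [hgsParams()] set; its `L` determines the layer count.
#' @param star a `StarGraph`; defaults to a full deterministic ring.
#' @param heads,lambda,curvature see [hgsState()].
#' @return length-M hyperbolic feature vector `f^h` of the planet.
#' @export
hgsEncode <- function(ringInit, planetInit, params, star = NULL,
                      heads = params$heads, lambda = 1, curvature = 1) {
  state <- hgsState(ringInit, planetInit, heads = heads, lambda = lambda,
                    curvature = curvature)
  if (is.null(star))
    star <- list(planet = 0L, ring = seq_len(nrow(state$ring)),
                 ringEdges = rep(TRUE, nrow(state$ring)), edgeProb = 1)
  for (l in seq_len(params$L)) state <- hgsLayer(state, star, params, l)
  res <- as.numeric(planetInit) + lambda * state$planet
  as.numeric(adBallProject(matrix(res, nrow = 1L), curvature))
}

# batched hyperbolic channel for one network stage:
# features (N x d) -> tangent-space output f^{h'} (N x M)
hyperbolicChannelForward <- function(features, edgeIdx, par, heads, L, lambda,
                                     curvature, edgeProb = 1, seed = 0L) {
  N <- nrow(edgeIdx)
  K <- ncol(edgeIdx)
  tang <- adLinear(features, par$inW, par$inb)
  ball <- adExpmap0(tang, curvature)
  nb <- as.vector(t(edgeIdx))
  ringH <- adGatherRows(ball, nb)
  S <- ball
  maskPrev <- maskNext <- NULL
  if (edgeProb < 1) {
    edges <- withSeed(seed, matrix(runif(N * K) < edgeProb, N, K))
    kIdx <- rep(seq_len(K), times = N)
    iIdx <- rep(seq_len(N), each = K)
    nextEdge <- edges[cbind(iIdx, kIdx)]
    maskPrev <- edges[cbind(iIdx, ifelse(kIdx == 1L, K, kIdx - 1L))]
    maskNext <- nextEdge
  }
  for (l in seq_len(L)) {
    upd <- hgsLayerApply(ringH, S, N, K, par$layers[[l]], heads,
                         maskPrev = maskPrev, maskNext = maskNext)
    ringH <- upd$ring
    S <- upd$planet
  }
  fh <- adBallProject(adAdd(ball, adScale(S, lambda)), curvature)
  adLogmap0(fh, curvature)
}

# parameters of the batched hyperbolic channel for one stage
hyperbolicChannelParams <- function(inputDim, M, heads = 4L, L = 2L, seed = 0L) {
  withSeed(seed, {
    base <- hgsParams(M, heads = heads, L = L, seed = NULL)
    c(base, list(inW = glorot(inputDim, M), inb = numeric(M)))
  })
}
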