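#' Exact K-nearest-neighbour graph via a kd-tree
#'
#' Builds the per-point neighbourhood index structure that feeds both encoder
#' channels. Neighbours are exact under Euclidean distance, exclude the point
#' itself, are sorted by ascending distance, and ties are broken toward the
#' lower point index so the graph is fully deterministic.
#'
#' @param cloud a [PointCloud-class] (or a bare N x 3 matrix).
#' @param K number of neighbours per point; must satisfy `K < N`. The
#'   pipeline default is 20.
#' @return a `NeighborGraph`: list with `neighborIndices` (N x K integer
#'   matrix, 1-based), `K`, and `N`.
#' @export
kdtreeKnn <- function(cloud, K = 20L) {
  p <- if (is(cloud, "PointCloud")) cloud@points else as.matrix(cloud)
  K <- as.integer(K)
  if (K >= nrow(p)) stop("K must be smaller than the number of points", call. = FALSE)
  stopIfNot(K >= 1L, "K must be at least 1")
  idx <- .knn_cpp(p, K)
  structure(list(neighborIndices = idx, K = K, N = nrow(p)),
            class = "NeighborGraph")
}

#' Farthest point sampling
#'
#' Greedy coverage-maximizing subset selection: after a seeded first pick,
#' each subsequent index maximizes its minimal distance to the already
#' selected set. Used by the graph pooling stages at a sampling rate of 4.
#'
#' @param cloud a [PointCloud-class] or N x 3 matrix.
#' @param rate integer sampling rate; `ceiling(N / rate)` indices are
#'   returned. `rate = 1` returns all indices.
#' @param seed seed determining the first pick: points are ranked by
#'   distance from the centroid and the `(seed mod N) + 1`-th farthest is
#'   chosen, so the pick is deterministic given the seed *and* covariant
#'   under permutations of the point order (seed 0 starts from the farthest
#'   point).
#' @return integer vector of selected point indices (1-based).
#' @export
farthestPointSampling <- function(cloud, rate = 4L, seed = 0L) {
  p <- if (is(cloud, "PointCloud")) cloud@points else as.matrix(cloud)
  rate <- as.integer(rate)
  stopIfNot(rate >= 1L, "rate must be at least 1")
  n <- nrow(p)
  m <- as.integer(ceiling(n / rate))
  if (rate == 1L) return(seq_len(n))
  d2 <- rowSums(sweep(p, 2L, colMeans(p))^2)
  start <- order(d2, decreasing = TRUE)[(as.integer(seed) %% n) + 1L]
  as.integer(.fps_cpp(p, m, start))
}

#' Spatial and feature edge encodings of a neighbourhood graph
#'
#' For every directed edge (i, j) of the graph builds the 6-dim spatial
#' encoding `[x_i; x_j - x_i]` and the 2D-dim feature encoding
#' `[f_i; f_j - f_i]`. Rows are ordered centre-major with the neighbour index
#' fastest, matching what the Euclidean channel consumes.
#'
#' @param cloud a [PointCloud-class] or N x 3 matrix.
#' @param features numeric N x D feature matrix aligned with the cloud.
#' @param graph a `NeighborGraph` from [kdtreeKnn()].
#' @return an `EdgeEncoding`: list with `spatial` (N*K x 6), `feature`
#'   (N*K x 2D), `kernelResponses` (NULL until filled by
#'   [adaptiveKernelResponse()]), `attentionWeights` (NULL until filled by
#'   [attentionPool()]), `K`, and `N`.
#' @export
edgeEncode <- function(cloud, features, graph) {
  p <- if (is(cloud, "PointCloud")) cloud@points else as.matrix(cloud)
  features <- as.matrix(features)
  stopIfNot(nrow(features) == nrow(p),
            "features row count must match the number of points")
  idx <- graph$neighborIndices
  K <- graph$K
  ctr <- rep(seq_len(nrow(p)), each = K)
  nb <- as.vector(t(idx))
  spatial <- cbind(p[ctr, , drop = FALSE], p[nb, , drop = FALSE] - p[ctr, , drop = FALSE])
  fi <- features[ctr, , drop = FALSE]
  feature <- cbind(fi, features[nb, , drop = FALSE] - fi)
  structure(list(spatial = spatial, feature = feature,
                 kernelResponses = NULL, attentionWeights = NULL,
                 K = K, N = nrow(p)),
            class = "EdgeEncoding")
}

#' Neighbourhood max pooling onto a sampled subset
#'
#' For each sampled point, takes the channel-wise maximum of the features
#' over its K-neighbourhood on the pre-sampling cloud (centre included).
#'
#' @param features numeric N x D matrix.
#' @param graph `NeighborGraph` on the full cloud.
#' @param sampled integer indices of the retained points.
#' @return numeric `length(sampled) x D` matrix of pooled features.
#' @export
neighborhoodMaxPool <- function(features, graph, sampled) {
  features <- as.matrix(features)
  stopIfNot(all(sampled >= 1L & sampled <= graph$N), "sampled indices out of range")
  idxMat <- cbind(sampled, graph$neighborIndices[sampled, , drop = FALSE])
  adMaxPoolGroup(features, idxMat)
}

#' Inverse-distance-weighted feature interpolation
#'
#' Brings coarse-stage features back to a fine point set: each fine point's
#' feature is the inverse-distance-weighted mean of its 3 nearest coarse
#' features (weights `1/(d + 1e-8)`, normalized), so a fine point coinciding
#' with a coarse point copies that coarse feature.
#'
#' @param coarsePoints coarse [PointCloud-class] or matrix (n x 3).
#' @param coarseFeatures numeric n x D matrix.
#' @param finePoints fine [PointCloud-class] or matrix (N x 3).
#' @return numeric N x D interpolated feature matrix.
#' @export
idwInterpolate <- function(coarsePoints, coarseFeatures, finePoints) {
  W <- idwWeights(coarsePoints, finePoints)
  as.matrix(W %*% as.matrix(coarseFeatures))
}

# sparse N_fine x N_coarse interpolation weight matrix (3-NN inverse distance)
idwWeights <- function(coarsePoints, finePoints) {
  cp <- if (is(coarsePoints, "PointCloud")) coarsePoints@points else as.matrix(coarsePoints)
  fp <- if (is(finePoints, "PointCloud")) finePoints@points else as.matrix(finePoints)
  nC <- nrow(cp)
  k <- min(3L, nC)
  d2 <- crossdist2(fp, cp)
  nF <- nrow(fp)
  if (nC == 1L) {
    return(Matrix::sparseMatrix(i = seq_len(nF), j = rep(1L, nF), x = 1,
                                dims = c(nF, 1L)))
  }
  ord <- apply(d2, 1L, function(r) order(r)[seq_len(k)])  # k x nF
  j <- as.vector(ord)
  i <- rep(seq_len(nF), each = k)
  d <- sqrt(d2[cbind(i, j)])
  w <- 1 / (d + 1e-8)
  wSum <- rowsum(w, group = i, reorder = FALSE)
  w <- w / wSum[i]
  Matrix::sparseMatrix(i = i, j = j, x = w, dims = c(nF, nC))
}
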