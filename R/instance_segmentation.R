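# Leaf instance segmentation: K-means++ seeding, Lloyd iterations with a
# per-iteration inertia trace, and elbow-based model selection.

kmeansPlusPlusInit <- function(X, K) {
  n <- nrow(X)
  centers <- matrix(NA_real_, K, ncol(X))
  first <- sample.int(n, 1L)
  centers[1L, ] <- X[first, ]
  minD2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
  if (K > 1L) for (k in 2:K) {
    tot <- sum(minD2)
    pick <- if (tot <= 0) sample.int(n, 1L)
      else sample.int(n, 1L, prob = minD2 / tot)
    centers[k, ] <- X[pick, ]
    minD2 <- pmin(minD2, rowSums(sweep(X, 2L, centers[k, ])^2))
  }
  centers
}

# Lloyd iterations; returns assignments, centers and the inertia recorded
# after every update (non-increasing by construction)
lloyd <- function(X, centers, maxIter = 300L, tol = 1e-6) {
  K <- nrow(centers)
  inertiaTrace <- numeric(0)
  assign <- NULL
  for (it in seq_len(maxIter)) {
    d2 <- crossdist2(X, centers)
    assign <- max.col(-d2)
    inertiaTrace <- c(inertiaTrace, sum(d2[cbind(seq_len(nrow(X)), assign)]))
    newCenters <- centers
    agg <- rowsum(X, group = assign, reorder = FALSE)
    sizes <- tabulate(assign, nbins = K)
    got <- as.integer(rownames(agg))
    newCenters[got, ] <- agg / sizes[got]
    # empty clusters keep their previous centre
    shift <- max(rowNorms(newCenters - centers))
    centers <- newCenters
    if (shift < tol) break
  }
  d2 <- crossdist2(X, centers)
  assign <- max.col(-d2)
  list(assign = assign, centers = centers,
       inertia = sum(d2[cbind(seq_len(nrow(X)), assign)]),
       inertiaTrace = inertiaTrace)
}

#' K-means clustering of leaf points into instances
#'
#' Runs K-means++ seeding followed by Lloyd iterations (convergence at
#' centroid shift `< 1e-6` or 300 iterations) on the leaf-labelled points
#' only; stem points keep instance id -1. Clustering operates on restored
#' metric coordinates since phenotyping follows.
#'
#' @param cloud a [PointCloud-class] with semantic labels (0 = leaf).
#' @param K number of leaf instances; must not exceed the leaf point count.
#' @param seed seed for the K-means++ draws.
#' @param nstart restarts; the solution with the lowest inertia wins.
#' @param leafLabel semantic label treated as leaf (default 0).
#' @return a `ClusteringResult`: list with `cloud` (instance ids filled:
#'   leaf instances 1..K, stem -1), `instanceIds` (per-leaf-point ids in
#'   `[0, K)`), `centroids` (K x 3), `inertia`, and `inertiaTrace`
#'   (per-Lloyd-iteration, non-increasing).
#' @export
kmeansLeafInstances <- function(cloud, K, seed = 0L, nstart = 10L,
                                leafLabel = 0L) {
  stopIfNot(is(cloud, "PointCloud"), "cloud must be a PointCloud")
  labs <- semanticLabels(cloud)
  stopIfNot(!is.null(labs), "cloud must carry semantic labels")
  leafIdx <- which(labs == leafLabel)
  K <- as.integer(K)
  if (K > length(leafIdx))
    stop("K exceeds the number of leaf points", call. = FALSE)
  X <- cloud@points[leafIdx, , drop = FALSE]
  best <- NULL
  for (r in seq_len(nstart)) {
    fit <- withSeed(childSeed(seed, r), {
      centers <- kmeansPlusPlusInit(X, K)
      lloyd(X, centers)
    })
    if (is.null(best) || fit$inertia < best$inertia) best <- fit
  }
  ids <- rep(-1L, npoints(cloud))
  ids[leafIdx] <- best$assign  # leaf instances 1..K; stem stays -1
  out <- cloud
  out@instanceIds <- ids
  structure(list(cloud = out, instanceIds = best$assign - 1L,
                 centroids = best$centers, inertia = best$inertia,
                 inertiaTrace = best$inertiaTrace),
            class = "ClusteringResult")
}

#' Elbow selection of the leaf instance count
#'
#' Runs seeded K-means over a range of K, records the inertia curve, and
#' returns the K maximizing the perpendicular distance from the curve to the
#' chord joining its endpoints (both axes normalized to `[0, 1]` first, the
#' usual kneedle-style geometric elbow).
#'
#' @param cloud a [PointCloud-class] with semantic labels, or a bare matrix
#'   of leaf points.
#' @param kRange candidate K values (default 1..10, matching plants carrying
#'   up to ~10 leaves); truncated with a warning if it exceeds the leaf
#'   point count.
#' @param seed seed shared by all K-means runs.
#' @param leafLabel semantic label treated as leaf.
#' @return list with `K` (the selected count) and `inertiaCurve`
#'   (data.frame of K and inertia, non-increasing).
#' @export
elbowSelectK <- function(cloud, kRange = 1:10, seed = 0L, leafLabel = 0L) {
  if (is(cloud, "PointCloud")) {
    labs <- semanticLabels(cloud)
    X <- if (is.null(labs)) cloud@points
      else cloud@points[labs == leafLabel, , drop = FALSE]
  } else {
    X <- as.matrix(cloud)
  }
  kRange <- sort(unique(as.integer(kRange)))
  stopIfNot(all(kRange >= 1L), "kRange must be positive")
  if (max(kRange) > nrow(X)) {
    warning("kRange truncated to the number of leaf points", call. = FALSE)
    kRange <- kRange[kRange <= nrow(X)]
  }
  # best fit per K: seeded K-means++ restarts plus a warm start that splits
  # the previous solution (guarantees a non-increasing inertia curve)
  inertia <- numeric(length(kRange))
  prev <- NULL
  for (ki in seq_along(kRange)) {
    k <- kRange[ki]
    best <- withSeed(childSeed(seed, k), {
      fits <- lapply(seq_len(5L), function(r) lloyd(X, kmeansPlusPlusInit(X, k)))
      fits[[which.min(vapply(fits, `[[`, numeric(1), "inertia"))]]
    })
    if (!is.null(prev) && nrow(prev$centers) == k - 1L) {
      d2 <- crossdist2(X, prev$centers)
      far <- which.max(d2[cbind(seq_len(nrow(X)), prev$assign)])
      warm <- lloyd(X, rbind(prev$centers, X[far, , drop = FALSE]))
      if (warm$inertia < best$inertia) best <- warm
    }
    inertia[ki] <- best$inertia
    prev <- best
  }
  curve <- data.frame(K = kRange, inertia = inertia)
  if (length(kRange) == 1L) return(list(K = kRange, inertiaCurve = curve))
  # no elbow is declared when one split barely helps (structureless cluster)
  if (kRange[1L] == 1L && length(kRange) >= 2L && kRange[2L] == 2L &&
      (inertia[1L] <= 0 || inertia[2L] / inertia[1L] > 0.5))
    return(list(K = 1L, inertiaCurve = curve))
  # geometric elbow on the [0,1]-normalized log-inertia curve: the log scale
  # makes the chord criterion sensitive to the bend where within-cluster
  # structure is exhausted rather than to the (always huge) first drops
  floorVal <- max(min(inertia[inertia > 0], na.rm = TRUE) * 1e-3, 1e-300)
  logInertia <- log(pmax(inertia, floorVal))
  xs <- (kRange - min(kRange)) / (max(kRange) - min(kRange))
  span <- max(logInertia) - min(logInertia)
  ys <- if (span > 0) (logInertia - min(logInertia)) / span else inertia * 0
  x1 <- xs[1L]; y1 <- ys[1L]
  x2 <- xs[length(xs)]; y2 <- ys[length(ys)]
  dist <- abs((y2 - y1) * xs - (x2 - x1) * ys + x2 * y1 - y2 * x1) /
    sqrt((y2 - y1)^2 + (x2 - x1)^2)
  list(K = kRange[which.max(dist)], inertiaCurve = curve)
}
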