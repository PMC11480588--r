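#' Plant height from a metric point cloud
#'
#' `C_h = z_max - z_min` over the full cloud in restored (metric)
#' coordinates.
#'
#' @param cloud a [PointCloud-class] (not normalized) or N x 3 matrix.
#' @return height in the cloud's length unit (cm for the standard pipeline).
#' @export
plantHeight <- function(cloud) {
  p <- if (is(cloud, "PointCloud")) cloud@points else as.matrix(cloud)
  max(p[, 3L]) - min(p[, 3L])
}

#' Leaf length and width via PCA-aligned extremal point pairs
#'
#' PCA aligns the leaf with its natural axes; the length is the Euclidean
#' distance between the two points extremal along the first principal axis,
#' the width the same along the second axis. Output is ordered so that
#' length >= width. Because the distances are measured between actual surface
#' points, leaf curvature inflates both slightly relative to a flattened
#' leaf.
#'
#' @param leaf a [PointCloud-class] or matrix of one leaf's points (>= 3
#'   non-collinear points).
#' @return named numeric `c(length = , width = )` in input units.
#' @export
leafLengthWidth <- function(leaf) {
  p <- if (is(leaf, "PointCloud")) leaf@points else as.matrix(leaf)
  if (nrow(p) < 3L)
    stop("at least 3 points are required to measure a leaf", call. = FALSE)
  pc <- prcomp(p, center = TRUE, scale. = FALSE)
  if (pc$sdev[2L] < 1e-12)
    stop("leaf points are collinear; length/width undefined", call. = FALSE)
  extent <- function(score) {
    lo <- which.min(score)
    hi <- which.max(score)
    sqrt(sum((p[hi, ] - p[lo, ])^2))
  }
  l <- extent(pc$x[, 1L])
  w <- extent(pc$x[, 2L])
  c(length = max(l, w), width = min(l, w))
}

#' Reference leaf area from manual length/width measurements
#'
#' The standard manual convention for the reference (ground-truth) leaf
#' area: `0.743 * length * width`.
#'
#' @param length,width leaf extent measurements (cm).
#' @return reference area (cm^2).
#' @examples
#' referenceLeafArea(10, 8)  # 59.44
#' @export
referenceLeafArea <- function(length, width) {
  stopIfNot(all(length >= 0) && all(width >= 0), "inputs must be non-negative")
  0.743 * length * width
}

# per-point unit normals by local PCA with BFS orientation propagation
estimateNormals <- function(p, k = 10L) {
  n <- nrow(p)
  k <- min(k, n - 1L)
  g <- .knn_cpp(p, k)
  normals <- matrix(0, n, 3L)
  for (i in seq_len(n)) {
    nb <- p[c(i, g[i, ]), , drop = FALSE]
    cv <- crossprod(sweep(nb, 2L, colMeans(nb)))
    normals[i, ] <- eigen(cv, symmetric = TRUE)$vectors[, 3L]
  }
  # propagate a consistent orientation over the KNN graph
  visited <- logical(n)
  queue <- 1L
  visited[1L] <- TRUE
  while (length(queue)) {
    i <- queue[1L]
    queue <- queue[-1L]
    for (j in g[i, ]) {
      if (visited[j]) next
      if (sum(normals[i, ] * normals[j, ]) < 0) normals[j, ] <- -normals[j, ]
      visited[j] <- TRUE
      queue <- c(queue, j)
    }
  }
  if (any(!visited)) {
    # disconnected leftovers keep their local orientation
    visited[] <- TRUE
  }
  normals
}

# triangle areas by Heron's formula from edge lengths
heronAreas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1L], , drop = FALSE]
  b <- vertices[triangles[, 2L], , drop = FALSE]
  c <- vertices[triangles[, 3L], , drop = FALSE]
  e1 <- sqrt(rowSums((a - b)^2))
  e2 <- sqrt(rowSums((b - c)^2))
  e3 <- sqrt(rowSums((c - a)^2))
  s <- (e1 + e2 + e3) / 2
  sq <- s * (s - e1) * (s - e2) * (s - e3)
  sq[sq < 0] <- 0
  sqrt(sq)
}

# cross-product triangle areas (independent check of the Heron sums)
crossAreas <- function(vertices, triangles) {
  a <- vertices[triangles[, 1L], , drop = FALSE]
  u <- vertices[triangles[, 2L], , drop = FALSE] - a
  v <- vertices[triangles[, 3L], , drop = FALSE] - a
  cx <- u[, 2L] * v[, 3L] - u[, 3L] * v[, 2L]
  cy <- u[, 3L] * v[, 1L] - u[, 1L] * v[, 3L]
  cz <- u[, 1L] * v[, 2L] - u[, 2L] * v[, 1L]
  sqrt(cx^2 + cy^2 + cz^2) / 2
}

#' Leaf area by ball-pivoting surface reconstruction
#'
#' Reconstructs the leaf surface with the ball-pivoting algorithm at the
#' given radii (ascending multi-radius passes fill holes left in sparser
#' regions) and sums the triangle areas by Heron's formula. Degenerate
#' triangles (area below 1e-12) are dropped from the mesh.
#'
#' @param leaf a [PointCloud-class] or matrix of one leaf's points in metric
#'   coordinates (>= 3 points).
#' @param radii positive pivot radii; default `c(1.5, 3, 6) *` the leaf's
#'   mean nearest-neighbour spacing.
#' @return list with `area` (sum of triangle areas, cm^2) and `mesh` (a
#'   `LeafMesh`: list of `vertices` and `triangles`).
#' @export
bpaLeafArea <- function(leaf, radii = NULL) {
  p <- if (is(leaf, "PointCloud")) leaf@points else as.matrix(leaf)
  if (nrow(p) < 3L)
    stop("at least 3 points are required for surface reconstruction",
         call. = FALSE)
  if (is.null(radii)) radii <- c(1.5, 3, 6) * meanNNDistance(p)
  stopIfNot(all(radii > 0), "radii must be positive")
  normals <- estimateNormals(p)
  tri <- .bpa_cpp(p, normals, as.numeric(radii))
  if (nrow(tri) == 0L)
    stop("ball pivoting produced no triangles; adjust the radii to the ",
         "sampling density", call. = FALSE)
  areas <- heronAreas(p, tri)
  keep <- areas > 1e-12
  tri <- tri[keep, , drop = FALSE]
  list(area = sum(areas[keep]),
       mesh = structure(list(vertices = p, triangles = tri),
                        class = "LeafMesh"))
}

#' Extract all phenotype parameters from an instance-labelled plant
#'
#' Plant height over the full cloud, and per leaf instance the PCA length,
#' width, and ball-pivoting surface area. The cloud must be in metric
#' (denormalized) coordinates.
#'
#' @param cloud a [PointCloud-class] with semantic labels and instance ids
#'   (leaf instances > 0, e.g. from [kmeansLeafInstances()]).
#' @param leafLabel semantic label treated as leaf.
#' @param radii optional BPA radii forwarded to [bpaLeafArea()].
#' @return list with `height` and `leaves` (data.frame: instance, n, length,
#'   width, area).
#' @export
extractPhenotypes <- function(cloud, leafLabel = 0L, radii = NULL) {
  stopIfNot(is(cloud, "PointCloud"), "cloud must be a PointCloud")
  labs <- semanticLabels(cloud)
  ids <- instanceIds(cloud)
  stopIfNot(!is.null(labs) && !is.null(ids),
            "cloud must carry semantic labels and instance ids")
  height <- plantHeight(cloud)
  leafIds <- sort(unique(ids[labs == leafLabel & ids >= 0L]))
  rows <- lapply(leafIds, function(li) {
    pts <- cloud@points[ids == li & labs == leafLabel, , drop = FALSE]
    if (nrow(pts) < 10L) return(NULL)
    lw <- leafLengthWidth(pts)
    area <- tryCatch(bpaLeafArea(pts, radii)$area, error = function(e) NA_real_)
    data.frame(instance = li, n = nrow(pts), length = lw[["length"]],
               width = lw[["width"]], area = area)
  })
  leaves <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  list(height = height, leaves = leaves)
}
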