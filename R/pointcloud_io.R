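#' Read a labelled point cloud from ShapeNet-Part-style text
#'
#' Each non-empty line holds at least four whitespace-separated numeric
#' fields `x y z label`; any extra per-line fields are ignored, except that a
#' fifth numeric field, when present on every line, is read as the instance
#' id (the same convention [writeLabeledTxt()] uses to export instance
#' segmentations).
#'
#' @param path path to an existing text file.
#' @return A [PointCloud-class] with `semanticLabels` populated.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("0 0 0 1", "0 0 2 0"), f)
#' readLabeledTxt(f)
#' @export
readLabeledTxt <- function(path) {
  stopIfNot(file.exists(path), sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineNo <- which(keep)
  if (!length(lines)) stop("empty point cloud file: ", path, call. = FALSE)
  fields <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(fields)
  bad <- which(nf < 4L)
  if (length(bad))
    stop(sprintf("parse error at line %d of %s: expected at least 4 fields",
                 lineNo[bad[1L]], path), call. = FALSE)
  nUse <- if (all(nf >= 5L)) 5L else 4L
  vals <- vapply(fields, function(f) as.numeric(f[seq_len(nUse)]), numeric(nUse))
  if (anyNA(vals)) {
    badLine <- which(apply(is.na(vals), 2L, any))[1L]
    stop(sprintf("parse error at line %d of %s: non-numeric field",
                 lineNo[badLine], path), call. = FALSE)
  }
  vals <- t(vals)
  pointCloud(vals[, 1:3, drop = FALSE],
    semanticLabels = as.integer(vals[, 4L]),
    instanceIds = if (nUse == 5L) as.integer(vals[, 5L]) else NULL
  )
}

#' Write a labelled point cloud as ShapeNet-Part-style text
#'
#' One line per point, `x y z label` at full float precision; when instance
#' ids are present a fifth column carries them.
#'
#' @param cloud a [PointCloud-class] with semantic labels present.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeLabeledTxt <- function(cloud, path) {
  stopIfNot(is(cloud, "PointCloud"), "cloud must be a PointCloud")
  stopIfNot(length(cloud@semanticLabels) > 0L,
            "cannot write a cloud without semantic labels")
  p <- cloud@points
  cols <- list(
    format(p[, 1L], digits = 17, trim = TRUE, scientific = FALSE),
    format(p[, 2L], digits = 17, trim = TRUE, scientific = FALSE),
    format(p[, 3L], digits = 17, trim = TRUE, scientific = FALSE),
    cloud@semanticLabels
  )
  if (length(cloud@instanceIds)) cols <- c(cols, list(cloud@instanceIds))
  out <- do.call(paste, cols)
  ok <- tryCatch({
    writeLines(out, path)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write to ", path, call. = FALSE)
  invisible(path)
}

#' Radius outlier removal
#'
#' Retains exactly the points having at least `minNeighbors` *other* points
#' within distance `radius`; label arrays are filtered consistently. The
#' defaults tie the radius to twice the mean nearest-neighbour distance of
#' the cloud, a scale-free choice that adapts to sampling density.
#'
#' @param cloud a [PointCloud-class].
#' @param radius positive search radius; default `2 *` mean NN distance.
#' @param minNeighbors minimum neighbour count (>= 1) required to keep a point.
#' @return the filtered [PointCloud-class].
#' @export
radiusOutlierRemoval <- function(cloud, radius = NULL, minNeighbors = 4L) {
  stopIfNot(is(cloud, "PointCloud"), "cloud must be a PointCloud")
  p <- cloud@points
  if (is.null(radius)) radius <- 2 * meanNNDistance(p)
  stopIfNot(is.finite(radius) && radius > 0, "radius must be positive")
  minNeighbors <- as.integer(minNeighbors)
  stopIfNot(minNeighbors >= 1L, "minNeighbors must be at least 1")
  n <- nrow(p)
  counts <- integer(n)
  # count neighbours in blocks to bound memory on large clouds
  block <- max(1L, min(n, as.integer(2e7 / n)))
  r2 <- radius^2
  for (s in seq(1L, n, by = block)) {
    e <- min(n, s + block - 1L)
    d2 <- crossdist2(p[s:e, , drop = FALSE], p)
    counts[s:e] <- rowSums(d2 <= r2) - 1L  # minus self
  }
  keep <- counts >= minNeighbors
  if (!any(keep))
    stop("radius outlier removal discarded every point; ",
         "increase radius or lower minNeighbors", call. = FALSE)
  cloud[keep]
}

#' Seeded uniform downsampling to an exact point count
#'
#' If the cloud has at least `targetN` points, draws a uniform sample without
#' replacement of exactly `targetN`; smaller clouds are upsampled with
#' replacement. Labels are carried along. The draw is deterministic given
#' `seed`.
#'
#' @param cloud a [PointCloud-class].
#' @param targetN number of points to keep (the pipeline default is 4096).
#' @param seed integer seed for the draw.
#' @return the resampled [PointCloud-class].
#' @export
uniformDownsample <- function(cloud, targetN = 4096L, seed = 0L) {
  stopIfNot(is(cloud, "PointCloud"), "cloud must be a PointCloud")
  targetN <- as.integer(targetN)
  stopIfNot(targetN >= 1L, "targetN must be at least 1")
  n <- npoints(cloud)
  idx <- withSeed(seed, {
    if (n >= targetN) sample.int(n, targetN, replace = FALSE)
    else sample.int(n, targetN, replace = TRUE)
  })
  cloud[idx]
}

#' Normalize a cloud to the unit ball, recording the inverse transform
#'
#' Centres on the coordinate-wise mean and divides by the maximum point
#' distance from the centroid, so every coordinate lands in `[-1, 1]`. The
#' returned transform restores metric coordinates via [denormalizePoints()].
#'
#' @param cloud a [PointCloud-class], not already normalized.
#' @return list with elements `cloud` (normalized [PointCloud-class]) and
#'   `transform` (a [NormalizationTransform-class]).
#' @examples
#' pc <- pointCloud(rbind(c(0, 0, 0), c(0, 0, 2)))
#' nrm <- normalizePoints(pc)
#' coords(nrm$cloud)   # (0,0,-1) and (0,0,1)
#' @export
normalizePoints <- function(cloud) {
  stopIfNot(is(cloud, "PointCloud"), "cloud must be a PointCloud")
  stopIfNot(!cloud@normalized, "cloud is already normalized")
  p <- cloud@points
  centroid <- colMeans(p)
  centred <- sweep(p, 2L, centroid)
  scale <- max(rowNorms(centred))
  if (scale <= 0)
    stop("all points coincide; normalization scale is zero", call. = FALSE)
  out <- cloud
  out@points <- centred / scale
  out@normalized <- TRUE
  validObject(out)
  list(
    cloud = out,
    transform = new("NormalizationTransform", centroid = as.numeric(centroid),
                    scale = scale)
  )
}

#' Invert unit-ball normalization
#'
#' @param cloud a normalized [PointCloud-class].
#' @param transform the [NormalizationTransform-class] recorded by
#'   [normalizePoints()].
#' @return the metric-space [PointCloud-class] (normalized flag cleared).
#' @export
denormalizePoints <- function(cloud, transform) {
  stopIfNot(is(cloud, "PointCloud"), "cloud must be a PointCloud")
  stopIfNot(is(transform, "NormalizationTransform"),
            "transform must be a NormalizationTransform")
  stopIfNot(cloud@normalized, "cloud is not normalized")
  out <- cloud
  out@normalized <- FALSE
  out@points <- sweep(cloud@points * transform@scale, 2L, -transform@centroid)
  validObject(out)
  out
}
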