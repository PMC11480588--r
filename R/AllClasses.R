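#' PointCloud: coordinates with optional semantic and instance labels
#'
#' The pipeline's universal currency. Holds an N x 3 coordinate matrix
#' (centimetres in raw space, dimensionless after [normalizePoints()]),
#' optional per-point semantic labels (0 = leaf, 1 = stem for the stem-leaf
#' task) and optional per-point instance ids (-1 = unassigned).
#'
#' @slot points numeric N x 3 matrix of coordinates.
#' @slot semanticLabels integer vector of length N, or `integer(0)` if absent.
#' @slot instanceIds integer vector of length N, or `integer(0)` if absent.
#' @slot normalized logical flag; `TRUE` after unit-ball normalization, in
#'   which case every coordinate lies in `[-1, 1]`.
#'
#' @seealso [pointCloud()], [normalizePoints()], [readLabeledTxt()]
#' @export
setClass("PointCloud",
  representation(
    points = "matrix",
    semanticLabels = "integer",
    instanceIds = "integer",
    normalized = "logical"
  ),
  prototype(
    semanticLabels = integer(0),
    instanceIds = integer(0),
    normalized = FALSE
  )
)

setValidity("PointCloud", function(object) {
  p <- object@points
  n <- nrow(p)
  if (is.null(n) || n < 1L) return("point cloud must contain at least one point")
  if (ncol(p) != 3L) return("points must be an N x 3 matrix")
  if (!all(is.finite(p))) return("all coordinates must be finite")
  if (length(object@semanticLabels) && length(object@semanticLabels) != n)
    return("semanticLabels length must equal the number of points")
  if (length(object@instanceIds) && length(object@instanceIds) != n)
    return("instanceIds length must equal the number of points")
  if (length(object@normalized) != 1L) return("normalized must be a single flag")
  if (object@normalized && any(abs(p) > 1 + 1e-9))
    return("normalized cloud has coordinates outside [-1, 1]")
  TRUE
})

#' Construct a PointCloud
#'
#' @param points numeric N x 3 matrix (or something coercible to one).
#' @param semanticLabels optional integer vector of per-point class labels.
#' @param instanceIds optional integer vector of per-point instance ids.
#' @param normalized logical; set by [normalizePoints()], rarely by hand.
#' @return A [PointCloud-class] object.
#' @examples
#' pc <- pointCloud(rbind(c(0, 0, 0), c(0, 0, 2)), semanticLabels = c(1L, 0L))
#' npoints(pc)
#' @export
pointCloud <- function(points, semanticLabels = NULL, instanceIds = NULL,
                       normalized = FALSE) {
  points <- as.matrix(points)
  storage.mode(points) <- "double"
  dimnames(points) <- NULL
  new("PointCloud",
    points = points,
    semanticLabels = if (is.null(semanticLabels)) integer(0) else as.integer(semanticLabels),
    instanceIds = if (is.null(instanceIds)) integer(0) else as.integer(instanceIds),
    normalized = normalized
  )
}

#' @describeIn PointCloud-class number of points
#' @param object,x a `PointCloud`
#' @export
setGeneric("npoints", function(x) standardGeneric("npoints"))

#' @rdname PointCloud-class
#' @export
setMethod("npoints", "PointCloud", function(x) nrow(x@points))

#' @describeIn PointCloud-class coordinate matrix accessor
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))

#' @rdname PointCloud-class
#' @export
setMethod("coords", "PointCloud", function(x) x@points)

#' @describeIn PointCloud-class semantic label accessor (NULL if absent)
#' @export
setGeneric("semanticLabels", function(x) standardGeneric("semanticLabels"))

#' @rdname PointCloud-class
#' @export
setMethod("semanticLabels", "PointCloud", function(x)
  if (length(x@semanticLabels)) x@semanticLabels else NULL)

#' @describeIn PointCloud-class replace semantic labels
#' @param value replacement labels / ids
#' @export
setGeneric("semanticLabels<-", function(x, value) standardGeneric("semanticLabels<-"))

#' @rdname PointCloud-class
#' @export
setMethod("semanticLabels<-", "PointCloud", function(x, value) {
  x@semanticLabels <- if (is.null(value)) integer(0) else as.integer(value)
  validObject(x)
  x
})

#' @describeIn PointCloud-class instance id accessor (NULL if absent)
#' @export
setGeneric("instanceIds", function(x) standardGeneric("instanceIds"))

#' @rdname PointCloud-class
#' @export
setMethod("instanceIds", "PointCloud", function(x)
  if (length(x@instanceIds)) x@instanceIds else NULL)

#' @describeIn PointCloud-class replace instance ids
#' @export
setGeneric("instanceIds<-", function(x, value) standardGeneric("instanceIds<-"))

#' @rdname PointCloud-class
#' @export
setMethod("instanceIds<-", "PointCloud", function(x, value) {
  x@instanceIds <- if (is.null(value)) integer(0) else as.integer(value)
  validObject(x)
  x
})

#' @describeIn PointCloud-class is the cloud unit-ball normalized?
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname PointCloud-class
#' @export
setMethod("isNormalized", "PointCloud", function(x) x@normalized)

setMethod("show", "PointCloud", function(object) {
  cat(sprintf(
    "PointCloud: %d points%s%s%s\n",
    npoints(object),
    if (object@normalized) " (normalized)" else "",
    if (length(object@semanticLabels))
      sprintf(", %d semantic classes", length(unique(object@semanticLabels))) else "",
    if (length(object@instanceIds))
      sprintf(", %d instances", length(unique(object@instanceIds))) else ""
  ))
  rng <- apply(object@points, 2, range)
  cat(sprintf(
    "  extent: x [%.3g, %.3g]  y [%.3g, %.3g]  z [%.3g, %.3g]\n",
    rng[1, 1], rng[2, 1], rng[1, 2], rng[2, 2], rng[1, 3], rng[2, 3]
  ))
})

#' Subset a point cloud by point index
#'
#' @param x a `PointCloud`
#' @param i integer or logical index over points
#' @param j,...,drop ignored
#' @return the subsetted `PointCloud` with labels filtered consistently
#' @export
setMethod("[", "PointCloud", function(x, i, j, ..., drop = FALSE) {
  new("PointCloud",
    points = x@points[i, , drop = FALSE],
    semanticLabels = if (length(x@semanticLabels)) x@semanticLabels[i] else integer(0),
    instanceIds = if (length(x@instanceIds)) x@instanceIds[i] else integer(0),
    normalized = x@normalized
  )
})

#' NormalizationTransform: recorded centroid/scale of unit-ball normalization
#'
#' @slot centroid numeric length-3 coordinate-wise mean of the raw cloud (cm).
#' @slot scale positive real; the maximum point distance from the centroid (cm).
#' @seealso [normalizePoints()], [denormalizePoints()]
#' @export
setClass("NormalizationTransform",
  representation(centroid = "numeric", scale = "numeric")
)

setValidity("NormalizationTransform", function(object) {
  if (length(object@centroid) != 3L) return("centroid must have length 3")
  if (length(object@scale) != 1L || !is.finite(object@scale) || object@scale <= 0)
    return("scale must be a single positive number")
  TRUE
})

setMethod("show", "NormalizationTransform", function(object) {
  cat(sprintf(
    "NormalizationTransform: centroid (%.4g, %.4g, %.4g), scale %.4g\n",
    object@centroid[1], object@centroid[2], object@centroid[3], object@scale
  ))
})

#' SegMetrics: per-class confusion counts and derived segmentation measures
#'
#' One-vs-rest confusion counts per semantic class together with the derived
#' intersection-over-union, precision, recall and F1 per class, plus the
#' aggregate mean IoU and overall accuracy.
#'
#' @slot counts integer matrix `numClasses x 4` with columns TP, FP, TN, FN.
#' @slot n total number of points.
#' @slot vacuous how classes absent from both prediction and truth enter the
#'   mean IoU: `"one"` scores them 1 (default), `"skip"` drops them.
#' @seealso [confusionCounts()]
#' @export
setClass("SegMetrics",
  representation(counts = "matrix", n = "integer", vacuous = "character"),
  prototype(vacuous = "one")
)

setValidity("SegMetrics", function(object) {
  cn <- object@counts
  if (ncol(cn) != 4L) return("counts must have columns TP, FP, TN, FN")
  if (any(cn < 0)) return("confusion counts must be non-negative")
  if (any(rowSums(cn) != object@n)) return("TP+FP+TN+FN must equal n for every class")
  if (!object@vacuous %in% c("one", "skip")) return("vacuous must be 'one' or 'skip'")
  TRUE
})
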