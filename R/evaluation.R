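#' Per-class confusion counts and segmentation metrics
#'
#' One-vs-rest TP/FP/TN/FN per class, from which IoU, precision, recall and
#' F1 follow per class, the mean IoU as their unweighted class average, and
#' the overall accuracy as the global fraction of correctly labelled points.
#'
#' @param pred integer vector of predicted labels in `[0, numClasses)`.
#' @param truth integer vector of true labels, same length.
#' @param numClasses number of semantic classes.
#' @param vacuous scoring of classes absent from both prediction and truth:
#'   `"one"` (IoU 1, default) or `"skip"` (dropped from the mean IoU).
#' @return a [SegMetrics-class].
#' @examples
#' m <- confusionCounts(c(0L, 0L, 1L), c(0L, 1L, 1L), 2L)
#' segMIoU(m); segOA(m)
#' @export
confusionCounts <- function(pred, truth, numClasses, vacuous = c("one", "skip")) {
  vacuous <- match.arg(vacuous)
  pred <- as.integer(pred)
  truth <- as.integer(truth)
  if (length(pred) != length(truth))
    stop("pred and truth must have equal length", call. = FALSE)
  stopIfNot(all(pred >= 0L & pred < numClasses), "pred labels out of range")
  stopIfNot(all(truth >= 0L & truth < numClasses), "truth labels out of range")
  n <- length(pred)
  counts <- t(vapply(seq_len(numClasses) - 1L, function(q) {
    tp <- sum(pred == q & truth == q)
    fp <- sum(pred == q & truth != q)
    fn <- sum(pred != q & truth == q)
    c(TP = tp, FP = fp, TN = n - tp - fp - fn, FN = fn)
  }, integer(4)))
  new("SegMetrics", counts = counts, n = n, vacuous = vacuous)
}

segRatio <- function(num, den) ifelse(den == 0, 1, num / den)

#' @describeIn confusionCounts per-class intersection-over-union
#'   `TP / (TP + FP + FN)` (1 for vacuous classes)
#' @param x a `SegMetrics`
#' @export
segIoU <- function(x) {
  cn <- x@counts
  segRatio(cn[, "TP"], cn[, "TP"] + cn[, "FP"] + cn[, "FN"])
}

#' @describeIn confusionCounts per-class precision `TP / (TP + FP)`
#' @export
segPrecision <- function(x) {
  cn <- x@counts
  segRatio(cn[, "TP"], cn[, "TP"] + cn[, "FP"])
}

#' @describeIn confusionCounts per-class recall `TP / (TP + FN)`
#' @export
segRecall <- function(x) {
  cn <- x@counts
  segRatio(cn[, "TP"], cn[, "TP"] + cn[, "FN"])
}

#' @describeIn confusionCounts per-class F1, the harmonic mean of precision
#'   and recall
#' @export
segF1 <- function(x) {
  p <- segPrecision(x)
  r <- segRecall(x)
  ifelse(p + r == 0, 0, 2 * p * r / (p + r))
}

#' @describeIn confusionCounts mean IoU over classes (vacuous classes scored
#'   per the `vacuous` policy)
#' @export
segMIoU <- function(x) {
  iou <- segIoU(x)
  if (x@vacuous == "skip") {
    cn <- x@counts
    present <- (cn[, "TP"] + cn[, "FP"] + cn[, "FN"]) > 0
    if (!any(present)) return(1)
    return(mean(iou[present]))
  }
  mean(iou)
}

#' @describeIn confusionCounts global overall accuracy, computed once as
#'   correct / n
#' @export
segOA <- function(x) {
  cn <- x@counts
  sum(cn[, "TP"]) / x@n
}

setMethod("show", "SegMetrics", function(object) {
  df <- as.data.frame(object)
  cat(sprintf("SegMetrics over %d points, %d classes\n",
              object@n, nrow(object@counts)))
  print(df, row.names = FALSE, digits = 4)
  cat(sprintf("mIoU %.4f   OA %.4f\n", segMIoU(object), segOA(object)))
})

#' @describeIn confusionCounts per-class metric table
#' @param row.names,optional,... ignored (S3 compatibility)
#' @export
as.data.frame.SegMetrics <- function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    class = seq_len(nrow(x@counts)) - 1L,
    TP = x@counts[, "TP"], FP = x@counts[, "FP"],
    TN = x@counts[, "TN"], FN = x@counts[, "FN"],
    IoU = segIoU(x), precision = segPrecision(x),
    recall = segRecall(x), F1 = segF1(x)
  )
}

#' Agreement between estimated and reference phenotype values
#'
#' `R^2 = 1 - sum((est - ref)^2) / sum((ref - mean(ref))^2)` and
#' `RMSE = sqrt(mean((est - ref)^2))`, in the units of the input.
#'
#' @param estimated numeric vector of estimated values.
#' @param reference numeric vector of reference (measured) values.
#' @return list with `r2` and `rmse`.
#' @examples
#' regressionMetrics(c(2, 3, 4), c(1, 2, 3))  # rmse 1, r2 -0.5
#' @export
regressionMetrics <- function(estimated, reference) {
  stopIfNot(length(estimated) == length(reference),
            "estimated and reference must have equal length")
  stopIfNot(length(reference) >= 2L, "at least two pairs are required")
  ssTot <- sum((reference - mean(reference))^2)
  if (ssTot <= 0)
    stop("reference values have zero variance; R^2 undefined", call. = FALSE)
  ssRes <- sum((estimated - reference)^2)
  list(r2 = 1 - ssRes / ssTot, rmse = sqrt(mean((estimated - reference)^2)))
}
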