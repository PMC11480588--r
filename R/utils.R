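# internal helpers shared across modules

# Run `expr` under a local RNG state seeded with `seed`, restoring the
# caller's state afterwards so library calls never perturb user RNG streams.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# derive a child seed from a base seed and a stream tag, staying within
# 32-bit integer range
childSeed <- function(seed, tag) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(tag) * 104729) %% 2147483587)
}

stopIfNot <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

rowNorms <- function(m) sqrt(rowSums(m * m))

# pairwise squared distances between rows of a and rows of b
crossdist2 <- function(a, b) {
  an <- rowSums(a * a)
  bn <- rowSums(b * b)
  d2 <- outer(an, bn, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  d2
}

# mean nearest-neighbour distance, the length scale several defaults hang off
meanNNDistance <- function(points) {
  n <- nrow(points)
  if (n < 2L) return(0)
  idx <- .knn_cpp(points, 1L)
  mean(sqrt(rowSums((points - points[idx[, 1L], , drop = FALSE])^2)))
}
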