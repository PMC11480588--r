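# shared fixtures: everything is generated in code, seeded for determinism

randomCloud <- function(n, seed = 1, labels = TRUE) {
  set.seed(seed)
  pointCloud(matrix(runif(n * 3, -1, 1), n, 3),
             semanticLabels = if (labels) sample(0:1, n, replace = TRUE))
}

# tiny architecture used by network unit tests (fast on one CPU)
tinyConfig <- function(K = 4L, ...) {
  ggeConfig(K = K, stageDims = c(4L, 4L, 4L, 4L, 4L), hgsLayers = 1L,
            hgsHeads = 2L, headDims = c(8L, 6L), ...)
}

tinyNormalizedCloud <- function(n = 160, seed = 1) {
  set.seed(seed)
  pointCloud(matrix(runif(n * 3, -1, 1), n, 3),
             semanticLabels = sample(0:1, n, replace = TRUE),
             normalized = TRUE)
}

# brute-force exact KNN oracle (distance sort, ties by lower index)
bruteKnn <- function(p, K) {
  n <- nrow(p)
  d <- as.matrix(dist(p))
  rows <- lapply(seq_len(n), function(i) {
    o <- order(d[i, -i], seq_len(n)[-i])[seq_len(K)]
    seq_len(n)[-i][o]
  })
  matrix(unlist(rows), nrow = n, byrow = TRUE)
}

# access to internal helpers under test
pps <- asNamespace("PlantPointSeg")
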