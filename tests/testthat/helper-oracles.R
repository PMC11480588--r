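# independent oracles used by both the unit and acceptance suites; all are
# naive loop/closed-form implementations kept separate from the package code

# loop-based adaptive-kernel response: h_ij[m] = LeakyReLU(<dx_ij, g_m(df_ij)>)
kernelOracle <- function(enc, params, slope = 0.2) {
  lr <- function(x) ifelse(x > 0, x, slope * x)
  M <- params$M
  out <- matrix(NA_real_, nrow(enc$spatial), M)
  for (r in seq_len(nrow(enc$spatial))) {
    hid <- lr(as.numeric(enc$feature[r, ] %*% params$kW1) + params$kb1)
    gAll <- as.numeric(hid %*% params$kW2) + params$kb2
    for (m in seq_len(M)) {
      gm <- gAll[((m - 1) * 6 + 1):(m * 6)]
      out[r, m] <- lr(sum(enc$spatial[r, ] * gm))
    }
  }
  out
}

# closed-form channel-wise softmax pooling over each point's K neighbours
poolOracle <- function(h, K) {
  N <- nrow(h) / K
  rows <- lapply(seq_len(N), function(i) {
    blk <- ((i - 1) * K + 1):(i * K)
    sapply(seq_len(ncol(h)), function(m) {
      w <- exp(h[blk, m] - max(h[blk, m]))
      w <- w / sum(w)
      sum(w * h[blk, m])
    })
  })
  matrix(unlist(rows), nrow = N, byrow = TRUE)
}

# explicit single-head scaled dot-product attention
attOracle <- function(q, Kmat, Vmat) {
  s <- as.numeric(Kmat %*% q) / sqrt(length(q))
  w <- exp(s - max(s)); w <- w / sum(w)
  as.numeric(t(Vmat) %*% w)
}

lnOracle <- function(x, eps = 1e-5) {
  mu <- mean(x)
  (x - mu) / sqrt(mean((x - mu)^2) + eps)
}

# kernel-generator parameters that emit one constant kernel
constKernelParams <- function(kernel, M = 1L, inputDim = 2L) {
  p <- adaptiveKernelParams(inputDim, M, seed = 1)
  p$kW1[] <- 0; p$kb1[] <- 0
  p$kW2[] <- 0; p$kb2 <- kernel
  p$postW <- diag(M); p$postb[] <- 0
  p
}

makeBlobs <- function(centers, nPer = 60, sd = 0.2, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i)
    sweep(matrix(rnorm(nPer * 3, sd = sd), nPer, 3), 2, -centers[i, ])))
}

# separated-leaf study conditions used by the clustering/phenotype checks;
# phenotyping runs at restored full sampling density (~12k points/plant)
separatedPlantSpec <- function(seed, stemHeight = 40, noise = 0.05,
                               pointsTotal = 4096L) {
  syntheticPlantSpec(seed = seed, stemHeight = stemHeight,
                     leafLengthRange = c(3, 5), nLeaves = 6L,
                     surfaceNoiseSd = noise, pointsTotal = pointsTotal)
}
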