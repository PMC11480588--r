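test_that("kd-tree KNN matches brute force and the collinear hand case", {
  z <- cbind(0, 0, c(0, 1, 3, 7))
  g <- kdtreeKnn(z, 1L)
  expect_equal(as.vector(g$neighborIndices), c(2L, 1L, 2L, 3L))

  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  g2 <- kdtreeKnn(tri, 2L)
  for (i in 1:3) expect_setequal(g2$neighborIndices[i, ], setdiff(1:3, i))

  expect_error(kdtreeKnn(tri, 3L), "smaller than")

  for (seed in 1:100) {
    set.seed(seed)
    n <- sample(5:64, 1)
    p <- matrix(runif(n * 3), n, 3)
    K <- sample.int(min(8L, n - 1L), 1)
    expect_equal(kdtreeKnn(p, K)$neighborIndices, bruteKnn(p, K),
                 info = sprintf("seed %d", seed))
  }
})

test_that("KNN breaks distance ties toward the lower index", {
  # 4 points at the corners of a square: two neighbours tie for each corner
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  g <- kdtreeKnn(sq, 2L)
  expect_equal(g$neighborIndices[1, ], c(2L, 3L))  # ties at distance 1
  expect_equal(g$neighborIndices[4, ], c(2L, 3L))
})

test_that("farthest point sampling selects greedy coverage subsets", {
  set.seed(3)
  p <- matrix(runif(4096 * 3), 4096, 3)
  idx <- farthestPointSampling(p, 4L, seed = 0)
  expect_length(idx, 1024L)
  expect_equal(farthestPointSampling(p, 1L), seq_len(4096))

  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0))
  picks <- farthestPointSampling(sq, 2L, seed = 0)
  # second pick is diagonal to the first
  expect_equal(sum(abs(sq[picks[1], ] - sq[picks[2], ])), 2)

  # greedy min-distance sequence is non-increasing
  set.seed(4)
  q <- matrix(runif(120 * 3), 120, 3)
  sel <- farthestPointSampling(q, 2L, seed = 0)
  minDists <- vapply(seq_along(sel)[-1], function(k) {
    d2 <- pps$crossdist2(q[sel[k], , drop = FALSE], q[sel[seq_len(k - 1)], , drop = FALSE])
    sqrt(min(d2))
  }, numeric(1))
  expect_true(all(diff(minDists) <= 1e-12))
  # deterministic given seed
  expect_identical(farthestPointSampling(q, 3L, seed = 5),
                   farthestPointSampling(q, 3L, seed = 5))
})

test_that("edge encodings concatenate centre and difference parts", {
  p <- rbind(c(0, 0, 0), c(1, 2, 3), c(-1, 0, 1))
  f <- rbind(c(1, 1), c(2, 0), c(1, 1))
  g <- kdtreeKnn(p, 1L)
  enc <- edgeEncode(p, f, g)
  expect_equal(dim(enc$spatial), c(3L, 6L))
  row1 <- enc$spatial[1, ]
  nb1 <- g$neighborIndices[1, 1]
  expect_equal(row1, c(0, 0, 0, p[nb1, ]))
  # f_i = f_j gives a zero difference part
  enc2 <- edgeEncode(p, rbind(c(1, 1), c(1, 1), c(1, 1)), g)
  expect_true(all(enc2$feature[, 3:4] == 0))
  # antisymmetry: the difference part negates when i and j swap roles
  j <- g$neighborIndices[1, 1]
  expect_equal(enc$feature[1, 3:4], f[j, ] - f[1, ])
  expect_equal(-enc$feature[1, 3:4], f[1, ] - f[j, ])
  expect_error(edgeEncode(p, f[1:2, ], g), "match")
})

test_that("neighbourhood max pooling equals the brute-force per-channel max", {
  set.seed(8)
  p <- matrix(runif(16 * 3), 16, 3)
  feats <- matrix(rnorm(16 * 5), 16, 5)
  g <- kdtreeKnn(p, 4L)
  sampled <- c(2L, 7L, 11L)
  pooled <- neighborhoodMaxPool(feats, g, sampled)
  oracle <- t(vapply(sampled, function(s) {
    rows <- c(s, g$neighborIndices[s, ])
    apply(feats[rows, , drop = FALSE], 2, max)
  }, numeric(5)))
  expect_equal(pooled, oracle)
  # constants and spikes propagate
  const <- neighborhoodMaxPool(matrix(1, 16, 2), g, sampled)
  expect_true(all(const == 1))
  spike <- matrix(0, 16, 1)
  spike[g$neighborIndices[2, 1], 1] <- 5
  expect_equal(neighborhoodMaxPool(spike, g, 2L)[1, 1], 5)
  # invariant under permutation of neighbour order
  g2 <- g
  g2$neighborIndices <- g$neighborIndices[, 4:1]
  expect_equal(neighborhoodMaxPool(feats, g2, sampled), pooled)
})

test_that("inverse-distance interpolation respects limits and constants", {
  coarse <- rbind(c(0, 0, 0), c(1, 0, 0), c(10, 10, 10))
  cf <- rbind(c(1, 2), c(3, 4), c(100, 100))
  # coincident fine point copies the coarse feature
  out <- idwInterpolate(coarse, cf, rbind(c(1, 0, 0)))
  expect_equal(as.vector(out), c(3, 4), tolerance = 1e-6)
  # equidistant between two near coarse points, third far: ~midpoint
  mid <- idwInterpolate(coarse, cf, rbind(c(0.5, 0, 0)))
  w <- c(1 / 0.5, 1 / 0.5, 1 / sqrt(sum((c(0.5, 0, 0) - c(10, 10, 10))^2)))
  w <- w / sum(w)
  expect_equal(as.vector(mid), as.vector(w %*% cf), tolerance = 1e-6)
  # constants preserved, permutation invariance of the coarse set
  set.seed(5)
  cp <- matrix(runif(30), 10, 3)
  fp <- matrix(runif(21), 7, 3)
  expect_equal(idwInterpolate(cp, matrix(2, 10, 3), fp), matrix(2, 7, 3),
               tolerance = 1e-9)
  perm <- sample(10)
  f2 <- matrix(rnorm(30), 10, 3)
  expect_equal(idwInterpolate(cp[perm, ], f2[perm, ], fp),
               idwInterpolate(cp, f2, fp), tolerance = 1e-9)
})
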