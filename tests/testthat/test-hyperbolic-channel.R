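test_that("Poincare maps are mutually inverse and ball-contained", {
  expect_equal(expmap0(c(0, 0, 0), 1), c(0, 0, 0))
  expect_equal(expmap0(c(1, 0, 0), 1), c(tanh(1), 0, 0), tolerance = 1e-9)
  expect_equal(logmap0(c(tanh(1), 0, 0), 1), c(1, 0, 0), tolerance = 1e-6)
  expect_equal(logmap0(c(0, 0), 2), c(0, 0))

  set.seed(2)
  for (c0 in c(0.5, 1, 2)) {
    # inverse identity at scales where artanh is numerically meaningful
    f <- matrix(rnorm(600), 200, 3) * rep(10^runif(200, -2, 0.2), 3)
    h <- expmap0(f, c0)
    expect_true(all(sqrt(c0) * sqrt(rowSums(h^2)) < 1))
    expect_equal(logmap0(h, c0), f, tolerance = 1e-6)
    # strict containment even at extreme norms (tanh saturation clamped)
    big <- matrix(rnorm(300), 100, 3) * rep(10^runif(100, 0, 3), 3)
    expect_true(all(sqrt(c0) * sqrt(rowSums(expmap0(big, c0)^2)) < 1))
  }
  # norm monotone
  n1 <- sqrt(sum(expmap0(c(0.3, 0, 0), 1)^2))
  n2 <- sqrt(sum(expmap0(c(0.6, 0, 0), 1)^2))
  expect_lt(n1, n2)
  expect_error(logmap0(c(1.2, 0, 0), 1), "ball")
  expect_error(expmap0(c(NA, 0, 0), 1), "finite")
})

test_that("star graphs keep ring edges with the requested probability", {
  set.seed(5)
  p <- matrix(runif(30), 10, 3)
  g <- kdtreeKnn(p, 4L)
  full <- buildStarGraph(g, 1L, edgeProb = 1)
  expect_equal(full$ring, g$neighborIndices[1, ])
  expect_true(all(full$ringEdges))
  none <- buildStarGraph(g, 2L, edgeProb = 0, seed = 1)
  expect_false(any(none$ringEdges))
  # seeded Monte-Carlo retention frequency at p = 0.5
  draws <- vapply(seq_len(2500), function(s)
    sum(buildStarGraph(g, 1L, edgeProb = 0.5, seed = s)$ringEdges), numeric(1))
  expect_equal(mean(draws) / 4, 0.5, tolerance = 0.02)
  expect_error(buildStarGraph(g, 1L, edgeProb = 1.4), "0, 1")
})

test_that("an HGS layer matches the explicit attention oracle", {
  K <- 3; M <- 4
  set.seed(7)
  ring <- matrix(rnorm(K * M, sd = 0.3), K, M)
  planet <- rnorm(M, sd = 0.3)
  params <- hgsParams(M, heads = 1L, L = 1L, seed = 3)
  star <- buildStarGraph(list(neighborIndices = matrix(1:K, 1)), 1L)
  state <- hgsState(ring, planet, heads = 1L)
  out <- hgsLayer(state, star, params, 1L)

  lp <- params$layers[[1]]
  ringNew <- matrix(NA_real_, K, M)
  for (k in seq_len(K)) {
    ctx <- rbind(ring[ifelse(k == 1, K, k - 1), ], ring[k, ],
                 ring[ifelse(k == K, 1, k + 1), ], planet)
    att <- attOracle(as.numeric(ring[k, ] %*% lp$ring$Wq),
                     ctx %*% lp$ring$Wk, ctx %*% lp$ring$Wv)
    ringNew[k, ] <- lnOracle(pmax(as.numeric(att %*% lp$ring$Wo), 0))
  }
  expect_equal(out$ring, ringNew, tolerance = 1e-8)

  ctx2 <- rbind(planet, ringNew)
  att2 <- attOracle(as.numeric(planet %*% lp$planet$Wq),
                    ctx2 %*% lp$planet$Wk, ctx2 %*% lp$planet$Wv)
  planetNew <- lnOracle(pmax(as.numeric(att2 %*% lp$planet$Wo), 0))
  expect_equal(out$planet, planetNew, tolerance = 1e-8)
})

test_that("all-zero embeddings stay finite and deterministic", {
  K <- 4; M <- 4
  params <- hgsParams(M, heads = 2L, L = 1L, seed = 1)
  star <- buildStarGraph(list(neighborIndices = matrix(1:K, 1)), 1L)
  st <- hgsState(matrix(0, K, M), rep(0, M), heads = 2L)
  out1 <- hgsLayer(st, star, params, 1L)
  out2 <- hgsLayer(st, star, params, 1L)
  expect_true(all(is.finite(out1$ring)) && all(is.finite(out1$planet)))
  expect_identical(out1, out2)
  expect_error(hgsLayer(hgsState(matrix(0, K, M), rep(0, M), heads = 4L),
                        star, params, 1L), "mismatch")
})

test_that("the planet embedding is invariant to cyclic ring relabelling", {
  for (K in 3:8) {
    set.seed(K)
    M <- 8
    ring <- matrix(rnorm(K * M, sd = 0.5), K, M)
    planet <- rnorm(M, sd = 0.5)
    params <- hgsParams(M, heads = 2L, L = 2L, seed = K)
    base <- hgsEncode(ring, planet, params, heads = 2L)
    for (s in seq_len(K - 1)) {
      shifted <- ring[c((s + 1):K, 1:s), , drop = FALSE]
      expect_equal(hgsEncode(shifted, planet, params, heads = 2L), base,
                   tolerance = 1e-8, info = sprintf("K=%d shift=%d", K, s))
    }
  }
})

test_that("hgsEncode residual behaves linearly in lambda", {
  K <- 4; M <- 4
  set.seed(9)
  ringT <- matrix(rnorm(K * M, sd = 0.4), K, M)
  ring <- expmap0(ringT, 1)
  planet <- expmap0(rnorm(M, sd = 0.2), 1)
  params <- hgsParams(M, heads = 2L, L = 1L, seed = 2)

  off <- hgsEncode(ring, planet, params, lambda = 0)
  expect_equal(off, planet, tolerance = 1e-9)

  # L = 1 equals one manual layer application plus the residual
  star <- buildStarGraph(list(neighborIndices = matrix(1:K, 1)), 1L)
  manual <- hgsLayer(hgsState(ring, planet, heads = 2L), star, params, 1L)
  one <- hgsEncode(ring, planet, params, lambda = 0.1)
  expect_equal(one, as.numeric(pps$adBallProject(
    matrix(planet + 0.1 * manual$planet, 1), 1)), tolerance = 1e-9)

  # doubling lambda doubles the increment (away from the ball clamp)
  d1 <- hgsEncode(ring, planet, params, lambda = 0.01) - off
  d2 <- hgsEncode(ring, planet, params, lambda = 0.02) - off
  expect_equal(d2, 2 * d1, tolerance = 1e-9)
})

test_that("the batched channel is reproducible and respects edgeProb", {
  set.seed(10)
  n <- 30; K <- 5; D <- 3; M <- 8
  f <- matrix(rnorm(n * D), n, D)
  g <- kdtreeKnn(matrix(runif(n * 3), n, 3), K)
  par <- pps$hyperbolicChannelParams(D, M, heads = 2L, L = 2L, seed = 1)
  a <- pps$hyperbolicChannelForward(f, g$neighborIndices, par, 2L, 2L, 1, 1)
  b <- pps$hyperbolicChannelForward(f, g$neighborIndices, par, 2L, 2L, 1, 1)
  expect_identical(a, b)
  # dropping ring edges changes the output but stays finite
  c <- pps$hyperbolicChannelForward(f, g$neighborIndices, par, 2L, 2L, 1, 1,
                                    edgeProb = 0.5, seed = 4)
  expect_true(all(is.finite(c)))
  expect_false(isTRUE(all.equal(a, c)))
})
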