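test_that("labelled text files parse with labels and survive a round trip", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0 0 1", "0 0 2 0"), f)
  pc <- readLabeledTxt(f)
  expect_equal(npoints(pc), 2L)
  expect_equal(semanticLabels(pc), c(1L, 0L))
  expect_equal(coords(pc), rbind(c(0, 0, 0), c(0, 0, 2)))

  pc2 <- randomCloud(25, seed = 7)
  out <- withr::local_tempfile(fileext = ".txt")
  writeLabeledTxt(pc2, out)
  back <- readLabeledTxt(out)
  expect_equal(coords(back), coords(pc2), tolerance = 1e-6)
  expect_identical(semanticLabels(back), semanticLabels(pc2))
  expect_length(readLines(out), 25L)
})

test_that("instance ids round-trip through the fifth column", {
  pc <- randomCloud(10, seed = 3)
  instanceIds(pc) <- rep(c(0L, 1L), 5)
  f <- withr::local_tempfile(fileext = ".txt")
  writeLabeledTxt(pc, f)
  back <- readLabeledTxt(f)
  expect_identical(instanceIds(back), instanceIds(pc))
})

test_that("malformed and degenerate files raise informative errors", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines("a b c 0", f)
  expect_error(readLabeledTxt(f), "line 1")
  writeLines(character(0), f)
  expect_error(readLabeledTxt(f), "empty")
  writeLines("1 2 3", f)
  expect_error(readLabeledTxt(f), "4 fields")
  expect_error(readLabeledTxt(file.path(tempdir(), "nope.txt")), "not found")
  expect_error(writeLabeledTxt(pointCloud(diag(3)), tempfile()), "labels")
  expect_error(
    writeLabeledTxt(randomCloud(3), file.path(tempdir(), "no/such/dir/x.txt")),
    "cannot write")
})

test_that("radius outlier removal keeps exactly the well-supported points", {
  set.seed(11)
  dense <- matrix(rnorm(300, sd = 0.1), 100, 3)
  iso <- c(10, 10, 10)  # ~10x the search radius away
  pc <- pointCloud(rbind(dense, iso),
                   semanticLabels = c(rep(0L, 100), 1L))
  r <- 1
  out <- radiusOutlierRemoval(pc, radius = r, minNeighbors = 3L)
  # brute-force neighbour-count oracle
  d <- as.matrix(dist(coords(pc)))
  keepOracle <- (rowSums(d <= r) - 1L) >= 3L
  expect_equal(npoints(out), sum(keepOracle))
  expect_false(any(apply(coords(out), 1, function(x) all(x == iso))))
  expect_identical(semanticLabels(out), semanticLabels(pc)[keepOracle])
})

test_that("radius outlier removal edge semantics and properties hold", {
  pair <- pointCloud(rbind(c(0, 0, 0), c(0.1, 0, 0)))
  expect_error(radiusOutlierRemoval(pair, radius = 1, minNeighbors = 0L),
               "at least 1")
  expect_equal(npoints(radiusOutlierRemoval(pair, radius = 1, minNeighbors = 1L)), 2L)
  same <- pointCloud(matrix(1, 5, 3))
  expect_equal(npoints(radiusOutlierRemoval(same, radius = 0.5, minNeighbors = 4L)), 5L)
  # subset of input; idempotent on a dense core with isolated outliers
  set.seed(5)
  core <- matrix(rnorm(240, sd = 0.05), 80, 3)
  pc <- pointCloud(rbind(core, matrix(5, 2, 3) + diag(3)[1:2, ]))
  f1 <- radiusOutlierRemoval(pc, radius = 0.5, minNeighbors = 3L)
  f2 <- radiusOutlierRemoval(f1, radius = 0.5, minNeighbors = 3L)
  expect_true(all(coords(f1) %in% coords(pc)))
  expect_equal(coords(f2), coords(f1))
  lonely <- pointCloud(rbind(c(0, 0, 0), c(5, 5, 5)))
  expect_error(radiusOutlierRemoval(lonely, radius = 1, minNeighbors = 1L),
               "discarded every point")
})

test_that("uniform downsampling hits the exact target and is seeded", {
  pc <- randomCloud(10000, seed = 2)
  down <- uniformDownsample(pc, 4096L, seed = 1)
  expect_equal(npoints(down), 4096L)
  expect_equal(npoints(uniformDownsample(randomCloud(50), 80L, seed = 1)), 80L)
  # same multiset when targetN = N
  perm <- uniformDownsample(pc, 10000L, seed = 3)
  expect_equal(sort(coords(perm)[, 1]), sort(coords(pc)[, 1]))
  # determinism
  expect_equal(coords(uniformDownsample(pc, 100L, seed = 9)),
               coords(uniformDownsample(pc, 100L, seed = 9)))
  # label distribution is preserved at N/2 (chi-square sanity)
  half <- uniformDownsample(pc, 5000L, seed = 4)
  tab <- table(factor(semanticLabels(half), levels = 0:1))
  exp_p <- prop.table(table(factor(semanticLabels(pc), levels = 0:1)))
  expect_gt(suppressWarnings(chisq.test(tab, p = exp_p)$p.value), 0.001)
})

test_that("unit-ball normalization matches the hand-computed case and inverts", {
  pc <- pointCloud(rbind(c(0, 0, 0), c(0, 0, 2)))
  nrm <- normalizePoints(pc)
  expect_equal(nrm$transform@centroid, c(0, 0, 1))
  expect_equal(nrm$transform@scale, 1)
  expect_equal(coords(nrm$cloud), rbind(c(0, 0, -1), c(0, 0, 1)))
  expect_true(isNormalized(nrm$cloud))

  for (seed in 1:3) {
    pc <- randomCloud(40, seed = seed)
    pc@points <- pc@points * 10 + seed
    nrm <- normalizePoints(pc)
    expect_lte(max(abs(coords(nrm$cloud))), 1)
    back <- denormalizePoints(nrm$cloud, nrm$transform)
    expect_equal(coords(back), coords(pc), tolerance = 1e-9)
    expect_false(isNormalized(back))
  }
  # single point and axis-aligned clouds
  expect_error(normalizePoints(pointCloud(matrix(1, 3, 3))), "scale is zero")
  axis <- pointCloud(cbind(seq(0, 5, length.out = 7), 0, 0))
  nrm <- normalizePoints(axis)
  expect_equal(coords(denormalizePoints(nrm$cloud, nrm$transform)),
               coords(axis), tolerance = 1e-9)
  expect_error(normalizePoints(nrm$cloud), "already normalized")
})

test_that("PLY files round-trip in ASCII and binary with labels", {
  pc <- randomCloud(20, seed = 13)
  instanceIds(pc) <- sample(0:3, 20, replace = TRUE)
  for (binary in c(TRUE, FALSE)) {
    f <- withr::local_tempfile(fileext = ".ply")
    writePly(pc, f, binary = binary)
    back <- readPly(f)
    expect_equal(coords(back), coords(pc), tolerance = 1e-9)
    expect_identical(semanticLabels(back), semanticLabels(pc))
    expect_identical(instanceIds(back), instanceIds(pc))
  }
})
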