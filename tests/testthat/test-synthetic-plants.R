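test_that("generated plants honour the construction contract", {
  spec <- syntheticPlantSpec(nLeaves = 6L, pointsTotal = 4096L, seed = 11)
  pl <- generatePlant(spec)
  expect_equal(npoints(pl$cloud), 4096L)
  expect_setequal(unique(semanticLabels(pl$cloud)), c(0L, 1L))
  expect_equal(sort(unique(instanceIds(pl$cloud))), 0:6)  # stem + 6 leaves
  expect_equal(nrow(pl$truth$leaves), 6L)
  # stem is the minority class, labels consistent with instances
  labs <- semanticLabels(pl$cloud)
  expect_lt(mean(labs == 1L), 0.5)
  expect_true(all(instanceIds(pl$cloud)[labs == 1L] == 0L))
  expect_true(all(instanceIds(pl$cloud)[labs == 0L] > 0L))
  # bit-identical regeneration under the same seed
  pl2 <- generatePlant(spec)
  expect_identical(coords(pl$cloud), coords(pl2$cloud))
  expect_identical(pl$truth, pl2$truth)
  expect_warning(generatePlant(syntheticPlantSpec(
    stemHeight = 5, leafLengthRange = c(10, 12), seed = 1)), "plausible")
})

test_that("noise-free flat leaves reproduce generator length and width", {
  spec <- syntheticPlantSpec(surfaceNoiseSd = 0, leafCurvature = 0, seed = 21)
  pl <- generatePlant(spec)
  labs <- semanticLabels(pl$cloud)
  ids <- instanceIds(pl$cloud)
  for (j in seq_len(nrow(pl$truth$leaves))) {
    pts <- coords(pl$cloud)[ids == j & labs == 0L, , drop = FALSE]
    lw <- leafLengthWidth(pts)
    expect_equal(unname(lw["length"]), pl$truth$leaves$length[j],
                 tolerance = 0.01)
    expect_equal(unname(lw["width"]), pl$truth$leaves$width[j],
                 tolerance = 0.01)
  }
  # height ground truth matches the measured noiseless extent
  expect_equal(plantHeight(pl$cloud), pl$truth$height, tolerance = 1e-9)
})

test_that("analytic leaf areas sit between ellipse bounds", {
  for (s in 1:5) {
    spec <- syntheticPlantSpec(seed = s, leafCurvature = runif(1, 0, 0.6))
    pl <- generatePlant(spec)
    lt <- pl$truth$leaves
    expect_true(all(lt$area >= 0.5 * lt$length * lt$width))
    expect_true(all(lt$area <= pi / 4 * lt$arcLength * lt$width + 1e-9))
  }
})

test_that("point allocation tracks organ surface areas", {
  spec <- syntheticPlantSpec(seed = 31, pointsTotal = 8192L)
  pl <- generatePlant(spec)
  labs <- semanticLabels(pl$cloud)
  stemArea <- 2 * pi * spec$stemRadius * spec$stemHeight
  leafArea <- sum(pl$truth$leaves$area)
  expected <- stemArea / (stemArea + leafArea)
  expect_equal(mean(labs == 1L), expected, tolerance = 0.1)
})

test_that("corruption by removal matches floor arithmetic exactly", {
  pl <- generatePlant(syntheticPlantSpec(seed = 41, pointsTotal = 4096L))
  for (ratio in c(0.2, 0.4, 0.6, 0.8)) {
    out <- corruptRemove(pl$cloud, ratio, seed = 1)
    expect_equal(npoints(out), 4096L - floor(ratio * 4096L))
  }
  expect_equal(npoints(corruptRemove(pl$cloud, 0.6, seed = 2)), 1639L)
  ident <- corruptRemove(pl$cloud, 0, seed = 1)
  expect_identical(coords(ident), coords(pl$cloud))
  # labels filtered consistently
  out <- corruptRemove(pl$cloud, 0.5, seed = 3)
  expect_equal(length(semanticLabels(out)), npoints(out))
  expect_error(corruptRemove(pl$cloud, 1), "\\[0, 1\\)")
})

test_that("noise corruption replaces points uniformly in the unit cube", {
  pl <- generatePlant(syntheticPlantSpec(seed = 51, pointsTotal = 2048L))
  nc <- normalizePoints(pl$cloud)$cloud
  expect_error(corruptNoise(pl$cloud, 10L), "normalized")
  expect_identical(coords(corruptNoise(nc, 0L, seed = 1)), coords(nc))
  all <- corruptNoise(nc, npoints(nc), seed = 2)
  expect_true(all(abs(coords(all)) <= 1))
  expect_identical(semanticLabels(all), semanticLabels(nc))
  expect_gt(mean(coords(all) != coords(nc)), 0.999)
  # empirical uniformity of injected coordinates (KS test)
  big <- corruptNoise(nc, 2000L, seed = 3)
  changed <- which(rowSums(coords(big) != coords(nc)) > 0)
  vals <- as.vector(coords(big)[changed, ])
  expect_gt(stats::ks.test(vals, "punif", -1, 1)$p.value, 0.01)
})

test_that("dataset generation splits deterministically and writes artifacts", {
  outDir <- withr::local_tempdir()
  man <- generateDataset(10L, split = c(0.7, 0.1, 0.2), seed = 5,
                         pointsTotal = 300L, outDir = outDir)
  expect_equal(lengths(man$split), c(train = 7L, val = 1L, test = 2L))
  allIdx <- sort(unname(unlist(man$split)))
  expect_equal(allIdx, 1:10)
  expect_true(file.exists(file.path(outDir, "manifest.json")))
  expect_true(file.exists(man$truthFile))
  expect_length(man$files, 10L)
  cl <- readLabeledTxt(man$files[1])
  expect_equal(npoints(cl), 300L)
  expect_false(is.null(instanceIds(cl)))
  # regeneration reproduces the manifest
  outDir2 <- withr::local_tempdir()
  man2 <- generateDataset(10L, split = c(0.7, 0.1, 0.2), seed = 5,
                          pointsTotal = 300L, outDir = outDir2)
  expect_identical(man$split, man2$split)
  expect_identical(readLines(man$files[3]), readLines(man2$files[3]))
  expect_error(generateDataset(5L, split = c(0.5, 0.2, 0.2)), "sum to 1")
})
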