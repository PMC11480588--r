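# Parametric cucumber-like plants: a gently curved vertical stem tube plus
# bent elliptical leaf patches laddered along the stem at golden-angle
# azimuths. Every surface has a closed-form area, so generated clouds come
# with analytic ground-truth phenotypes.

#' Specification of one synthetic plant
#'
#' Defaults emulate a cucumber seedling at the 6-8 leaf stage: ~25 cm tall,
#' thin stem, 8-14 cm leaves with width ~0.6-0.8 of length and a mild
#' downward bend. Points are allocated to stem and leaves proportionally to
#' surface area, making the thin stem the minority class as in real plants.
#'
#' @param stemHeight stem height (cm).
#' @param stemRadius stem tube radius (cm).
#' @param nLeaves leaf count.
#' @param leafLengthRange min/max leaf arc length (cm).
#' @param leafWidthRatioRange min/max width as a fraction of length.
#' @param leafCurvature total droop bend of the leaf midrib (radians).
#' @param tiltRange initial leaf elevation angle range (radians).
#' @param junctionGap radial gap between stem surface and leaf base (cm);
#'   small values create the tight stem-leaf junctions that make the
#'   boundary hard.
#' @param pointsTotal exact number of points in the cloud.
#' @param surfaceNoiseSd isotropic Gaussian surface noise (cm).
#' @param seed RNG seed; the same spec is bit-reproducible.
#' @return a `SyntheticPlantSpec` list.
#' @export
syntheticPlantSpec <- function(stemHeight = 25, stemRadius = 0.3, nLeaves = 7L,
                               leafLengthRange = c(8, 14),
                               leafWidthRatioRange = c(0.6, 0.8),
                               leafCurvature = 0.4,
                               tiltRange = c(0.45, 0.9),
                               junctionGap = 0.3,
                               pointsTotal = 4096L, surfaceNoiseSd = 0.05,
                               seed = 1L) {
  stopIfNot(stemHeight > 0 && stemRadius > 0, "stem extents must be positive")
  stopIfNot(nLeaves >= 1L, "at least one leaf is required")
  stopIfNot(pointsTotal >= 100L, "pointsTotal must be at least 100")
  stopIfNot(all(leafLengthRange > 0), "leaf lengths must be positive")
  structure(list(stemHeight = stemHeight, stemRadius = stemRadius,
                 nLeaves = as.integer(nLeaves),
                 leafLengthRange = leafLengthRange,
                 leafWidthRatioRange = leafWidthRatioRange,
                 leafCurvature = leafCurvature, tiltRange = tiltRange,
                 junctionGap = junctionGap,
                 pointsTotal = as.integer(pointsTotal),
                 surfaceNoiseSd = surfaceNoiseSd, seed = as.integer(seed)),
            class = "SyntheticPlantSpec")
}

# midrib of a drooping leaf: arc length L, initial elevation tilt, total
# bend kappa; returns radial/vertical offsets at curve parameter s in [0,1]
leafMidrib <- function(s, L, tilt, kappa) {
  if (abs(kappa) < 1e-9) {
    list(radial = L * s * cos(tilt), vertical = L * s * sin(tilt))
  } else {
    list(radial = L * (sin(tilt) - sin(tilt - kappa * s)) / kappa,
         vertical = L * (cos(tilt - kappa * s) - cos(tilt)) / kappa)
  }
}

#' Generate one synthetic plant with ground-truth phenotypes
#'
#' The stem is a point tube on a slightly bowed vertical centerline
#' (semantic label 1, instance 0); each leaf is a bent elliptical patch
#' (label 0, instances 1..nLeaves) attached at laddered heights and
#' golden-angle azimuths. Four deterministic extreme points (base, tip, and
#' the two lateral width extremes) are always included per leaf so extent
#' measurements can recover the generator parameters exactly at zero noise.
#'
#' Ground truth: `height` is the z-extent of the noise-free geometry; per
#' leaf, `length` is the base-tip chord, `width` the maximal lateral extent,
#' and `area` the closed-form patch area `pi/4 * arcLength * width` (exact
#' for this ruled surface, any curvature).
#'
#' @param spec a [syntheticPlantSpec()].
#' @return list with `cloud` (a labelled [PointCloud-class], exactly
#'   `pointsTotal` points) and `truth` (list: `height`, `leaves` data.frame
#'   with instance, length, width, area, arcLength).
#' @export
generatePlant <- function(spec) {
  stopIfNot(inherits(spec, "SyntheticPlantSpec"),
            "spec must come from syntheticPlantSpec()")
  withSeed(spec$seed, {
    H <- spec$stemHeight
    nL <- spec$nLeaves
    arcLen <- runif(nL, spec$leafLengthRange[1L], spec$leafLengthRange[2L])
    widths <- arcLen * runif(nL, spec$leafWidthRatioRange[1L],
                             spec$leafWidthRatioRange[2L])
    tilts <- runif(nL, spec$tiltRange[1L], spec$tiltRange[2L])
    attach <- H * seq(0.30, 0.95, length.out = nL) +
      runif(nL, -0.02, 0.02) * H
    azim <- (2.399963 * seq_len(nL) + runif(1L, 0, 2 * pi)) %% (2 * pi)
    if (max(arcLen) > 1.2 * H)
      warning("leaf length exceeds plausible extent relative to the stem",
              call. = FALSE)

    # area-proportional point allocation with a floor per organ
    stemArea <- 2 * pi * spec$stemRadius * H
    leafAreas <- pi / 4 * arcLen * widths
    raw <- c(stemArea, leafAreas) / sum(stemArea, leafAreas) * spec$pointsTotal
    alloc <- pmax(floor(raw), c(50L, rep(30L, nL)))
    # largest-remainder style fix-up to the exact total
    while (sum(alloc) > spec$pointsTotal) {
      i <- which.max(alloc)
      alloc[i] <- alloc[i] - 1L
    }
    while (sum(alloc) < spec$pointsTotal) {
      i <- which.max(raw - alloc)
      alloc[i] <- alloc[i] + 1L
    }

    # stem: bowed centerline + tube surface
    bowX <- runif(1L, -0.02, 0.02) * H
    bowY <- runif(1L, -0.02, 0.02) * H
    stemCenter <- function(t) cbind(bowX * sin(pi * t), bowY * sin(pi * t), t * H)
    nS <- alloc[1L]
    tS <- runif(nS)
    aS <- runif(nS, 0, 2 * pi)
    stemPts <- stemCenter(tS) +
      cbind(spec$stemRadius * cos(aS), spec$stemRadius * sin(aS), 0)

    leafPts <- vector("list", nL)
    for (j in seq_len(nL)) {
      m <- alloc[j + 1L]
      # rejection-sample s with density prop. to the elliptical half-width
      s <- numeric(0)
      while (length(s) < m - 4L) {
        cand <- runif(2L * m)
        keep <- runif(2L * m) < sqrt(pmax(0, 1 - (2 * cand - 1)^2))
        s <- c(s, cand[keep])
      }
      s <- s[seq_len(m - 4L)]
      tt <- runif(m - 4L, -1, 1)
      s <- c(s, 0, 1, 0.5, 0.5)          # extremes: base, tip, both sides
      tt <- c(tt, 0, 0, -1, 1)
      mid <- leafMidrib(s, arcLen[j], tilts[j], spec$leafCurvature)
      halfW <- (widths[j] / 2) * sqrt(pmax(0, 1 - (2 * s - 1)^2))
      rHat <- c(cos(azim[j]), sin(azim[j]), 0)
      yHat <- c(-sin(azim[j]), cos(azim[j]), 0)
      base <- stemCenter(attach[j] / H)[1L, ] +
        rHat * (spec$stemRadius + spec$junctionGap)
      leafPts[[j]] <- t(base + t(
        outer(mid$radial, rHat) + outer(tt * halfW, yHat) +
          outer(mid$vertical, c(0, 0, 1))
      ))
    }

    pts <- rbind(stemPts, do.call(rbind, leafPts))
    labels <- c(rep(1L, nS), rep(0L, sum(alloc[-1L])))
    instances <- c(rep(0L, nS), rep(seq_len(nL), alloc[-1L]))
    heightTruth <- max(pts[, 3L]) - min(pts[, 3L])
    chord <- vapply(seq_len(nL), function(j) {
      tip <- leafMidrib(1, arcLen[j], tilts[j], spec$leafCurvature)
      sqrt(tip$radial^2 + tip$vertical^2)
    }, numeric(1))
    if (spec$surfaceNoiseSd > 0)
      pts <- pts + matrix(rnorm(length(pts), 0, spec$surfaceNoiseSd),
                          nrow(pts), 3L)
    list(
      cloud = pointCloud(pts, semanticLabels = labels, instanceIds = instances),
      truth = list(
        height = heightTruth,
        leaves = data.frame(instance = seq_len(nL), length = chord,
                            width = widths, area = pi / 4 * arcLen * widths,
                            arcLength = arcLen)
      )
    )
  })
}

#' Random point removal (density robustness corruption)
#'
#' Removes `floor(ratio * N)` seeded uniformly chosen points, emulating the
#' density robustness protocol (ratios 0.2/0.4/0.6/0.8).
#'
#' @param cloud a [PointCloud-class].
#' @param ratio removal fraction in `[0, 1)`.
#' @param seed seed for the draw.
#' @return the thinned [PointCloud-class].
#' @export
corruptRemove <- function(cloud, ratio, seed = 0L) {
  stopIfNot(ratio >= 0 && ratio < 1, "ratio must lie in [0, 1)")
  n <- npoints(cloud)
  nRemove <- floor(ratio * n)
  if (nRemove == 0L) return(cloud)
  drop <- withSeed(seed, sample.int(n, nRemove))
  cloud[-drop]
}

#' Uniform-noise replacement (noise robustness corruption)
#'
#' Replaces a seeded selection of `count` points of a normalized cloud by
#' uniform draws from `[-1, 1]^3`; the replaced points keep their labels
#' (the replacement protocol of the noise robustness test).
#'
#' @param cloud a normalized [PointCloud-class].
#' @param count number of points to replace (`<= N`).
#' @param seed seed for selection and draws.
#' @return the corrupted [PointCloud-class].
#' @export
corruptNoise <- function(cloud, count, seed = 0L) {
  stopIfNot(isNormalized(cloud), "corruptNoise operates on normalized clouds")
  count <- as.integer(count)
  n <- npoints(cloud)
  stopIfNot(count >= 0L && count <= n, "count must lie in [0, N]")
  if (count == 0L) return(cloud)
  withSeed(seed, {
    idx <- sample.int(n, count)
    out <- cloud
    out@points[idx, ] <- matrix(runif(3L * count, -1, 1), count, 3L)
    out
  })
}

#' Default parameter ranges for dataset generation
#'
#' @return list of ranges from which [generateDataset()] draws per-plant
#'   specs.
#' @export
syntheticSpecRanges <- function() {
  list(stemHeight = c(20, 30), stemRadius = c(0.25, 0.4), nLeaves = c(6L, 8L),
       leafLengthRange = c(8, 14), leafWidthRatioRange = c(0.6, 0.8),
       leafCurvature = c(0.2, 0.5), surfaceNoiseSd = c(0.05, 0.05))
}

#' Generate a dataset of synthetic plants with a deterministic split
#'
#' Draws per-plant specs from the ranges, generates every plant, splits
#' deterministically (seeded shuffle, then contiguous train/val/test
#' blocks), and - when `outDir` is given - writes each plant as labelled
#' text (with instance ids as a fifth column), the ground truth as CSV, and
#' a JSON manifest.
#'
#' @param nPlants number of plants.
#' @param specRanges ranges as from [syntheticSpecRanges()].
#' @param split fractions `c(train, val, test)` summing to 1. The reference
#'   protocol's 7:2:1 train:test:validation ratio corresponds to
#'   `c(0.7, 0.1, 0.2)`.
#' @param seed master seed.
#' @param pointsTotal points per plant.
#' @param outDir optional output directory.
#' @return the manifest: list with `plants` (list of `cloud`/`truth` pairs,
#'   only when `outDir` is NULL), `split` (list of index vectors), `files`
#'   (when written), `seed`.
#' @export
generateDataset <- function(nPlants, specRanges = syntheticSpecRanges(),
                            split = c(0.7, 0.1, 0.2), seed = 0L,
                            pointsTotal = 4096L, outDir = NULL) {
  stopIfNot(abs(sum(split) - 1) < 1e-9, "split fractions must sum to 1")
  stopIfNot(length(split) == 3L, "split must be c(train, val, test)")
  specs <- withSeed(childSeed(seed, 1L), lapply(seq_len(nPlants), function(i) {
    r <- specRanges
    syntheticPlantSpec(
      stemHeight = runif(1, r$stemHeight[1L], r$stemHeight[2L]),
      stemRadius = runif(1, r$stemRadius[1L], r$stemRadius[2L]),
      nLeaves = sample(seq(r$nLeaves[1L], r$nLeaves[2L]), 1L),
      leafLengthRange = r$leafLengthRange,
      leafWidthRatioRange = r$leafWidthRatioRange,
      leafCurvature = runif(1, r$leafCurvature[1L], r$leafCurvature[2L]),
      pointsTotal = pointsTotal,
      surfaceNoiseSd = runif(1, r$surfaceNoiseSd[1L], r$surfaceNoiseSd[2L]),
      seed = childSeed(seed, 100L + i)
    )
  }))
  plants <- lapply(specs, generatePlant)
  ord <- withSeed(childSeed(seed, 2L), sample.int(nPlants, nPlants))
  nTrain <- round(split[1L] * nPlants)
  nVal <- round(split[2L] * nPlants)
  idxSplit <- list(
    train = sort(ord[seq_len(nTrain)]),
    val = sort(ord[nTrain + seq_len(min(nVal, nPlants - nTrain))]),
    test = sort(ord[setdiff(seq_len(nPlants), seq_len(nTrain + nVal))])
  )
  manifest <- list(nPlants = nPlants, split = idxSplit, seed = seed)
  if (is.null(outDir)) {
    manifest$plants <- plants
    return(manifest)
  }
  dir.create(file.path(outDir, "plants"), recursive = TRUE, showWarnings = FALSE)
  files <- character(nPlants)
  truthRows <- list()
  for (i in seq_len(nPlants)) {
    files[i] <- file.path(outDir, "plants", sprintf("plant_%04d.txt", i))
    writeLabeledTxt(plants[[i]]$cloud, files[i])
    tr <- plants[[i]]$truth
    truthRows[[i]] <- cbind(plant = i, height = tr$height, tr$leaves)
  }
  truth <- do.call(rbind, truthRows)
  truthFile <- file.path(outDir, "truth.csv")
  write.table(truth, truthFile, sep = ",", row.names = FALSE, quote = FALSE)
  manifest$files <- files
  manifest$truthFile <- truthFile
  jsonlite::write_json(
    list(nPlants = nPlants, files = files, truthFile = truthFile,
         split = idxSplit, seed = seed),
    file.path(outDir, "manifest.json"), auto_unbox = TRUE, pretty = TRUE
  )
  manifest$manifestFile <- file.path(outDir, "manifest.json")
  manifest
}
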