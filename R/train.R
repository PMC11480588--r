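#' Loss configuration: cross-entropy plus triplet embedding loss
#'
#' The training objective is `alpha * L_CE + beta * L_triplet` with
#' `alpha + beta = 1`. The triplet term pulls same-class point embeddings
#' together and pushes different-class embeddings apart by at least the
#' squared-distance margin.
#'
#' @param alpha,beta mixing weights, non-negative, summing to 1.
#' @param margin triplet margin (on squared distances), > 0.
#' @param tripletsPerBatch number of seeded random triplets per step.
#' @return a `LossConfig` list.
#' @export
lossConfig <- function(alpha = 0.9, beta = 0.1, margin = 0.2,
                       tripletsPerBatch = 128L) {
  stopIfNot(alpha >= 0 && beta >= 0, "alpha and beta must be non-negative")
  if (abs(alpha + beta - 1) > 1e-9)
    stop("alpha + beta must equal 1", call. = FALSE)
  stopIfNot(margin > 0, "margin must be positive")
  structure(list(alpha = alpha, beta = beta, margin = margin,
                 tripletsPerBatch = as.integer(tripletsPerBatch)),
            class = "LossConfig")
}

#' Mean softmax cross-entropy of per-point class scores
#'
#' `L_C = -(1/n) sum_i sum_q y_iq log p_iq` with `p = softmax(scores)`; the
#' log is clamped at `1e-12`.
#'
#' @param scores N x p matrix of unnormalized class scores.
#' @param labels integer vector of true classes in `[0, p)`.
#' @return scalar loss.
#' @export
crossEntropyLoss <- function(scores, labels) {
  scores <- as.matrix(scores)
  labels <- as.integer(labels)
  stopIfNot(length(labels) == nrow(scores), "labels misaligned with scores")
  stopIfNot(all(labels >= 0L & labels < ncol(scores)), "labels out of range")
  adCrossEntropy(scores, labels)
}

# seeded triplet index draw: anchor uniform, positive from the anchor's
# class, negative from the other classes
sampleTriplets <- function(labels, count, seed) {
  classes <- unique(labels)
  counts <- table(labels)
  posClasses <- as.integer(names(counts)[counts >= 2L])
  if (length(classes) < 2L || !length(posClasses)) return(NULL)
  withSeed(seed, {
    anchors <- integer(count); positives <- integer(count); negatives <- integer(count)
    anchorPool <- which(labels %in% posClasses)
    byClass <- split(seq_along(labels), labels)
    a <- anchorPool[sample.int(length(anchorPool), count, replace = TRUE)]
    for (t in seq_len(count)) {
      lab <- labels[a[t]]
      pool <- byClass[[as.character(lab)]]
      repeat {
        p <- pool[sample.int(length(pool), 1L)]
        if (p != a[t] || length(pool) == 1L) break
      }
      negPool <- which(labels != lab)
      anchors[t] <- a[t]
      positives[t] <- p
      negatives[t] <- negPool[sample.int(length(negPool), 1L)]
    }
    list(anchor = anchors, positive = positives, negative = negatives)
  })
}

#' Triplet embedding loss over seeded random triplets
#'
#' Mean over sampled triplets of
#' `max(0, ||f_a - f_+||^2 - ||f_a - f_-||^2 + margin)`.
#'
#' @param features N x D per-point embedding matrix.
#' @param labels integer class labels aligned with rows.
#' @param cfg a [lossConfig()].
#' @param seed seed for the triplet draw.
#' @return scalar loss (0 with a warning when only one class is present).
#' @export
tripletLoss <- function(features, labels, cfg = lossConfig(), seed = 0L) {
  labels <- as.integer(labels)
  stopIfNot(length(labels) == nrow(as.matrix(adVal(features))),
            "labels misaligned with features")
  tri <- sampleTriplets(labels, cfg$tripletsPerBatch, seed)
  if (is.null(tri)) {
    warning("triplet loss undefined on a single-class batch; returning 0",
            call. = FALSE)
    return(0)
  }
  adTripletHinge(features, tri$anchor, tri$positive, tri$negative, cfg$margin)
}

#' Combined training loss
#'
#' @param scores N x p class scores.
#' @param features N x D embedding used by the triplet term.
#' @param labels integer class labels.
#' @param cfg a [lossConfig()] (validated so that `alpha + beta = 1`).
#' @param seed seed for the triplet draw.
#' @return scalar `alpha * L_CE + beta * L_triplet`.
#' @export
combinedLoss <- function(scores, features, labels, cfg = lossConfig(),
                         seed = 0L) {
  stopIfNot(inherits(cfg, "LossConfig"), "cfg must come from lossConfig()")
  ce <- adCrossEntropy(if (isNode(scores)) scores else as.matrix(scores),
                       as.integer(labels))
  if (cfg$beta == 0) return(if (isNode(ce)) ce else cfg$alpha * ce)
  tri <- tripletLoss(features, labels, cfg, seed)
  adAdd(adScale(ce, cfg$alpha), adScale(tri, cfg$beta))
}

#' Optimizer configuration
#'
#' SGD with momentum 0.9 under a cosine-annealed learning rate running from
#' `lrMax` at the first epoch to `lrMin` at `epochs`; training stops early
#' when the validation loss has not improved for `patience` epochs, or when
#' the within-epoch training accuracy reaches `stopTrainAcc` (if set).
#'
#' @param epochs maximum epoch count (the reference schedule uses 200).
#' @param batchSize clouds per gradient step (default 4).
#' @param lrMax,lrMin cosine schedule endpoints (defaults 0.1 and 0.001).
#' @param momentum SGD momentum coefficient.
#' @param patience early-stopping patience in epochs.
#' @param clipNorm global gradient-norm clip (NULL disables).
#' @param stopTrainAcc optional accuracy threshold for early convergence.
#' @param seed master seed for shuffling, triplet draws and initialization.
#' @param verbose print one line per epoch.
#' @return an `OptConfig` list.
#' @export
optConfig <- function(epochs = 200L, batchSize = 4L, lrMax = 0.1,
                      lrMin = 0.001, momentum = 0.9, patience = 10L,
                      clipNorm = 5, stopTrainAcc = NULL, seed = 0L,
                      verbose = FALSE) {
  structure(list(epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 lrMax = lrMax, lrMin = lrMin, momentum = momentum,
                 patience = as.integer(patience), clipNorm = clipNorm,
                 stopTrainAcc = stopTrainAcc, seed = as.integer(seed),
                 verbose = isTRUE(verbose)),
            class = "OptConfig")
}

#' Cosine-annealed learning rate
#'
#' @param epoch 0-based epoch index.
#' @param opt an [optConfig()].
#' @return the learning rate; `lrMax` at epoch 0, `lrMin` at the last epoch.
#' @export
cosineLr <- function(epoch, opt) {
  T <- max(opt$epochs - 1L, 1L)
  opt$lrMin + 0.5 * (opt$lrMax - opt$lrMin) * (1 + cos(pi * min(epoch, T) / T))
}

# merge prepared clouds into one block-diagonal batch
mergePrepared <- function(preps) {
  if (length(preps) == 1L) return(preps[[1L]])
  nLevels <- 4L
  coords <- vector("list", nLevels)
  offsets <- matrix(0L, length(preps) + 1L, nLevels)
  for (lv in seq_len(nLevels)) {
    coords[[lv]] <- do.call(rbind, lapply(preps, function(p) p$coords[[lv]]))
    offsets[, lv] <- cumsum(c(0L, vapply(preps, function(p)
      nrow(p$coords[[lv]]), integer(1))))
  }
  graphs <- lapply(1:3, function(lv) {
    idx <- do.call(rbind, lapply(seq_along(preps), function(ci)
      preps[[ci]]$graphs[[lv]]$neighborIndices + offsets[ci, lv]))
    list(neighborIndices = idx, K = ncol(idx), N = nrow(idx))
  })
  pools <- lapply(1:3, function(lv) {
    do.call(rbind, lapply(seq_along(preps), function(ci)
      preps[[ci]]$pools[[lv]] + offsets[ci, lv]))
  })
  interp <- lapply(1:3, function(iv) {
    do.call(Matrix::bdiag, lapply(preps, function(p) p$interp[[iv]]))
  })
  labels <- unlist(lapply(preps, function(p) p$labels), use.names = FALSE)
  list(coords = coords, graphs = graphs, pools = pools,
       interp = interp, labels = labels, N = nrow(coords[[1L]]))
}

# clip gradient tree to a global norm bound
clipGradients <- function(grads, clipNorm) {
  if (is.null(clipNorm)) return(grads)
  nrm <- sqrt(paramsSumSq(grads))
  if (!is.finite(nrm) || nrm <= clipNorm) return(grads)
  mapParams(grads, function(g) g * (clipNorm / nrm))
}

#' Train the segmentation network
#'
#' SGD with momentum under a cosine-annealed learning rate on batches of
#' prepared clouds (all coordinate-dependent structures - KNN graphs, FPS
#' subsets, pooling neighbourhoods and interpolation weights - are
#' precomputed once per cloud). Aborts on a non-finite loss.
#'
#' @param train list of labelled, normalized [PointCloud-class] objects.
#' @param val optional validation list of the same form; drives early
#'   stopping.
#' @param cfg a [ggeConfig()].
#' @param loss a [lossConfig()].
#' @param opt an [optConfig()].
#' @return an `segNetModel`: list with `params`, `cfg`, `loss`, `opt`,
#'   `history` (one row per epoch: lr, train loss/accuracy, validation
#'   loss/accuracy) and `epochsRun`.
#' @export
trainModel <- function(train, val = NULL, cfg = ggeConfig(),
                       loss = lossConfig(), opt = optConfig()) {
  stopIfNot(length(train) >= 1L, "training set is empty")
  for (cl in c(train, val)) {
    stopIfNot(is(cl, "PointCloud") && isNormalized(cl) &&
                length(cl@semanticLabels) > 0L,
              "every cloud must be a labelled, normalized PointCloud")
  }
  preps <- lapply(seq_along(train), function(i) {
    f <- if (i == 1L) identity else suppressWarnings
    f(prepareCloud(train[[i]], cfg, childSeed(opt$seed, i)))
  })
  valPreps <- if (!is.null(val))
    lapply(seq_along(val), function(i)
      suppressWarnings(prepareCloud(val[[i]], cfg, childSeed(opt$seed, 1000L + i))))

  params <- segNetInit(cfg, seed = opt$seed)
  velocity <- mapParams(params, function(x) x * 0)
  history <- data.frame()
  bestVal <- Inf
  stale <- 0L
  step <- 0L
  nTrain <- length(preps)

  evalSet <- function(ps) {
    tot <- 0; correct <- 0L; n <- 0L
    for (p in ps) {
      out <- segNetForwardCore(p, params, cfg, seed = opt$seed)
      sc <- adVal(out$scores)
      tot <- tot + adCrossEntropy(sc, p$labels) * nrow(sc)
      correct <- correct + sum(max.col(sc) - 1L == p$labels)
      n <- n + nrow(sc)
    }
    list(loss = tot / n, acc = correct / n)
  }

  for (epoch in seq_len(opt$epochs) - 1L) {
    lr <- cosineLr(epoch, opt)
    ord <- withSeed(childSeed(opt$seed, 2000L + epoch),
                    sample.int(nTrain, nTrain))
    batches <- split(ord, ceiling(seq_along(ord) / opt$batchSize))
    epochLoss <- 0; epochCorrect <- 0L; epochN <- 0L
    for (b in batches) {
      step <- step + 1L
      merged <- mergePrepared(preps[b])
      wrapped <- paramsWrap(params)
      adTapeStart()
      out <- segNetForwardCore(merged, wrapped, cfg,
                               seed = childSeed(opt$seed, 3000L + step))
      lossNode <- combinedLoss(out$scores, out$embedding, merged$labels, loss,
                               seed = childSeed(opt$seed, 4000L + step))
      lossVal <- adVal(lossNode)
      if (!is.finite(lossVal)) {
        adTapeStop()
        stop(sprintf("non-finite loss at epoch %d step %d (lr %.4g); ",
                     epoch, step, lr),
             "training aborted", call. = FALSE)
      }
      adBackward(lossNode)
      adTapeStop()
      grads <- clipGradients(paramsGradTree(wrapped), opt$clipNorm)
      velocity <- mapParams2(velocity, grads, function(v, g)
        opt$momentum * v - lr * g)
      params <- mapParams2(params, velocity, function(p, v) p + v)
      sc <- adVal(out$scores)
      epochLoss <- epochLoss + lossVal * nrow(sc)
      epochCorrect <- epochCorrect + sum(max.col(sc) - 1L == merged$labels)
      epochN <- epochN + nrow(sc)
    }
    trainLoss <- epochLoss / epochN
    trainAcc <- epochCorrect / epochN
    valStats <- if (!is.null(valPreps)) evalSet(valPreps)
      else list(loss = NA_real_, acc = NA_real_)
    history <- rbind(history, data.frame(
      epoch = epoch, lr = lr, trainLoss = trainLoss, trainAcc = trainAcc,
      valLoss = valStats$loss, valAcc = valStats$acc
    ))
    if (opt$verbose)
      message(sprintf(
        "epoch %3d lr %.4f train loss %.4f acc %.3f val loss %s acc %s",
        epoch, lr, trainLoss, trainAcc,
        formatC(valStats$loss, digits = 4, format = "f"),
        formatC(valStats$acc, digits = 3, format = "f")))
    monitor <- if (!is.null(valPreps)) valStats$loss else trainLoss
    if (monitor < bestVal - 1e-6) {
      bestVal <- monitor
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    if (!is.null(opt$stopTrainAcc) && trainAcc >= opt$stopTrainAcc) {
      # within-epoch batch accuracy mixes weights; confirm with an exact
      # pass over the training set before stopping early
      exact <- evalSet(preps)$acc
      if (opt$verbose)
        message(sprintf("  exact training accuracy %.4f", exact))
      if (exact >= opt$stopTrainAcc) break
    }
    if (stale >= opt$patience) break
  }
  structure(list(params = params, cfg = cfg, loss = loss, opt = opt,
                 history = history, epochsRun = nrow(history),
                 version = "1"),
            class = "segNetModel")
}

#' Predict per-point semantic labels
#'
#' Argmax over the network's class scores; the input coordinates are left
#' untouched. Unnormalized clouds are normalized internally for the forward
#' pass only.
#'
#' @param cloud a [PointCloud-class].
#' @param model a trained `segNetModel` from [trainModel()].
#' @param seed seed for farthest point sampling in the forward pass.
#' @return the cloud with `semanticLabels` replaced by predictions.
#' @export
predictLabels <- function(cloud, model, seed = 0L) {
  stopIfNot(inherits(model, "segNetModel"), "model must come from trainModel()")
  work <- cloud
  if (!isNormalized(work)) work <- normalizePoints(work)$cloud
  prep <- suppressWarnings(prepareCloud(work, model$cfg, seed))
  out <- segNetForwardCore(prep, model$params, model$cfg, seed)
  sc <- adVal(out$scores)
  res <- cloud
  res@semanticLabels <- as.integer(max.col(sc) - 1L)
  res
}

#' Save / load a trained model
#'
#' The checkpoint is a versioned RDS archive of parameters plus the full
#' configuration (architecture, loss, optimizer, history).
#'
#' @param model an `segNetModel`.
#' @param path file path.
#' @return `path` (save) or the model (load).
#' @export
saveModel <- function(model, path) {
  stopIfNot(inherits(model, "segNetModel"), "not an segNetModel")
  saveRDS(model, path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  model <- readRDS(path)
  stopIfNot(inherits(model, "segNetModel"), "checkpoint does not hold an segNetModel")
  stopIfNot(identical(model$version, "1"), "unsupported checkpoint version")
  model
}
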