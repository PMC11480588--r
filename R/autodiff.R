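# Minimal reverse-mode automatic differentiation over dense matrices.
#
# Nodes are environments holding a value, an accumulated gradient and a
# backward closure; a global tape records creation order so that walking it
# in reverse is a valid topological order. Every op also accepts plain
# matrices (and returns one when no argument tracks gradients), so the same
# forward code serves training and inference.
#
# Fused ops (attention, layer norm, Poincare maps, softmax pooling, losses)
# carry hand-derived backward passes; everything heavy reduces to BLAS-backed
# matrix products, `rowsum`, and vectorized reshapes.

.adEnv <- new.env(parent = emptyenv())
.adEnv$tape <- NULL
.adEnv$n <- 0L

adTapeStart <- function() {
  .adEnv$tape <- vector("list", 256L)
  .adEnv$n <- 0L
  invisible(NULL)
}

adTapeStop <- function() {
  .adEnv$tape <- NULL
  .adEnv$n <- 0L
  invisible(NULL)
}

adTapeActive <- function() !is.null(.adEnv$tape)

isNode <- function(x) inherits(x, "adNode")

adVal <- function(x) if (isNode(x)) x$value else x

# leaf node (parameter); grads accumulate on it but it is not on the tape
adLeaf <- function(value) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  class(node) <- "adNode"
  node
}

adRecord <- function(value, parents, backfn, cache = NULL) {
  node <- new.env(parent = emptyenv())
  node$value <- value
  node$grad <- NULL
  node$parents <- parents
  node$backfn <- backfn
  node$cache <- cache
  class(node) <- "adNode"
  n <- .adEnv$n + 1L
  if (n > length(.adEnv$tape)) .adEnv$tape <- c(.adEnv$tape, vector("list", length(.adEnv$tape)))
  .adEnv$tape[[n]] <- node
  .adEnv$n <- n
  node
}

# op entry: returns TRUE when the result must be recorded
adTracked <- function(...) {
  if (!adTapeActive()) return(FALSE)
  for (x in list(...)) if (isNode(x)) return(TRUE)
  FALSE
}

adAccum <- function(p, g) {
  if (!isNode(p) || is.null(g)) return(invisible(NULL))
  p$grad <- if (is.null(p$grad)) g else p$grad + g
  invisible(NULL)
}

# backpropagate from a scalar node; afterwards leaf nodes carry $grad
adBackward <- function(loss) {
  stopIfNot(isNode(loss), "loss must be an adNode")
  loss$grad <- 1
  for (k in seq(.adEnv$n, 1L)) {
    node <- .adEnv$tape[[k]]
    if (is.null(node$grad)) next
    gs <- node$backfn(node)
    ps <- node$parents
    for (i in seq_along(ps)) adAccum(ps[[i]], gs[[i]])
    if (!identical(node, loss)) node$grad <- NULL
  }
  invisible(NULL)
}

## ---- primitive ops ---------------------------------------------------------

adMatmul <- function(a, b) {
  av <- adVal(a); bv <- adVal(b)
  out <- av %*% bv
  if (!adTracked(a, b)) return(out)
  adRecord(out, list(a, b), function(node) {
    g <- node$grad
    list(
      if (isNode(node$parents[[1L]])) g %*% t(node$cache$bv) else NULL,
      if (isNode(node$parents[[2L]])) crossprod(node$cache$av, g) else NULL
    )
  }, cache = list(av = av, bv = bv))
}

# m + row vector v, recycled over rows (faster than sweep: no aperm)
addRowVec <- function(m, v) .add_rowvec_cpp(m, as.numeric(v))

mulRowVec <- function(m, v) m * rep(v, each = nrow(m))

# leaky rectifier; the backward mask is recovered from the output's sign
lrelu <- function(x, slope) .lrelu_fwd_cpp(x, slope)

lreluBack <- function(g, y, slope) .lrelu_bwd_cpp(g, y, slope)

# column sums over contiguous equal-size row blocks: rows grouped per block,
# within-block index fastest; returns nBlocks x ncol
blockColSums <- function(m, T) {
  B <- nrow(m) %/% T
  matrix(.colSums(matrix(m, nrow = T), T, B * ncol(m)), nrow = B)
}

# x %*% W + bias (bias recycled over rows; added in place into the fresh
# matmul result)
adLinear <- function(x, W, b = NULL) {
  xv <- adVal(x); Wv <- adVal(W)
  out <- xv %*% Wv
  if (!is.null(b)) out <- .add_rowvec_ip_cpp(out, as.numeric(adVal(b)))
  if (!adTracked(x, W, b)) return(out)
  adRecord(out, list(x, W, b), function(node) {
    g <- node$grad
    list(
      if (isNode(node$parents[[1L]])) tcrossprod(g, node$cache$Wv) else NULL,
      if (isNode(node$parents[[2L]])) crossprod(node$cache$xv, g) else NULL,
      if (isNode(node$parents[[3L]])) colSums(g) else NULL
    )
  }, cache = list(xv = xv, Wv = Wv))
}

adAdd <- function(a, b) {
  out <- adVal(a) + adVal(b)
  if (!adTracked(a, b)) return(out)
  adRecord(out, list(a, b), function(node) list(node$grad, node$grad))
}

adSub <- function(a, b) {
  out <- adVal(a) - adVal(b)
  if (!adTracked(a, b)) return(out)
  adRecord(out, list(a, b), function(node) list(node$grad, -node$grad))
}

adMul <- function(a, b) {
  av <- adVal(a); bv <- adVal(b)
  out <- av * bv
  if (!adTracked(a, b)) return(out)
  adRecord(out, list(a, b), function(node)
    list(node$grad * node$cache$bv, node$grad * node$cache$av),
    cache = list(av = av, bv = bv))
}

adScale <- function(a, s) {
  out <- adVal(a) * s
  if (!adTracked(a)) return(out)
  adRecord(out, list(a), function(node) list(node$grad * node$cache$s),
           cache = list(s = s))
}

adConcatCols <- function(...) {
  args <- list(...)
  vals <- lapply(args, adVal)
  out <- do.call(cbind, vals)
  if (!do.call(adTracked, args)) return(out)
  widths <- vapply(vals, ncol, integer(1))
  adRecord(out, args, function(node) {
    g <- node$grad
    ends <- cumsum(node$cache$widths)
    starts <- c(1L, head(ends, -1L) + 1L)
    lapply(seq_along(node$parents), function(i)
      if (isNode(node$parents[[i]])) g[, starts[i]:ends[i], drop = FALSE] else NULL)
  }, cache = list(widths = widths))
}

adRbind <- function(a, b) {
  av <- adVal(a); bv <- adVal(b)
  out <- rbind(av, bv)
  if (!adTracked(a, b)) return(out)
  na <- nrow(av)
  adRecord(out, list(a, b), function(node) {
    g <- node$grad
    na <- node$cache$na
    list(g[seq_len(na), , drop = FALSE], g[-seq_len(na), , drop = FALSE])
  }, cache = list(na = na))
}

# gather rows from the virtual concatenation [a; b] without materializing it
adGatherRows2 <- function(a, b, idx) {
  av <- adVal(a); bv <- adVal(b)
  out <- .gather2_cpp(av, bv, as.integer(idx))
  if (!adTracked(a, b)) return(out)
  adRecord(out, list(a, b), function(node) {
    cc <- node$cache
    sc <- .scatter2_cpp(node$grad, cc$idx, cc$na, cc$nb)
    list(
      if (isNode(node$parents[[1L]])) sc$da else NULL,
      if (isNode(node$parents[[2L]])) sc$db else NULL
    )
  }, cache = list(idx = as.integer(idx), na = nrow(av), nb = nrow(bv)))
}

# gather rows; backward scatter-adds into the source
adGatherRows <- function(x, idx) {
  xv <- adVal(x)
  out <- xv[idx, , drop = FALSE]
  if (!adTracked(x)) return(out)
  adRecord(out, list(x), function(node)
    list(.scatter_add_cpp(node$grad, node$cache$idx, node$cache$n)),
    cache = list(idx = as.integer(idx), n = nrow(xv)))
}

adLeakyRelu <- function(x, slope = 0.2) {
  xv <- adVal(x)
  y <- lrelu(xv, slope)
  if (!adTracked(x)) return(y)
  adRecord(y, list(x), function(node)
    list(lreluBack(node$grad, node$value, node$cache$slope)),
    cache = list(slope = slope))
}

adRelu <- function(x) {
  xv <- adVal(x)
  out <- pmax(xv, 0)
  if (!adTracked(x)) return(out)
  adRecord(out, list(x), function(node)
    list(node$grad * (node$cache$xv > 0)), cache = list(xv = xv))
}

adSigmoid <- function(x) {
  out <- 1 / (1 + exp(-adVal(x)))
  if (!adTracked(x)) return(out)
  adRecord(out, list(x), function(node) {
    s <- node$cache$s
    list(node$grad * s * (1 - s))
  }, cache = list(s = out))
}

## ---- fused blocks ----------------------------------------------------------

# kernel responses of the adaptive graph convolution:
#   h[r, m] = LeakyReLU( <dx[r, ], G[r, (m-1)*6 + (1:6)]> )
# dx is the 6-dim spatial encoding (constant w.r.t. parameters), G the
# generated kernels (rows x 6M).
adKernelResponse <- function(dx, G, M, slope = 0.2) {
  Gv <- adVal(G)
  h <- .kernel_response_fwd_cpp(dx, Gv, M, slope)
  if (!adTracked(G)) return(h)
  adRecord(h, list(G), function(node) {
    cc <- node$cache
    list(.kernel_response_bwd_cpp(node$grad, node$value, cc$dx, cc$M,
                                  cc$slope))
  }, cache = list(dx = dx, M = M, slope = slope))
}

# channel-wise softmax attention pooling over each point's K neighbours.
# h has N*K rows (neighbour index fastest); returns list(pooled N x M,
# weights N*K x M).
softmaxPoolForward <- function(hv, K) {
  fw <- .softmax_pool_fwd_cpp(hv, K)
  list(pooled = fw$pooled, weights = fw$weights)
}

adSoftmaxPool <- function(h, K) {
  hv <- adVal(h)
  fw <- softmaxPoolForward(hv, K)
  if (!adTracked(h)) return(fw$pooled)
  adRecord(fw$pooled, list(h), function(node) {
    cc <- node$cache
    list(.softmax_pool_bwd_cpp(node$grad, cc$w, cc$hv, node$value, cc$K))
  }, cache = list(hv = hv, w = fw$weights, K = K))
}

# multi-head scaled dot-product attention with one query per group and Tslots
# keys/values per group (rows of Ks/Vs grouped by query, slot index fastest)
attentionForward <- function(Qv, Ksv, Vsv, Tslots, heads) {
  M <- ncol(Qv)
  stopIfNot((M %/% heads) * heads == M, "head count must divide the feature width")
  fw <- .att_fwd_cpp(Qv, Ksv, Vsv, Tslots, heads)
  list(O = fw$O, w = fw$w)
}

adAttention <- function(Q, Ks, Vs, Tslots, heads) {
  Qv <- adVal(Q); Ksv <- adVal(Ks); Vsv <- adVal(Vs)
  fw <- attentionForward(Qv, Ksv, Vsv, Tslots, heads)
  if (!adTracked(Q, Ks, Vs)) return(fw$O)
  adRecord(fw$O, list(Q, Ks, Vs), function(node) {
    cc <- node$cache
    bw <- .att_bwd_cpp(node$grad, cc$Qv, cc$Ksv, cc$Vsv, cc$w, cc$Tslots,
                       cc$heads)
    list(
      if (isNode(node$parents[[1L]])) bw$dQ else NULL,
      if (isNode(node$parents[[2L]])) bw$dK else NULL,
      if (isNode(node$parents[[3L]])) bw$dV else NULL
    )
  }, cache = list(Qv = Qv, Ksv = Ksv, Vsv = Vsv, w = fw$w, Tslots = Tslots,
                  heads = heads))
}

# row-wise layer normalization with learnable gain/offset
adLayerNorm <- function(x, gamma, beta, eps = 1e-5) {
  xv <- adVal(x)
  mu <- rowMeans(xv)
  xc <- xv - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- addRowVec(mulRowVec(xhat, as.numeric(adVal(gamma))), adVal(beta))
  if (!adTracked(x, gamma, beta)) return(out)
  adRecord(out, list(x, gamma, beta), function(node) {
    cc <- node$cache
    g <- node$grad
    gg <- mulRowVec(g, cc$gamma)
    m1 <- rowMeans(gg)
    m2 <- rowMeans(gg * cc$xhat)
    dx <- (gg - m1 - cc$xhat * m2) * cc$inv
    list(
      if (isNode(node$parents[[1L]])) dx else NULL,
      if (isNode(node$parents[[2L]])) colSums(g * cc$xhat) else NULL,
      if (isNode(node$parents[[3L]])) colSums(g) else NULL
    )
  }, cache = list(xhat = xhat, inv = inv, gamma = as.numeric(adVal(gamma))))
}

# Poincare-ball exponential map at the origin (curvature -c, c > 0):
#   exp_0^c(f) = tanh(sqrt(c) ||f||) * f / (sqrt(c) ||f||)
expmapRadial <- function(n, c) {
  u <- sqrt(c) * n
  phi <- ifelse(u < 1e-7, 1 - u^2 / 3, tanh(u) / u)
  dphi <- ifelse(u < 1e-7, -2 * c * n / 3,
                 sqrt(c) * (u * (1 - tanh(u)^2) - tanh(u)) / u^2)
  list(phi = phi, dphi = dphi)
}

adExpmap0 <- function(x, c) {
  xv <- adVal(x)
  stopIfNot(all(is.finite(xv)), "expmap0 requires finite input")
  n <- rowNorms(xv)
  r <- expmapRadial(n, c)
  # enforce strict ball containment under floating point: tanh saturates to
  # exactly 1 for arguments beyond ~19, which would land on the boundary
  sat <- sqrt(c) * n * r$phi >= 1 - 1e-12
  if (any(sat)) r$phi[sat] <- (1 - 1e-10) / (sqrt(c) * n[sat])
  out <- xv * r$phi
  if (!adTracked(x)) return(out)
  adRecord(out, list(x), function(node) {
    cc <- node$cache
    dot <- rowSums(cc$xv * node$grad)
    safeN <- pmax(cc$n, 1e-12)
    list(node$grad * cc$phi + cc$xv * (cc$dphi * dot / safeN))
  }, cache = list(xv = xv, n = n, phi = r$phi, dphi = r$dphi))
}

logmapRadial <- function(n, c) {
  u <- sqrt(c) * n
  psi <- ifelse(u < 1e-7, 1 + u^2 / 3, atanh(u) / u)
  dpsi <- ifelse(u < 1e-7, 2 * c * n / 3,
                 sqrt(c) * (u / (1 - u^2) - atanh(u)) / u^2)
  list(psi = psi, dpsi = dpsi)
}

adLogmap0 <- function(x, c) {
  xv <- adVal(x)
  n <- rowNorms(xv)
  if (any(sqrt(c) * n >= 1))
    stop("logmap0: point outside the Poincare ball (||h|| * sqrt(c) >= 1)",
         call. = FALSE)
  r <- logmapRadial(n, c)
  out <- xv * r$psi
  if (!adTracked(x)) return(out)
  adRecord(out, list(x), function(node) {
    cc <- node$cache
    dot <- rowSums(cc$xv * node$grad)
    safeN <- pmax(cc$n, 1e-12)
    list(node$grad * cc$psi + cc$xv * (cc$dpsi * dot / safeN))
  }, cache = list(xv = xv, n = n, psi = r$psi, dpsi = r$dpsi))
}

# clamp rows to the open ball of radius maxNorm/sqrt(c); identity inside
adBallProject <- function(x, c, maxNorm = 1 - 1e-4) {
  xv <- adVal(x)
  n <- rowNorms(xv)
  r <- maxNorm / sqrt(c)
  fac <- ifelse(n > r, r / n, 1)
  out <- xv * fac
  if (!adTracked(x)) return(out)
  adRecord(out, list(x), function(node) {
    cc <- node$cache
    g <- node$grad
    scaled <- cc$fac < 1
    dx <- g * cc$fac
    if (any(scaled)) {
      dot <- rowSums(cc$xv * g)
      corr <- ifelse(scaled, cc$r / pmax(cc$n, 1e-12)^3, 0)
      dx <- dx - cc$xv * (corr * dot)
    }
    list(dx)
  }, cache = list(xv = xv, n = n, fac = fac, r = r))
}

# sparse constant weights times features (decoder interpolation)
adSpmm <- function(W, x) {
  xv <- adVal(x)
  out <- as.matrix(W %*% xv)
  if (!adTracked(x)) return(out)
  adRecord(out, list(x), function(node)
    list(as.matrix(Matrix::crossprod(node$cache$W, node$grad))),
    cache = list(W = W))
}

# channel-wise max over index groups (graph pooling); idxMat is S x m of
# global row indices into x (0 = padding, ignored)
adMaxPoolGroup <- function(x, idxMat) {
  xv <- adVal(x)
  storage.mode(idxMat) <- "integer"
  fw <- .group_max_cpp(xv, idxMat)
  if (!adTracked(x)) return(fw$max)
  adRecord(fw$max, list(x), function(node)
    list(.group_max_bwd_cpp(node$grad, node$cache$arg, node$cache$n)),
    cache = list(arg = fw$arg, n = nrow(xv)))
}

# mean cross-entropy with softmax, truth as 0-based integer labels
adCrossEntropy <- function(scores, labels) {
  sv <- adVal(scores)
  n <- nrow(sv)
  mx <- apply(sv, 1L, max)
  E <- exp(sv - mx)
  p <- E / rowSums(E)
  picked <- p[cbind(seq_len(n), labels + 1L)]
  out <- -mean(log(pmax(picked, 1e-12)))
  if (!adTracked(scores)) return(out)
  adRecord(out, list(scores), function(node) {
    cc <- node$cache
    Y <- matrix(0, nrow(cc$p), ncol(cc$p))
    Y[cbind(seq_len(nrow(cc$p)), cc$labels + 1L)] <- 1
    list(node$grad * (cc$p - Y) / nrow(cc$p))
  }, cache = list(p = p, labels = labels))
}

# mean hinge over sampled triplets: max(0, ||fa-fp||^2 - ||fa-fn||^2 + margin)
adTripletHinge <- function(emb, anchor, positive, negative, margin) {
  fv <- adVal(emb)
  fa <- fv[anchor, , drop = FALSE]
  fp <- fv[positive, , drop = FALSE]
  fn <- fv[negative, , drop = FALSE]
  dPos <- rowSums((fa - fp)^2)
  dNeg <- rowSums((fa - fn)^2)
  v <- dPos - dNeg + margin
  act <- v > 0
  out <- mean(pmax(v, 0))
  if (!adTracked(emb)) return(out)
  adRecord(out, list(emb), function(node) {
    cc <- node$cache
    w <- node$grad * cc$act / length(cc$act)
    dfa <- 2 * w * (cc$fn - cc$fp)  # note: d/dfa = 2(fa-fp) - 2(fa-fn) = 2(fn-fp)
    dfp <- -2 * w * (cc$fa - cc$fp)
    dfn <- 2 * w * (cc$fa - cc$fn)
    idx <- c(cc$anchor, cc$positive, cc$negative)
    g <- rbind(dfa, dfp, dfn)
    src <- matrix(0, cc$n, ncol(g))
    agg <- rowsum(g, group = idx, reorder = FALSE)
    src[as.integer(rownames(agg)), ] <- agg
    list(src)
  }, cache = list(fa = fa, fp = fp, fn = fn, act = as.numeric(act),
                  anchor = anchor, positive = positive, negative = negative,
                  n = nrow(fv)))
}

# finite-difference gradient of a scalar function of one matrix, used by the
# test suite to validate the hand-written backward passes
numericGradient <- function(fn, x, eps = 1e-5) {
  g <- x * 0
  for (i in seq_along(x)) {
    xp <- x; xp[i] <- xp[i] + eps
    xm <- x; xm[i] <- xm[i] - eps
    g[i] <- (fn(xp) - fn(xm)) / (2 * eps)
  }
  g
}
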