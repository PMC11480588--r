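#' Parameters of the adaptive-kernel Euclidean channel
#'
#' The kernel generator is one shared two-layer perceptron mapping the 2D-dim
#' feature encoding of an edge to M stacked 6-dim kernels (mathematically
#' identical to M separate maps, cheaper); the channel ends in a linear
#' post-pooling map M -> M.
#'
#' @param inputDim D, the per-point feature width entering the channel.
#' @param M number of kernels = channel output width.
#' @param hiddenDim width of the kernel generator's hidden layer (default M).
#' @param seed seed for Glorot-uniform initialization.
#' @return named list of weight matrices/vectors (an `AdaptiveKernelParams`).
#' @export
adaptiveKernelParams <- function(inputDim, M, hiddenDim = M, seed = 0L) {
  withSeed(seed, list(
    kW1 = glorot(2L * inputDim, hiddenDim),
    kb1 = numeric(hiddenDim),
    kW2 = glorot(hiddenDim, 6L * M),
    kb2 = numeric(6L * M),
    postW = glorot(M, M),
    postb = numeric(M),
    M = as.integer(M)
  ))
}

glorot <- function(fanIn, fanOut) {
  lim <- sqrt(6 / (fanIn + fanOut))
  matrix(runif(fanIn * fanOut, -lim, lim), fanIn, fanOut)
}

# generated kernels for every edge: rows x 6M
kernelGenerate <- function(featureEnc, params, slope = 0.2) {
  hid <- adLeakyRelu(adLinear(featureEnc, params$kW1, params$kb1), slope)
  adLinear(hid, params$kW2, params$kb2)
}

#' Adaptive kernel responses over a neighbourhood
#'
#' For each neighbour j and kernel m computes
#' `h_ij[m] = LeakyReLU(<dx_ij, g_m(df_ij)>)`: the learned kernels
#' `g_m(df_ij)` are generated from the feature encoding and contracted
#' against the 6-dim spatial encoding.
#'
#' @param enc an `EdgeEncoding` from [edgeEncode()] with `spatial` and
#'   `feature` filled.
#' @param params an `AdaptiveKernelParams` from [adaptiveKernelParams()];
#'   the generated kernels must be 6-dimensional per channel.
#' @param slope LeakyReLU negative slope (default 0.2).
#' @return `enc` with `kernelResponses` filled (N*K x M).
#' @export
adaptiveKernelResponse <- function(enc, params, slope = 0.2) {
  stopIfNot(inherits(enc, "EdgeEncoding"), "enc must be an EdgeEncoding")
  stopIfNot(!is.null(enc$spatial) && !is.null(enc$feature),
            "enc must have spatial and feature encodings filled")
  stopIfNot(ncol(params$kW1) == nrow(params$kW2), "kernel generator shape mismatch")
  if (ncol(params$kW2) != 6L * params$M)
    stop("kernel generator must emit 6-dimensional kernels per channel",
         call. = FALSE)
  stopIfNot(ncol(enc$feature) == nrow(params$kW1),
            "feature encoding width does not match the kernel generator")
  G <- kernelGenerate(enc$feature, params, slope)
  enc$kernelResponses <- adKernelResponse(enc$spatial, G, params$M, slope)
  enc
}

#' Attention pooling of kernel responses into a per-point feature
#'
#' Channel-wise softmax over each point's K neighbours, applied to the kernel
#' responses, followed by the channel's linear post-map: the Euclidean-space
#' feature `f_i^e`.
#'
#' @param enc an `EdgeEncoding` with `kernelResponses` filled.
#' @param params the same `AdaptiveKernelParams`.
#' @param slope LeakyReLU negative slope of the post-map.
#' @return list with `features` (N x M matrix `f^e`) and `enc` (the encoding
#'   with `attentionWeights` filled, each row block summing to 1 per channel).
#' @export
attentionPool <- function(enc, params, slope = 0.2) {
  stopIfNot(inherits(enc, "EdgeEncoding"), "enc must be an EdgeEncoding")
  if (is.null(enc$kernelResponses))
    stop("kernelResponses not filled; run adaptiveKernelResponse first",
         call. = FALSE)
  stopIfNot(enc$K >= 1L, "empty neighborhood")
  h <- enc$kernelResponses
  fw <- softmaxPoolForward(adVal(h), enc$K)
  enc$attentionWeights <- fw$weights
  pooled <- adSoftmaxPool(h, enc$K)
  feat <- adLeakyRelu(adLinear(pooled, params$postW, params$postb), slope)
  list(features = feat, enc = enc)
}

# full Euclidean channel for one stage: coords + features -> f^e (N x M)
euclideanChannelForward <- function(coords, features, edgeIdx, params,
                                    slope = 0.2) {
  K <- ncol(edgeIdx)
  N <- nrow(coords)
  ctr <- rep(seq_len(N), each = K)
  nb <- as.vector(t(edgeIdx))
  dx <- cbind(coords[ctr, , drop = FALSE],
              coords[nb, , drop = FALSE] - coords[ctr, , drop = FALSE])
  fi <- adGatherRows(features, ctr)
  fj <- adGatherRows(features, nb)
  df <- adConcatCols(fi, adSub(fj, fi))
  G <- kernelGenerate(df, params, slope)
  h <- adKernelResponse(dx, G, params$M, slope)
  pooled <- adSoftmaxPool(h, K)
  adLeakyRelu(adLinear(pooled, params$postW, params$postb), slope)
}
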