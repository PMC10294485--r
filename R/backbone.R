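# The `small_cnn` backbone: three frozen randomly-initialized 3x3
# convolution blocks with average pooling, producing a 32-dim globally
# pooled tile descriptor. Convolutions are computed as im2col patch
# matrices times a weight matrix, which keeps the whole forward pass in
# vectorized matrix algebra. The trainable part of the network (the 1x1
# projection "last conv layer" and the linear head) lives in
# mil_classifier.R; the blocks here stay frozen through training.

# Average pooling with stride = window = s (truncating partial windows).
avg_pool <- function(m, s) {
  H <- nrow(m); W <- ncol(m)
  H2 <- H %/% s; W2 <- W %/% s
  m <- m[seq_len(H2 * s), seq_len(W2 * s), drop = FALSE]
  rowpooled <- matrix(colMeans(matrix(m, nrow = s)), nrow = H2)     # H2 x W2*s
  t(matrix(colMeans(matrix(t(rowpooled), nrow = s)), nrow = W2))    # H2 x W2
}

# 'valid' 3x3 convolution over a list of C channel matrices.
# W: (9C) x F weight matrix, b: length-F bias. Returns list of F matrices.
conv3x3 <- function(channels, W, b) {
  H <- nrow(channels[[1L]]); Wd <- ncol(channels[[1L]])
  H2 <- H - 2L; W2 <- Wd - 2L
  ncols <- 9L * length(channels)
  P <- matrix(0, H2 * W2, ncols)
  j <- 0L
  for (ch in channels) {
    for (dc in 0:2) {
      for (dr in 0:2) {
        j <- j + 1L
        P[, j] <- as.vector(ch[(1L + dr):(H2 + dr), (1L + dc):(W2 + dc)])
      }
    }
  }
  out <- P %*% W
  out <- sweep(out, 2L, b, `+`)
  lapply(seq_len(ncol(out)), function(f) matrix(out[, f], H2, W2))
}

relu_list <- function(lst) lapply(lst, function(m) {
  m[m < 0] <- 0
  m
})

#' Initialize the frozen `small_cnn` backbone
#'
#' Three 3x3 convolution blocks (8, 16, 32 filters) over a 4x-downsampled
#' input, He-initialized from the configuration seed and frozen: training
#' never touches these weights. The global-average-pooled output is a
#' 32-dimensional tile descriptor.
#'
#' @param config a [model_config()].
#' @return A `small_cnn` backbone object (weights + architecture constants).
#' @export
init_backbone <- function(config) {
  if (!identical(config$backbone, "small_cnn")) {
    abort_wsimil(
      paste0("backbone '", config$backbone, "' is not available in this build; ",
             "use 'small_cnn'"),
      "wsimil_config_error"
    )
  }
  he <- function(fan_in, n) stats::rnorm(n, 0, sqrt(2 / fan_in))
  with_seed(derive_seed(config$seed, "backbone"), {
    structure(
      list(
        W1 = matrix(he(27, 27 * 8), 27, 8), b1 = rep(0, 8),
        W2 = matrix(he(72, 72 * 16), 72, 16), b2 = rep(0, 16),
        W3 = matrix(he(144, 144 * 32), 144, 32), b3 = rep(0, 32),
        input_pool = 4L, feature_dim = 32L, frozen = TRUE
      ),
      class = "small_cnn"
    )
  })
}

#' Frozen-backbone forward pass for one preprocessed tile
#'
#' @param backbone a `small_cnn` from [init_backbone()].
#' @param x H x W x 3 standardized float array (from [preprocess_tile()]).
#' @return Numeric vector of length `backbone$feature_dim` (global average
#'   pool of the last block's activations).
#' @export
backbone_features <- function(backbone, x) {
  chans <- lapply(1:3, function(ch) avg_pool(x[, , ch], backbone$input_pool))
  backbone_forward_pooled(backbone, chans)
}

# Conv stack on already input-pooled (and standardized) channel matrices.
backbone_forward_pooled <- function(backbone, chans) {
  h <- relu_list(conv3x3(chans, backbone$W1, backbone$b1))
  h <- lapply(h, avg_pool, s = 2L)
  h <- relu_list(conv3x3(h, backbone$W2, backbone$b2))
  h <- lapply(h, avg_pool, s = 2L)
  h <- relu_list(conv3x3(h, backbone$W3, backbone$b3))
  vapply(h, mean, numeric(1L))
}

# Input-pooled standardized channels of a raw tile. The input pooling and
# the affine standardization commute with whole-image flips (the tile edge
# is a multiple of the pool stride), so flip variants can be formed on the
# pooled maps without re-running the pooling.
pooled_tile_channels <- function(backbone, tile, config) {
  if (!is.null(config$normalizer)) {
    tile <- apply_reinhard(tile, config$normalizer)
  }
  lapply(1:3, function(ch) {
    m <- avg_pool(tile[, , ch] / 255, backbone$input_pool)
    (m - config$input_mean[ch]) / config$input_std[ch]
  })
}

flip_channels <- function(chans, horizontal, vertical) {
  lapply(chans, function(m) {
    if (horizontal) m <- m[, rev(seq_len(ncol(m))), drop = FALSE]
    if (vertical) m <- m[rev(seq_len(nrow(m))), , drop = FALSE]
    m
  })
}
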