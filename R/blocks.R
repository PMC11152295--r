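# Composite blocks: locally-enhanced feed-forward (LFFN), the efficient
# convolutional block (ECB = MHCA -> LFFN) and the local transformer block
# (LTB = ESA -> MHCA -> LFFN), plus stage patch embeddings.

#' Locally-enhanced feed-forward parameters
#'
#' A 1x1 expansion convolution, a 3x3 depthwise convolution that injects local
#' context, hard-swish activations, a squeeze-excitation gate and a 1x1
#' projection back to the block width. The surrounding block adds the residual
#' connection.
#'
#' @param channels block width.
#' @param expansion hidden-width multiplier.
#' @param se include the squeeze-excitation gate.
#' @param bias biases in the convolutions.
#' @return an LFFN module usable with [lffn_forward()].
#' @export
lffn_params <- function(channels, expansion = 3, se = TRUE, bias = TRUE) {
  H <- as.integer(floor(channels * expansion))
  self <- new_layer("lffn")
  self$channels <- channels
  layers <- list(
    conv2d(channels, H, kernel = 1, bias = bias),
    batchnorm(H),
    act_layer("hswish"),
    conv2d(H, H, kernel = 3, groups = H, bias = bias),
    batchnorm(H),
    act_layer("hswish")
  )
  if (se) layers <- c(layers, list(se_layer(H, max(1L, H %/% channels))))
  layers <- c(layers, list(
    conv2d(H, channels, kernel = 1, bias = bias),
    batchnorm(channels)
  ))
  self$body <- do.call(sequential, layers)
  self$children <- list(self$body)
  self$forward <- function(x, train = FALSE) self$body$forward(x, train)
  self$backward <- function(dy) self$body$backward(dy)
  self
}

#' Apply the locally-enhanced feed-forward network (with residual)
#'
#' Computes `x + LFFN(x)`; shape preserving.
#'
#' @param x an [fmap].
#' @param params module from [lffn_params()]; if missing, a module matching
#'   `ncol(x)` with `expansion` is created (untrained weights).
#' @param expansion hidden-width multiplier used when `params` is missing.
#' @param train logical; training mode.
#' @export
lffn_forward <- function(x, params = NULL, expansion = 3, train = FALSE) {
  if (is.null(params)) params <- lffn_params(ncol(x), expansion)
  fmap_like(unclass(x) + unclass(params$forward(x, train)), x)
}

# residual wrapper: y = x + droppath(branch(x))
residual <- function(branch, path_dropout = 0) {
  self <- new_layer("residual")
  self$branch <- branch
  self$dp <- droppath(path_dropout)
  self$children <- list(branch, self$dp)
  self$forward <- function(x, train = FALSE) {
    b <- self$dp$forward(self$branch$forward(x, train), train)
    fmap_like(unclass(x) + unclass(b), x)
  }
  self$backward <- function(dy) {
    db <- self$branch$backward(self$dp$backward(dy))
    fmap_like(unclass(dy) + unclass(db), dy)
  }
  self
}

# patch embedding: optional stride-2 average pool, then 1x1 channel projection
patch_embed <- function(cin, cout, pool_stride = 1, bias = TRUE) {
  layers <- list()
  if (pool_stride > 1) layers <- list(avgpool2d(pool_stride))
  layers <- c(layers, list(conv2d(cin, cout, kernel = 1, bias = bias),
                           batchnorm(cout)))
  do.call(sequential, layers)
}

#' Efficient convolutional block (ECB)
#'
#' `x -> [channel adapt] -> x + MHCA(x) -> x + LFFN(BN(x))`, with stochastic
#' depth on both residual branches.
#'
#' @param cin input channels (a 1x1 adapter is inserted when `cin != dim`).
#' @param dim block output channels.
#' @param conv block conventions, see [medvit_conventions()].
#' @param path_dropout stochastic-depth rate for this block.
#' @return an ECB module usable with [ecb_forward()].
#' @export
ecb_block <- function(cin, dim, conv = medvit_conventions(), path_dropout = 0) {
  self <- new_layer("ecb")
  self$kind <- "ECB"
  self$cin <- cin; self$dim <- dim
  heads <- max(1L, dim %/% conv$head_dim)
  self$adapt <- if (cin != dim) patch_embed(cin, dim, 1, conv$conv_bias) else NULL
  self$attn <- residual(
    mhca_params(dim, heads, conv$mhca_proj_norm, conv$conv_bias),
    path_dropout
  )
  self$pre_norm <- batchnorm(dim)
  self$ffn <- residual(
    sequential(self$pre_norm,
               lffn_params(dim, conv$ecb_mlp_ratio, conv$se, conv$conv_bias)),
    path_dropout
  )
  self$children <- c(
    if (!is.null(self$adapt)) list(self$adapt),
    list(self$attn, self$ffn)
  )
  self$forward <- function(x, train = FALSE) {
    if (!is.null(self$adapt)) x <- self$adapt$forward(x, train)
    x <- self$attn$forward(x, train)
    self$ffn$forward(x, train)
  }
  self$backward <- function(dy) {
    dy <- self$ffn$backward(dy)
    dy <- self$attn$backward(dy)
    if (!is.null(self$adapt)) dy <- self$adapt$backward(dy)
    dy
  }
  self
}

#' Local transformer block (LTB)
#'
#' Splits the block width into a transformer part (ESA over all tokens with
#' average-pooled keys/values) and a convolutional part (MHCA), concatenates
#' the two paths and finishes with an LFFN, all with residual connections and
#' stochastic depth.
#'
#' @param cin input channels.
#' @param dim block output channels.
#' @param pool_stride ESA key/value pooling stride for this stage.
#' @param conv block conventions, see [medvit_conventions()].
#' @param path_dropout stochastic-depth rate for this block.
#' @return an LTB module usable with [ltb_forward()].
#' @export
ltb_block <- function(cin, dim, pool_stride = 1, conv = medvit_conventions(),
                      path_dropout = 0) {
  self <- new_layer("ltb")
  self$kind <- "LTB"
  self$cin <- cin; self$dim <- dim
  m <- make_divisible(dim * conv$mix_ratio, conv$head_dim)
  c2 <- dim - m
  stopifnot(m >= conv$head_dim, c2 >= conv$head_dim)
  self$mhsa_ch <- m; self$mhca_ch <- c2
  self$pe_in <- patch_embed(cin, m, 1, conv$conv_bias)
  self$norm1 <- batchnorm(m)
  self$esa <- esa_params(m, max(1L, m %/% conv$head_dim), pool_stride,
                         conv$attn_bias, conv$attn_bias, conv$pool_kv_norm)
  self$dp_esa <- droppath(path_dropout)
  self$proj <- patch_embed(m, c2, 1, conv$conv_bias)
  self$mhca <- residual(
    mhca_params(c2, max(1L, c2 %/% conv$head_dim), conv$mhca_proj_norm,
                conv$conv_bias),
    path_dropout
  )
  self$norm2 <- batchnorm(dim)
  self$ffn <- residual(
    sequential(self$norm2,
               lffn_params(dim, conv$ltb_mlp_ratio, conv$se, conv$conv_bias)),
    path_dropout
  )
  self$children <- list(self$pe_in, self$norm1, self$esa, self$dp_esa,
                        self$proj, self$mhca, self$ffn)
  self$forward <- function(x, train = FALSE) {
    x1 <- self$pe_in$forward(x, train)
    b <- self$dp_esa$forward(self$esa$forward(self$norm1$forward(x1, train), train), train)
    x1 <- fmap_like(unclass(x1) + unclass(b), x1)
    x2 <- self$proj$forward(x1, train)
    x2 <- self$mhca$forward(x2, train)
    self$ffn$forward(fmap_like(cbind(unclass(x1), unclass(x2)), x1), train)
  }
  self$backward <- function(dy) {
    dy <- self$ffn$backward(dy)
    m <- self$mhsa_ch
    d1 <- fmap_like(unclass(dy)[, seq_len(m), drop = FALSE], dy)
    d2 <- fmap_like(unclass(dy)[, (m + 1):ncol(dy), drop = FALSE], dy)
    d2 <- self$mhca$backward(d2)
    d1 <- fmap_like(unclass(d1) + unclass(self$proj$backward(d2)), d1)
    db <- self$norm1$backward(self$esa$backward(self$dp_esa$backward(d1)))
    d1 <- fmap_like(unclass(d1) + unclass(db), d1)
    self$pe_in$backward(d1)
  }
  self
}

#' Run an ECB block
#' @param x an [fmap] with `cin` channels.
#' @param block module from [ecb_block()].
#' @param train logical; training mode.
#' @export
ecb_forward <- function(x, block, train = FALSE) block$forward(x, train)

#' Run an LTB block
#' @param x an [fmap] with `cin` channels.
#' @param block module from [ltb_block()].
#' @param train logical; training mode.
#' @export
ltb_forward <- function(x, block, train = FALSE) block$forward(x, train)

# channel rounding used for the transformer/convolution split inside LTB
make_divisible <- function(v, divisor) {
  nv <- max(divisor, (floor(v + divisor / 2) %/% divisor) * divisor)
  if (nv < 0.9 * v) nv <- nv + divisor
  as.integer(nv)
}
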