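# Attention modules: multi-head convolutional attention (MHCA) and efficient
# self-attention (ESA) with average-pooled keys/values.

#' Multi-head convolutional attention parameters
#'
#' MHCA aggregates every token with its 3x3 neighbourhood through per-head
#' learnable weights (a grouped convolution with one group per head), then
#' mixes the concatenated head outputs with a 1x1 output projection.
#'
#' @param channels number of input/output channels of the block.
#' @param heads number of attention heads; `channels` must be divisible by
#'   `heads`. Defaults to one head per 32 channels.
#' @param proj_norm apply batch normalization after the output projection.
#' @param bias use biases in the convolutions.
#' @return an MHCA module usable with [mhca_forward()].
#' @export
mhca_params <- function(channels, heads = max(1L, channels %/% 32L),
                        proj_norm = TRUE, bias = TRUE) {
  if (heads < 1 || channels %% heads != 0) {
    stop(sprintf(
      "MHCA block with %d channels cannot use %d heads: channels must be divisible by heads",
      channels, heads
    ), call. = FALSE)
  }
  self <- new_layer("mhca")
  self$channels <- channels
  self$heads <- as.integer(heads)
  layers <- list(
    conv2d(channels, channels, kernel = 3, groups = heads, bias = bias),
    batchnorm(channels),
    act_layer("relu"),
    conv2d(channels, channels, kernel = 1, bias = bias)
  )
  if (proj_norm) layers <- c(layers, list(batchnorm(channels)))
  self$body <- do.call(sequential, layers)
  self$children <- list(self$body)
  self$forward <- function(x, train = FALSE) {
    if (ncol(x) != channels) {
      stop(sprintf(
        "MHCA block expects %d channels, got %d", channels, ncol(x)
      ), call. = FALSE)
    }
    self$body$forward(x, train)
  }
  self$backward <- function(dy) self$body$backward(dy)
  self
}

#' Apply multi-head convolutional attention
#'
#' @param x an [fmap].
#' @param params module from [mhca_params()].
#' @param train logical; training mode (batch statistics in normalization).
#' @return an [fmap] of identical spatial dimensions.
#' @export
mhca_forward <- function(x, params, train = FALSE) params$forward(x, train)

#' Efficient self-attention parameters
#'
#' Standard multi-head scaled dot-product self-attention over the spatial
#' tokens, with keys and values computed from an average-pooled (stride
#' `pool_stride`) copy of the input to reduce the quadratic token cost. With
#' `pool_stride = 1` the pooling is the identity and the layer is exactly
#' multi-head self-attention.
#'
#' @param channels token embedding width; must be divisible by `heads`.
#' @param heads number of attention heads.
#' @param pool_stride stride of the average-pool applied before the key/value
#'   projections.
#' @param qkv_bias,proj_bias biases on the projections (off by default).
#' @param pool_norm batch-normalize pooled tokens (only when
#'   `pool_stride > 1`).
#' @return an ESA module usable with [esa_forward()].
#' @export
esa_params <- function(channels, heads = max(1L, channels %/% 32L),
                       pool_stride = 1, qkv_bias = FALSE, proj_bias = FALSE,
                       pool_norm = TRUE) {
  stopifnot(pool_stride >= 1)
  if (heads < 1 || channels %% heads != 0) {
    stop(sprintf(
      "ESA block with %d channels cannot use %d heads: channels must be divisible by heads",
      channels, heads
    ), call. = FALSE)
  }
  self <- new_layer("esa")
  self$channels <- channels
  self$heads <- as.integer(heads)
  self$head_dim <- channels %/% heads
  self$pool_stride <- as.integer(pool_stride)
  self$q <- linear(channels, channels, bias = qkv_bias)
  self$k <- linear(channels, channels, bias = qkv_bias)
  self$v <- linear(channels, channels, bias = qkv_bias)
  self$proj <- linear(channels, channels, bias = proj_bias)
  self$pool <- avgpool2d(pool_stride)
  self$children <- list(self$q, self$k, self$v, self$proj, self$pool)
  if (pool_stride > 1 && pool_norm) {
    self$pool_bn <- batchnorm(channels)
    self$children <- c(self$children, list(self$pool_bn))
  }

  self$forward <- function(x, train = FALSE) {
    n <- attr(x, "n"); h <- attr(x, "h"); w <- attr(x, "w")
    tokens <- h * w
    xp <- self$pool$forward(x, train)
    if (!is.null(self$pool_bn)) xp <- self$pool_bn$forward(xp, train)
    tp <- attr(xp, "h") * attr(xp, "w")
    Q <- self$q$forward(unclass(x), train)
    K <- self$k$forward(unclass(xp), train)
    V <- self$v$forward(unclass(xp), train)
    d <- self$head_dim
    scale <- 1 / sqrt(d)
    O <- matrix(0, n * tokens, channels)
    A <- vector("list", n * self$heads)
    for (b in seq_len(n)) {
      rq <- ((b - 1) * tokens + 1):(b * tokens)
      rk <- ((b - 1) * tp + 1):(b * tp)
      for (hh in seq_len(self$heads)) {
        cols <- ((hh - 1) * d + 1):(hh * d)
        S <- (Q[rq, cols, drop = FALSE] %*% t(K[rk, cols, drop = FALSE])) * scale
        S <- S - apply(S, 1, max)
        E <- exp(S)
        Ab <- E / rowSums(E)
        O[rq, cols] <- Ab %*% V[rk, cols, drop = FALSE]
        A[[(b - 1) * self$heads + hh]] <- Ab
      }
    }
    y <- self$proj$forward(O, train)
    self$cache <- list(
      x = x, xp = xp, Q = Q, K = K, V = V, A = A,
      tokens = tokens, tp = tp, n = n
    )
    fmap_like(y, x)
  }

  self$backward <- function(dy) {
    cc <- self$cache
    dO <- self$proj$backward(unclass(dy))
    d <- self$head_dim
    scale <- 1 / sqrt(d)
    n <- cc$n; tokens <- cc$tokens; tp <- cc$tp
    dQ <- matrix(0, n * tokens, channels)
    dK <- matrix(0, n * tp, channels)
    dV <- matrix(0, n * tp, channels)
    for (b in seq_len(n)) {
      rq <- ((b - 1) * tokens + 1):(b * tokens)
      rk <- ((b - 1) * tp + 1):(b * tp)
      for (hh in seq_len(self$heads)) {
        cols <- ((hh - 1) * d + 1):(hh * d)
        Ab <- cc$A[[(b - 1) * self$heads + hh]]
        dOb <- dO[rq, cols, drop = FALSE]
        dA <- dOb %*% t(cc$V[rk, cols, drop = FALSE])
        dV[rk, cols] <- crossprod(Ab, dOb)
        dS <- Ab * (dA - rowSums(dA * Ab))
        dQ[rq, cols] <- (dS %*% cc$K[rk, cols, drop = FALSE]) * scale
        dK[rk, cols] <- (crossprod(dS, cc$Q[rq, cols, drop = FALSE])) * scale
      }
    }
    dx <- self$q$backward(dQ)
    dxp <- self$k$backward(dK) + self$v$backward(dV)
    dxp <- fmap_like(dxp, cc$xp)
    if (!is.null(self$pool_bn)) dxp <- self$pool_bn$backward(dxp)
    dx <- dx + unclass(self$pool$backward(dxp))
    x <- cc$x
    self$cache <- NULL
    fmap_like(dx, x)
  }
  self
}

#' Apply efficient self-attention
#'
#' @param x an [fmap]; the spatial positions are the attention tokens.
#' @param params module from [esa_params()].
#' @param train logical; training mode.
#' @return an [fmap] with the same spatial dimensions as `x`.
#' @export
esa_forward <- function(x, params, train = FALSE) params$forward(x, train)
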