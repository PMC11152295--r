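# Core differentiable layers. Every layer is an environment carrying its
# parameters, gradient accumulators and cached activations; forward/backward
# are explicit so no external autograd framework is needed. Feature maps use
# the token-matrix representation of fmap().

new_layer <- function(type) {
  self <- new.env(parent = emptyenv())
  self$type <- type
  self$params <- list()
  self$grads <- list()
  self$children <- list()
  class(self) <- "osn_layer"
  self
}

#' @export
print.osn_layer <- function(x, ...) {
  cat(sprintf("<layer:%s params=%d>\n", x$type, n_layer_params(x)))
  invisible(x)
}

# depth-first list of leaf layers holding parameters
collect_layers <- function(layer) {
  out <- list()
  if (length(layer$params)) out <- list(layer)
  for (ch in layer$children) out <- c(out, collect_layers(ch))
  out
}

n_layer_params <- function(layer) {
  sum(vapply(collect_layers(layer), function(l) {
    sum(vapply(l$params, length, numeric(1)))
  }, numeric(1)))
}

zero_grads <- function(layer) {
  for (l in collect_layers(layer)) {
    l$grads <- lapply(l$params, function(p) {
      if (is.null(dim(p))) numeric(length(p)) else array(0, dim = dim(p))
    })
  }
  invisible(NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---- convolution index maps (memoized) -------------------------------------

.conv_cache <- new.env(parent = emptyenv())

# Row indices into the token matrix for each kernel tap; 0 marks zero padding.
# Returns list(idx = (n*ho*wo) x k^2 integer matrix, ho, wo). `ceil` gives the
# ceil-mode output size used by pooling.
conv_index <- function(n, h, w, k, stride, pad, ceil = FALSE) {
  key <- paste(n, h, w, k, stride, pad, ceil, sep = "_")
  hit <- .conv_cache[[key]]
  if (!is.null(hit)) return(hit)
  rnd <- if (ceil) ceiling else floor
  ho <- as.integer(rnd((h + 2 * pad - k) / stride) + 1)
  wo <- as.integer(rnd((w + 2 * pad - k) / stride) + 1)
  io <- rep(rep(seq_len(ho), each = wo), times = n)
  jo <- rep(rep(seq_len(wo), times = ho), times = n)
  nn <- rep(seq_len(n), each = ho * wo)
  idx <- matrix(0L, nrow = n * ho * wo, ncol = k * k)
  t <- 0L
  for (ti in seq_len(k)) {
    for (tj in seq_len(k)) {
      t <- t + 1L
      ii <- (io - 1L) * stride + ti - pad
      jj <- (jo - 1L) * stride + tj - pad
      ok <- ii >= 1L & ii <= h & jj >= 1L & jj <= w
      v <- integer(length(ii))
      v[ok] <- (nn[ok] - 1L) * (h * w) + (ii[ok] - 1L) * w + jj[ok]
      idx[, t] <- v
    }
  }
  res <- list(idx = idx, ho = ho, wo = wo)
  .conv_cache[[key]] <- res
  res
}

init_weight <- function(fan_in, dims) {
  sd <- sqrt(2 / fan_in)
  array(stats::rnorm(prod(dims), sd = sd), dim = dims)
}

# ---- conv2d ----------------------------------------------------------------

# 'same' padding for odd kernels; weight stored as (k^2 * cin_g) x cout with
# tap-major row order; output channel columns are contiguous per group.
conv2d <- function(cin, cout, kernel = 1, stride = 1, groups = 1, bias = TRUE) {
  stopifnot(kernel %in% c(1L, 2L, 3L), stride %in% c(1L, 2L),
            cin %% groups == 0, cout %% groups == 0)
  self <- new_layer("conv2d")
  cin_g <- cin %/% groups
  cout_g <- cout %/% groups
  self$cin <- cin; self$cout <- cout; self$kernel <- as.integer(kernel)
  self$stride <- as.integer(stride); self$groups <- as.integer(groups)
  self$pad <- kernel %/% 2L
  self$params$W <- init_weight(kernel^2 * cin_g, c(kernel^2 * cin_g, cout))
  if (bias) self$params$b <- numeric(cout)
  self$depthwise <- (groups == cin && cin == cout)

  self$forward <- function(x, train = FALSE) {
    stopifnot(ncol(x) == cin)
    n <- attr(x, "n"); h <- attr(x, "h"); w <- attr(x, "w")
    k2 <- self$kernel^2
    W <- self$params$W
    if (self$kernel == 1L && self$stride == 1L && groups == 1L) {
      ci <- NULL
      y <- unclass(x) %*% W
      self$cache <- list(x = x, ci = NULL)
    } else if (self$depthwise) {
      ci <- conv_index(n, h, w, self$kernel, self$stride, self$pad)
      x0 <- rbind(0, unclass(x))
      y <- matrix(0, nrow(ci$idx), cout)
      for (t in seq_len(k2)) {
        xt <- x0[ci$idx[, t] + 1L, , drop = FALSE]
        y <- y + xt * rep(W[t, ], each = nrow(xt))
      }
      self$cache <- list(x = x, ci = ci, x0 = x0)
    } else {
      ci <- conv_index(n, h, w, self$kernel, self$stride, self$pad)
      x0 <- rbind(0, unclass(x))
      P <- vector("list", groups)
      y <- matrix(0, nrow(ci$idx), cout)
      for (g in seq_len(groups)) {
        chg <- ((g - 1L) * cin_g + 1L):(g * cin_g)
        og <- ((g - 1L) * cout_g + 1L):(g * cout_g)
        Pg <- matrix(0, nrow(ci$idx), k2 * cin_g)
        for (t in seq_len(k2)) {
          Pg[, ((t - 1L) * cin_g + 1L):(t * cin_g)] <-
            x0[ci$idx[, t] + 1L, chg, drop = FALSE]
        }
        y[, og] <- Pg %*% W[, og, drop = FALSE]
        P[[g]] <- Pg
      }
      self$cache <- list(x = x, ci = ci, P = P)
    }
    if (!is.null(self$params$b)) y <- y + rep(self$params$b, each = nrow(y))
    ho <- if (is.null(ci)) attr(x, "h") else ci$ho
    wo <- if (is.null(ci)) attr(x, "w") else ci$wo
    fmap(y, n, ho, wo)
  }

  self$backward <- function(dy) {
    x <- self$cache$x
    ci <- self$cache$ci
    n <- attr(x, "n"); h <- attr(x, "h"); w <- attr(x, "w")
    k2 <- self$kernel^2
    W <- self$params$W
    dy <- unclass(dy)
    if (!is.null(self$params$b)) {
      self$grads$b <- self$grads$b + colSums(dy)
    }
    if (is.null(ci)) { # pure 1x1 stride-1 ungrouped
      self$grads$W <- self$grads$W + crossprod(unclass(x), dy)
      dx <- dy %*% t(W)
      return(fmap_like(dx, x))
    }
    dx <- matrix(0, nrow(x), cin)
    if (self$depthwise) {
      x0 <- self$cache$x0
      dW <- self$grads$W
      for (t in seq_len(k2)) {
        xt <- x0[ci$idx[, t] + 1L, , drop = FALSE]
        dW[t, ] <- dW[t, ] + colSums(xt * dy)
        rows <- ci$idx[, t]
        ok <- rows > 0L
        contrib <- dy[ok, , drop = FALSE] * rep(W[t, ], each = sum(ok))
        dx[rows[ok], ] <- dx[rows[ok], , drop = FALSE] + contrib
      }
      self$grads$W <- dW
    } else {
      for (g in seq_len(groups)) {
        chg <- ((g - 1L) * cin_g + 1L):(g * cin_g)
        og <- ((g - 1L) * cout_g + 1L):(g * cout_g)
        Pg <- self$cache$P[[g]]
        dyg <- dy[, og, drop = FALSE]
        self$grads$W[, og] <- self$grads$W[, og, drop = FALSE] + crossprod(Pg, dyg)
        dPg <- dyg %*% t(W[, og, drop = FALSE])
        for (t in seq_len(k2)) {
          rows <- ci$idx[, t]
          ok <- rows > 0L
          dx[rows[ok], chg] <- dx[rows[ok], chg, drop = FALSE] +
            dPg[ok, ((t - 1L) * cin_g + 1L):(t * cin_g), drop = FALSE]
        }
      }
    }
    self$cache <- NULL
    fmap_like(dx, x)
  }
  self
}

# ---- batch normalization ---------------------------------------------------

batchnorm <- function(C, eps = 1e-5, momentum = 0.1) {
  self <- new_layer("batchnorm")
  self$C <- C; self$eps <- eps; self$momentum <- momentum
  self$params$gamma <- rep(1, C)
  self$params$beta <- rep(0, C)
  self$running_mean <- rep(0, C)
  self$running_var <- rep(1, C)

  self$forward <- function(x, train = FALSE) {
    xm <- unclass(x)
    if (train) {
      mu <- colMeans(xm)
      xc <- xm - rep(mu, each = nrow(xm))
      va <- colMeans(xc * xc) # biased
      m <- nrow(xm)
      unbiased <- if (m > 1) va * m / (m - 1) else va
      self$running_mean <- (1 - self$momentum) * self$running_mean + self$momentum * mu
      self$running_var <- (1 - self$momentum) * self$running_var + self$momentum * unbiased
    } else {
      mu <- self$running_mean
      va <- self$running_var
      xc <- xm - rep(mu, each = nrow(xm))
    }
    istd <- 1 / sqrt(va + self$eps)
    xhat <- xc * rep(istd, each = nrow(xm))
    y <- xhat * rep(self$params$gamma, each = nrow(xm)) +
      rep(self$params$beta, each = nrow(xm))
    self$cache <- list(xhat = xhat, istd = istd, train = train, x = x)
    fmap_like(y, x)
  }

  self$backward <- function(dy) {
    dy <- unclass(dy)
    xhat <- self$cache$xhat
    istd <- self$cache$istd
    m <- nrow(dy)
    self$grads$gamma <- self$grads$gamma + colSums(dy * xhat)
    self$grads$beta <- self$grads$beta + colSums(dy)
    gi <- self$params$gamma * istd
    if (self$cache$train) {
      mg <- colMeans(dy)
      mgx <- colMeans(dy * xhat)
      dx <- (dy - rep(mg, each = m) - xhat * rep(mgx, each = m)) *
        rep(gi, each = m)
    } else {
      dx <- dy * rep(gi, each = m)
    }
    x <- self$cache$x
    self$cache <- NULL
    fmap_like(dx, x)
  }
  self
}

# ---- activations -----------------------------------------------------------

act_layer <- function(kind = c("relu", "hswish", "hsigmoid")) {
  kind <- match.arg(kind)
  self <- new_layer(paste0("act_", kind))
  self$forward <- function(x, train = FALSE) {
    xm <- unclass(x)
    y <- switch(kind,
      relu = pmax(xm, 0),
      hswish = xm * pmin(pmax(xm + 3, 0), 6) / 6,
      hsigmoid = pmin(pmax(xm + 3, 0), 6) / 6
    )
    self$cache <- list(x = x)
    fmap_like(y, x)
  }
  self$backward <- function(dy) {
    xm <- unclass(self$cache$x)
    d <- switch(kind,
      relu = (xm > 0) * 1,
      hswish = ifelse(xm <= -3, 0, ifelse(xm >= 3, 1, (2 * xm + 3) / 6)),
      hsigmoid = ifelse(xm > -3 & xm < 3, 1 / 6, 0)
    )
    dx <- unclass(dy) * d
    x <- self$cache$x
    self$cache <- NULL
    fmap_like(dx, x)
  }
  self
}

# ---- average pooling (kernel = stride, ceil mode, valid-count averaging) ---

avgpool2d <- function(stride) {
  self <- new_layer("avgpool2d")
  self$stride <- as.integer(stride)
  self$forward <- function(x, train = FALSE) {
    if (self$stride == 1L) {
      self$cache <- list(identity = TRUE, x = x)
      return(x)
    }
    k <- self$stride
    n <- attr(x, "n"); h <- attr(x, "h"); w <- attr(x, "w")
    ci <- conv_index(n, h, w, k, k, 0L, ceil = TRUE)
    x0 <- rbind(0, unclass(x))
    y <- matrix(0, nrow(ci$idx), ncol(x))
    cnt <- rowSums(ci$idx > 0L)
    for (t in seq_len(k^2)) y <- y + x0[ci$idx[, t] + 1L, , drop = FALSE]
    y <- y / cnt
    self$cache <- list(identity = FALSE, x = x, ci = ci, cnt = cnt)
    fmap(y, n, ci$ho, ci$wo)
  }
  self$backward <- function(dy) {
    if (isTRUE(self$cache$identity)) {
      x <- self$cache$x; self$cache <- NULL
      return(dy)
    }
    x <- self$cache$x
    ci <- self$cache$ci
    k <- self$stride
    dyn <- unclass(dy) / self$cache$cnt
    dx <- matrix(0, nrow(x), ncol(x))
    for (t in seq_len(k^2)) {
      rows <- ci$idx[, t]
      ok <- rows > 0L
      dx[rows[ok], ] <- dx[rows[ok], , drop = FALSE] + dyn[ok, , drop = FALSE]
    }
    self$cache <- NULL
    fmap_like(dx, x)
  }
  self
}

# ---- global average pooling: fmap -> (n x C) matrix ------------------------

global_avgpool <- function() {
  self <- new_layer("gap")
  self$forward <- function(x, train = FALSE) {
    n <- attr(x, "n"); hw <- attr(x, "h") * attr(x, "w")
    grp <- rep(seq_len(n), each = hw)
    y <- rowsum(unclass(x), grp) / hw
    rownames(y) <- NULL
    self$cache <- list(x = x)
    y
  }
  self$backward <- function(dy) {
    x <- self$cache$x
    n <- attr(x, "n"); hw <- attr(x, "h") * attr(x, "w")
    dx <- (unclass(dy) / hw)[rep(seq_len(n), each = hw), , drop = FALSE]
    self$cache <- NULL
    fmap_like(dx, x)
  }
  self
}

# ---- linear (dense) on plain matrices --------------------------------------

linear <- function(din, dout, bias = TRUE) {
  self <- new_layer("linear")
  self$params$W <- init_weight(din, c(din, dout))
  if (bias) self$params$b <- numeric(dout)
  self$forward <- function(x, train = FALSE) {
    y <- x %*% self$params$W
    if (!is.null(self$params$b)) y <- y + rep(self$params$b, each = nrow(y))
    self$cache <- list(x = x)
    y
  }
  self$backward <- function(dy) {
    x <- self$cache$x
    self$grads$W <- self$grads$W + crossprod(x, dy)
    if (!is.null(self$params$b)) self$grads$b <- self$grads$b + colSums(dy)
    self$cache <- NULL
    dy %*% t(self$params$W)
  }
  self
}

# ---- squeeze-excitation gate -----------------------------------------------

se_layer <- function(H, reduced) {
  self <- new_layer("se")
  self$fc1 <- linear(H, reduced)
  self$fc2 <- linear(reduced, H)
  self$children <- list(self$fc1, self$fc2)
  self$forward <- function(x, train = FALSE) {
    n <- attr(x, "n"); hw <- attr(x, "h") * attr(x, "w")
    grp <- rep(seq_len(n), each = hw)
    z <- rowsum(unclass(x), grp) / hw
    rownames(z) <- NULL
    a1 <- self$fc1$forward(z, train)
    r1 <- pmax(a1, 0)
    a2 <- self$fc2$forward(r1, train)
    g <- pmin(pmax(a2 + 3, 0), 6) / 6
    gexp <- g[grp, , drop = FALSE]
    y <- unclass(x) * gexp
    self$cache <- list(x = x, a1 = a1, a2 = a2, g = g, grp = grp, hw = hw)
    fmap_like(y, x)
  }
  self$backward <- function(dy) {
    cc <- self$cache
    x <- cc$x
    dy <- unclass(dy)
    gexp <- cc$g[cc$grp, , drop = FALSE]
    dx <- dy * gexp
    dg <- rowsum(dy * unclass(x), cc$grp)
    da2 <- dg * ifelse(cc$a2 > -3 & cc$a2 < 3, 1 / 6, 0)
    dr1 <- self$fc2$backward(da2)
    da1 <- dr1 * (cc$a1 > 0)
    dz <- self$fc1$backward(da1)
    dx <- dx + (dz / cc$hw)[cc$grp, , drop = FALSE]
    self$cache <- NULL
    fmap_like(dx, x)
  }
  self
}

# ---- stochastic depth on residual branches ---------------------------------

droppath <- function(p) {
  self <- new_layer("droppath")
  self$p <- p
  self$forward <- function(x, train = FALSE) {
    if (!train || self$p <= 0) {
      self$cache <- list(mask = NULL, x = x)
      return(x)
    }
    n <- attr(x, "n"); hw <- attr(x, "h") * attr(x, "w")
    keep <- stats::rbinom(n, 1, 1 - self$p) / (1 - self$p)
    mask <- rep(keep, each = hw)
    self$cache <- list(mask = mask, x = x)
    fmap_like(unclass(x) * mask, x)
  }
  self$backward <- function(dy) {
    mask <- self$cache$mask
    x <- self$cache$x
    self$cache <- NULL
    if (is.null(mask)) return(dy)
    fmap_like(unclass(dy) * mask, x)
  }
  self
}

# ---- sequential container --------------------------------------------------

sequential <- function(...) {
  self <- new_layer("sequential")
  self$children <- list(...)
  self$forward <- function(x, train = FALSE) {
    for (ch in self$children) x <- ch$forward(x, train)
    x
  }
  self$backward <- function(dy) {
    for (ch in rev(self$children)) dy <- ch$backward(dy)
    dy
  }
  self
}
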