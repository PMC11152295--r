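# Building blocks and the declarative model builder.

test_that("MHCA preserves spatial shape and validates head divisibility", {
  set.seed(1)
  p <- mhca_params(96, heads = 3)
  x <- fmap(matrix(rnorm(2 * 56 * 56 * 96, sd = 0.1), ncol = 96), 2, 56, 56)
  y <- mhca_forward(x, p)
  expect_equal(dim(y), dim(x))
  expect_equal(attr(y, "h"), 56)
  expect_equal(attr(y, "w"), 56)
  expect_error(mhca_params(96, heads = 5), "divisible")
  expect_error(mhca_forward(fmap(matrix(0, 4, 7), 1, 2, 2), mhca_params(8, 2)),
               "expects 8 channels")
})

test_that("MHCA with identity projections reduces to the 3x3 aggregation", {
  # one head, output projection = identity, normalization at its resting
  # state: the block computes exactly the learned weighted sum of each token
  # with its 8 neighbours (positive inputs keep ReLU inactive as a gate)
  set.seed(2)
  C <- 3
  p <- zero_bn_eps(mhca_params(C, heads = 1, proj_norm = FALSE, bias = FALSE))
  agg <- array(rnorm(9 * C * C, sd = 0.2)^2, dim = c(9 * C, C)) # positive
  p$body$children[[1]]$params$W <- agg
  p$body$children[[4]]$params$W <- diag(C)
  x <- fmap(matrix(runif(1 * 3 * 3 * C), ncol = C), 1, 3, 3)
  y <- mhca_forward(x, p)
  # independent dense 3x3 convolution oracle over the 3x3 grid
  xi <- fmap_to_array(x)[1, , , ]
  oracle <- array(0, dim = c(C, 3, 3))
  for (i in 1:3) for (j in 1:3) {
    acc <- numeric(C)
    t <- 0
    for (di in -1:1) for (dj in -1:1) {
      t <- t + 1
      ii <- i + di; jj <- j + dj
      v <- if (ii >= 1 && ii <= 3 && jj >= 1 && jj <= 3) xi[, ii, jj] else numeric(C)
      acc <- acc + as.numeric(v %*% agg[((t - 1) * C + 1):(t * C), ])
    }
    oracle[, i, j] <- pmax(acc, 0) # ReLU (all sums positive anyway)
  }
  expect_equal(as.numeric(fmap_to_array(y)[1, , , ]), as.numeric(oracle),
               tolerance = 1e-10)
})

test_that("hand-evaluated MHCA on a 2x2 grid matches direct arithmetic", {
  set.seed(3)
  C <- 4
  p <- zero_bn_eps(mhca_params(C, heads = 2, proj_norm = FALSE, bias = FALSE))
  x <- fmap(matrix(abs(rnorm(1 * 2 * 2 * C)), ncol = C), 1, 2, 2)
  y <- mhca_forward(x, p)
  # direct composition: per-head grouped 3x3 aggregation over all 4 tokens,
  # ReLU, then the 1x1 output projection
  W <- p$body$children[[1]]$params$W   # (9 * 2) x 4, tap-major per group
  Wo <- p$body$children[[4]]$params$W
  xi <- fmap_to_array(x)[1, , , , drop = FALSE]
  taps <- expand.grid(dj = -1:1, di = -1:1) # tap order: ti-major in weights
  manual <- matrix(0, 4, C) # tokens x channels
  tok <- 0
  for (i in 1:2) for (j in 1:2) {
    tok <- tok + 1
    for (g in 1:2) {
      chg <- ((g - 1) * 2 + 1):(g * 2)
      acc <- numeric(2)
      for (t in 1:9) {
        di <- ((t - 1) %/% 3) - 1; dj <- ((t - 1) %% 3) - 1
        ii <- i + di; jj <- j + dj
        v <- if (ii >= 1 && ii <= 2 && jj >= 1 && jj <= 2) {
          xi[1, chg, ii, jj]
        } else c(0, 0)
        acc <- acc + as.numeric(v %*% W[((t - 1) * 2 + 1):(t * 2), chg])
      }
      manual[tok, chg] <- acc
    }
  }
  manual <- pmax(manual, 0) %*% Wo
  got <- fmap_to_array(y)[1, , , ]
  # token (i, j) of the manual loop corresponds to row-major raster order
  got_tokens <- rbind(got[, 1, 1], got[, 1, 2], got[, 2, 1], got[, 2, 2])
  expect_equal(got_tokens, manual, tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("LFFN is shape preserving and zero weights give the pure residual", {
  set.seed(4)
  p <- lffn_params(192, expansion = 3)
  x <- fmap(matrix(rnorm(2 * 28 * 28 * 192, sd = 0.1), ncol = 192), 2, 28, 28)
  y <- lffn_forward(x, p)
  expect_equal(dim(y), dim(x))
  for (l in octstitch:::collect_layers(p)) {
    for (pn in names(l$params)) l$params[[pn]][] <- 0
  }
  # with the squeeze-excitation gate the branch is 0 * gate = 0 everywhere
  y0 <- lffn_forward(x, p)
  expect_equal(unclass(y0), unclass(x), tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("LFFN with fixed small weights matches a hand-computed conv chain", {
  C <- 2; H <- 4
  p <- zero_bn_eps(lffn_params(C, expansion = 2, se = FALSE, bias = FALSE))
  layers <- octstitch:::collect_layers(p)
  # layers: conv1x1 (C->H), bn(H), dw3x3, bn(H), conv1x1 (H->C), bn(C)
  W1 <- matrix(seq(0.1, 0.8, by = 0.1), C, H)
  Wd <- matrix(seq(-0.4, 0.5, length.out = 9 * H), 9, H)
  W2 <- matrix(seq(-0.2, 0.5, length.out = H * C), H, C)
  layers[[1]]$params$W <- W1
  layers[[3]]$params$W <- Wd
  layers[[5]]$params$W <- W2
  x <- fmap(matrix(seq(0.05, 0.8, length.out = 8), ncol = C), 1, 2, 2)
  y <- lffn_forward(x, p) # eval mode: normalizations are identities
  hsw <- function(v) v * pmin(pmax(v + 3, 0), 6) / 6
  a <- hsw(unclass(x) %*% W1) # (4 tokens x H)
  A <- array(0, c(2, 2, H))
  for (i in 1:2) for (j in 1:2) A[i, j, ] <- a[(i - 1) * 2 + j, ]
  b <- array(0, c(2, 2, H))
  for (i in 1:2) for (j in 1:2) for (c2 in 1:H) {
    acc <- 0
    for (t in 1:9) {
      di <- ((t - 1) %/% 3) - 1; dj <- ((t - 1) %% 3) - 1
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && ii <= 2 && jj >= 1 && jj <= 2) {
        acc <- acc + A[ii, jj, c2] * Wd[t, c2]
      }
    }
    b[i, j, c2] <- acc
  }
  bm <- matrix(0, 4, H)
  for (i in 1:2) for (j in 1:2) bm[(i - 1) * 2 + j, ] <- b[i, j, ]
  manual <- unclass(x) + hsw(bm) %*% W2
  expect_equal(unclass(y), manual, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("ESA with pool stride 1 equals brute-force multi-head attention", {
  set.seed(5)
  for (heads in c(1, 2)) {
    C <- 4
    p <- esa_params(C, heads = heads, pool_stride = 1)
    x <- fmap(matrix(rnorm(2 * 4 * 4 * C), ncol = C), 2, 4, 4) # 16 tokens
    y <- esa_forward(x, p)
    d <- C / heads
    manual <- matrix(0, nrow(x), C)
    for (b in 1:2) {
      rows <- ((b - 1) * 16 + 1):(b * 16)
      X <- unclass(x)[rows, ]
      Q <- X %*% p$q$params$W; K <- X %*% p$k$params$W; V <- X %*% p$v$params$W
      for (hh in seq_len(heads)) {
        cols <- ((hh - 1) * d + 1):(hh * d)
        S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(d)
        A <- exp(S) / rowSums(exp(S))
        manual[rows, cols] <- A %*% V[, cols, drop = FALSE]
      }
    }
    manual <- manual %*% p$proj$params$W
    expect_equal(unclass(y), manual, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("ESA pools keys/values by the stated stride", {
  set.seed(6)
  p <- esa_params(384, heads = 12, pool_stride = 2)
  x <- fmap(matrix(rnorm(2 * 14 * 14 * 384, sd = 0.05), ncol = 384), 2, 14, 14)
  y <- esa_forward(x, p)
  expect_equal(p$cache$tp, 49) # 14x14 tokens pooled to 7x7 keys/values
  expect_equal(dim(y), dim(x))
  expect_equal(attr(y, "h"), 14)
})

test_that("ECB and LTB blocks propagate shapes per the stage table", {
  set.seed(7)
  conv <- medvit_conventions()
  # stage-2 LTB: 192 -> 256 channels at 28x28
  ltb <- ltb_block(192, 256, pool_stride = 4, conv = conv)
  x <- fmap(matrix(rnorm(2 * 28 * 28 * 192, sd = 0.05), ncol = 192), 2, 28, 28)
  y <- ltb_forward(x, ltb)
  expect_equal(ncol(y), 256)
  expect_equal(attr(y, "h"), 28)
  # dropout off + eval mode: deterministic across calls
  y2 <- ltb_forward(x, ltb)
  expect_identical(unclass(y), unclass(y2))
  # stage-3 stack: ECB384 x4 then LTB512 on 14x14
  blocks <- c(lapply(1:4, function(i) ecb_block(384, 384, conv)),
              list(ltb_block(384, 512, 2, conv)))
  z <- fmap(matrix(rnorm(1 * 14 * 14 * 384, sd = 0.05), ncol = 384), 1, 14, 14)
  for (b in blocks) z <- b$forward(z)
  expect_equal(ncol(z), 512)
  expect_equal(attr(z, "h"), 14)
  expect_equal(attr(z, "w"), 14)
})

test_that("the builder halves spatial size per stage (stem stride 4)", {
  m <- fixture_reduced_model("reduced_micro")
  # reduced spec at 32x32: stem stride 4 then halving per stage
  x <- fmap(matrix(runif(2 * 32 * 32 * 3), ncol = 3), 2, 32, 32)
  sizes <- integer(0)
  z <- m$stem$forward(x)
  expect_equal(attr(z, "h"), 8)
  for (s in 1:4) {
    z <- m$stage_pe[[s]]$forward(z)
    for (b in which(m$block_info$stage == s)) z <- m$blocks[[b]]$forward(z)
    sizes <- c(sizes, attr(z, "h"))
  }
  expect_equal(sizes, c(8, 4, 2, 1))
  logits <- m$forward(x)
  expect_equal(dim(logits), c(2, 3))
})

test_that("micro and tiny differ only in stage-3 repeat and path dropout", {
  micro <- medvit_spec("micro")
  tiny <- medvit_spec("tiny")
  expect_equal(micro$stages[[3]]$group_repeat, 1L)
  expect_equal(tiny$stages[[3]]$group_repeat, 2L)
  expect_equal(micro$path_dropout, 0.05)
  expect_equal(tiny$path_dropout, 0.1)
  micro$stages[[3]]$group_repeat <- 2L
  micro$path_dropout <- 0.1
  micro$name <- "tiny"
  expect_identical(micro, tiny)
})

test_that("specifications validate their invariants and round-trip as JSON", {
  spec <- medvit_spec("micro")
  bad <- spec
  bad$stages <- bad$stages[1:3]
  expect_error(octstitch:::validate_medvit_spec(bad), "4 stages")
  expect_error(medvit_spec("micro", num_classes = 1), "num_classes")
  f <- tempfile(fileext = ".json")
  spec_to_json(spec, f)
  spec2 <- spec_from_json(f)
  expect_identical(spec, spec2)
})

test_that("model state save/load round-trips through a checkpoint", {
  m <- build_medvit(medvit_spec("reduced_micro"), seed = 11)
  dir <- tempfile()
  save_checkpoint(m, dir, list(epoch = 3L, best_val_auc = 0.91))
  loaded <- load_checkpoint(dir)
  expect_identical(loaded$model$spec, m$spec)
  expect_equal(loaded$state$epoch, 3L)
  x <- fmap(matrix(runif(1 * 32 * 32 * 3), ncol = 3), 1, 32, 32)
  expect_equal(loaded$model$forward(x), m$forward(x), tolerance = 1e-12)
})
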