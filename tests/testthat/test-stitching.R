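# Candidate enumeration, least-squares stitch initialization, stitched
# forward passes and space training.

test_that("paired enumeration is the k=2, s=1 sliding window", {
  expect_equal(enumerate_paired(3, 3), data.frame(n = 1:2, m = 2:3))
  expect_equal(nrow(enumerate_paired(1, 1)), 0)
  # brute-force window oracle: windows (start .. start+1), count = L - 1
  for (L in 2:6) {
    windows <- lapply(seq_len(L - 1), function(s) c(s, s + 1))
    got <- enumerate_paired(L, L)
    expect_equal(nrow(got), length(windows))
    expect_equal(got$n, vapply(windows, `[`, numeric(1), 1))
    expect_equal(got$m, vapply(windows, `[`, numeric(1), 2))
  }
  expect_error(enumerate_paired(3, 4), "unpaired")
})

test_that("unpaired enumeration forms proportional buckets", {
  # brute-force bucket oracle
  bucket_oracle <- function(la, lb) {
    out <- NULL
    for (j in seq_len(lb)) {
      n <- floor((j - 1) * la / lb) + 1
      m <- j + 1
      if (m <= lb) out <- rbind(out, data.frame(n = n, m = m))
    }
    out
  }
  got <- enumerate_unpaired(5, 10)
  expect_equal(got, bucket_oracle(5, 10), ignore_attr = TRUE)
  expect_equal(unname(table(factor(got$n, levels = 1:5))[1:4]), rep(2L, 4),
               ignore_attr = TRUE) # front blocks 1..4 cover 2 positions each
  expect_equal(nrow(got), 9) # ten raw assignments minus the one with m > 10
  got25 <- enumerate_unpaired(2, 5)
  expect_equal(got25, bucket_oracle(2, 5), ignore_attr = TRUE)
  expect_equal(as.integer(table(floor((seq_len(5) - 1) * 2 / 5) + 1)),
               c(3L, 2L)) # bucket sizes {3, 2}
  # equal lengths degenerate to the one-to-one paired alignment
  expect_equal(enumerate_unpaired(4, 4), enumerate_paired(4, 4))
  expect_error(enumerate_unpaired(5, 3), "shallower")
})

test_that("build_space composes stage-wise candidates and prunes odd indexes", {
  front <- stitch_anchor(fixture_reduced_model("reduced_micro", 1), 1L)
  back <- stitch_anchor(fixture_reduced_model("reduced_tiny", 2), 2L)
  raw <- build_space(front, back, prune = FALSE)
  # reduced stages: front (1,2,2,2) vs back (1,2,4,2) blocks
  # stage 1 depth 1 -> none; stage 2 paired -> 1; stage 3 unpaired (2,4) -> 3;
  # stage 4 paired -> 1
  expect_equal(nrow(raw$configs), 5)
  expect_equal(raw$configs$raw_id, 0:4)
  expect_equal(raw$configs$stage, c(2, 3, 3, 3, 4))
  pruned <- build_space(front, back, prune = TRUE)
  expect_equal(nrow(pruned$configs), ceiling(nrow(raw$configs) / 2))
  expect_equal(pruned$configs$raw_id, c(0L, 2L, 4L)) # odd raw ids dropped
  expect_equal(pruned$configs$config_id, 0:2)        # survivors re-indexed
  # stitch dimensions follow the cut/entry channels
  expect_equal(pruned$configs$d_in,
               front$cut_points$channels[pruned$configs$n_flat])
  expect_equal(pruned$configs$d_out,
               back$cut_points$channels[pruned$configs$m_flat - 1L])
})

test_that("least-squares stitch initialization solves the closed form", {
  set.seed(21)
  d <- 6; N <- 10 * d
  A <- matrix(rnorm(N * d), N, d)
  # self-stitch: B = A recovers the identity
  st <- init_stitch_least_squares(A, A)
  expect_equal(st$params$W, diag(d), tolerance = 1e-6, ignore_attr = TRUE)
  expect_equal(st$params$b, rep(0, d), tolerance = 1e-6)
  # planted solution with bias
  W0 <- matrix(rnorm(d * 4), d, 4)
  b0 <- rnorm(4)
  B <- A %*% W0 + rep(b0, each = N)
  st <- init_stitch_least_squares(A, B)
  expect_equal(st$params$W, W0, tolerance = 1e-5)
  expect_equal(st$params$b, b0, tolerance = 1e-5)
  # overdetermined noisy case: residual equals the normal-equations solution
  Bn <- B + matrix(rnorm(N * 4, sd = 0.3), N, 4)
  st <- init_stitch_least_squares(A, Bn)
  X <- cbind(A, 1)
  coef_ne <- solve(crossprod(X), crossprod(X, Bn))
  res_pkg <- norm(X %*% rbind(st$params$W, st$params$b) - Bn, "F")
  res_ne <- norm(X %*% coef_ne - Bn, "F")
  expect_equal(res_pkg, res_ne, tolerance = 1e-8)
  # optimality: random perturbations never do better on the fit batch
  set.seed(22)
  for (trial in 1:100) {
    Wp <- st$params$W + matrix(rnorm(d * 4, sd = 1e-2), d, 4)
    res_p <- norm(A %*% Wp + rep(st$params$b, each = N) - Bn, "F")
    expect_gte(res_p, res_pkg)
  }
  # degenerate input: rank deficiency warns and returns the min-norm fit
  Ad <- A
  Ad[, d] <- Ad[, 1]
  expect_warning(init_stitch_least_squares(Ad, Bn), "rank-deficient")
  expect_error(init_stitch_least_squares(A[1:5, ], Bn), "token count")
})

test_that("self-stitching a model reproduces its own logits at every cut", {
  m <- fixture_reduced_model("reduced_micro", 5)
  m2 <- octstitch:::clone_model(m)
  space <- build_space(stitch_anchor(m, 1L), stitch_anchor(m2, 2L),
                       prune = FALSE)
  set.seed(30)
  x <- fmap(matrix(runif(4 * 32 * 32 * 3), ncol = 3), 4, 32, 32)
  ref <- m$forward(x)
  for (i in seq_len(nrow(space$configs))) {
    cf <- space$configs[i, ]
    # identity stitch is only exact when the entry follows the cut directly
    if (cf$m_flat != cf$n_flat + 1L || cf$d_in != cf$d_out) next
    space$stitches[[i]]$params$W <- diag(cf$d_in)
    space$stitches[[i]]$params$b <- numeric(cf$d_out)
    space$stitches[[i]]$initialized <- TRUE
    got <- stitched_forward(x, space, cf$config_id)
    expect_equal(got, ref, tolerance = 1e-5, ignore_attr = TRUE)
  }
})

test_that("every configuration of a built space runs end to end", {
  front <- stitch_anchor(fixture_reduced_model("reduced_micro", 1), 1L)
  back <- stitch_anchor(fixture_reduced_model("reduced_tiny", 2), 2L)
  space <- build_space(front, back, prune = FALSE)
  expect_error(stitched_forward(fmap(matrix(0, 32 * 32, 3), 1, 32, 32),
                                space, 0), "not initialized")
  set.seed(31)
  imgs <- lapply(1:110, function(i) matrix(runif(32 * 32), 32, 32))
  # stage-4 cuts can be rank-deficient at this scale; min-norm fallback warns
  space <- suppressWarnings(init_space(space, imgs))
  x <- images_to_fmap(imgs[1:4], 3)
  for (cid in space$configs$config_id) {
    logits <- stitched_forward(x, space, cid)
    expect_equal(dim(logits), c(4, 3))
    expect_true(all(is.finite(logits)))
  }
  expect_error(stitched_forward(x, space, 99), "no configuration")
})

test_that("stitched networks count their assembled parameters correctly", {
  front <- stitch_anchor(fixture_reduced_model("reduced_micro", 1), 1L)
  back <- stitch_anchor(fixture_reduced_model("reduced_tiny", 2), 2L)
  space <- build_space(front, back, prune = FALSE)
  fi <- front$model$block_info
  bi <- back$model$block_info
  np <- octstitch:::n_layer_params
  for (i in seq_len(nrow(space$configs))) {
    cf <- space$configs[i, ]
    # independent accounting: walk every module on the assembled path
    expected <- np(front$model$stem)
    for (s in seq_len(cf$stage)) expected <- expected + np(front$model$stage_pe[[s]])
    for (b in seq_len(cf$n_flat)) expected <- expected + np(front$model$blocks[[b]])
    expected <- expected + cf$d_in * cf$d_out + cf$d_out # stitch W + b
    for (b in cf$m_flat:nrow(bi)) expected <- expected + np(back$model$blocks[[b]])
    for (s in setdiff(unique(bi$stage[bi$block >= cf$m_flat]), cf$stage)) {
      expected <- expected + np(back$model$stage_pe[[s]])
    }
    expected <- expected + np(back$model$head_norm) + np(back$model$fc)
    expect_equal(octstitch:::stitched_param_count(space, cf$config_id),
                 as.integer(expected))
  }
  manifest <- tempfile(fileext = ".csv")
  write_space_manifest(space, manifest)
  mf <- read.csv(manifest)
  expect_equal(nrow(mf), nrow(space$configs))
  expect_true(all(c("config_id", "stitch_params", "total_params") %in% names(mf)))
})

test_that("per-config calibration only touches statistics, reversibly", {
  ds <- fixture_dataset(64, 32, seed = 45)
  front <- stitch_anchor(octstitch:::clone_model(
    fixture_reduced_model("reduced_micro", 1)), 1L)
  back <- stitch_anchor(octstitch:::clone_model(
    fixture_reduced_model("reduced_tiny", 2)), 2L)
  sp <- build_space(front, back, prune = TRUE)
  imgs <- lapply(ds$images, normalize_image, params = normalize_params("NEH"))
  sp <- suppressWarnings(init_space(sp, imgs))
  w_before <- octstitch:::model_state(back$model)
  snap <- octstitch:::snapshot_bn_stats(list(front$model, back$model))
  calibrate_stitched(sp, 0, imgs)
  w_after <- octstitch:::model_state(back$model)
  # parameters unchanged; running statistics on the path changed
  expect_identical(lapply(w_before, `[[`, "params"),
                   lapply(w_after, `[[`, "params"))
  expect_false(identical(w_before, w_after))
  # stochastic-depth rates and momentum restored
  octstitch:::walk_layers_of_type(back$model, "batchnorm", function(l) {
    expect_equal(l$momentum, 0.1)
  })
  octstitch:::restore_bn_stats(snap)
  expect_identical(w_before, octstitch:::model_state(back$model))
  # calibrated evaluation is deterministic
  x <- images_to_fmap(imgs[1:4], 3)
  m1 <- octstitch:::evaluate_stitched(sp, 0, ds, normalize_params("NEH"),
                                      calibration_images = imgs)
  m2 <- octstitch:::evaluate_stitched(sp, 0, ds, normalize_params("NEH"),
                                      calibration_images = imgs)
  expect_identical(m1, m2)
})

test_that("space training is reproducible and reduces loss on one config", {
  ds <- fixture_dataset(64, 32, seed = 40)
  make_space <- function() {
    front <- stitch_anchor(octstitch:::clone_model(
      fixture_reduced_model("reduced_micro", 1)), 1L)
    back <- stitch_anchor(octstitch:::clone_model(
      fixture_reduced_model("reduced_tiny", 2)), 2L)
    sp <- build_space(front, back, prune = TRUE)
    imgs <- lapply(ds$images[1:60], normalize_image,
                   params = normalize_params("NEH"))
    suppressWarnings(init_space(sp, imgs))
  }
  run_weights <- function() {
    sp <- make_space()
    sp <- train_stitched(sp, ds, iterations = 6, batch_size = 16,
                         lr = 1e-3, augment = NULL, seed = 77)
    lapply(sp$stitches, function(s) s$params)
  }
  expect_identical(run_weights(), run_weights()) # bitwise determinism
  # degenerate single-config space: the one stitch trains every step and the
  # loss on a fixed batch decreases at a small learning rate
  front <- stitch_anchor(octstitch:::clone_model(
    fixture_reduced_model("reduced_micro", 1)), 1L)
  back <- stitch_anchor(octstitch:::clone_model(
    fixture_reduced_model("reduced_tiny", 2)), 2L)
  sp1 <- build_space(front, back, prune = TRUE)
  sp1$configs <- sp1$configs[1, , drop = FALSE]
  sp1$stitches <- sp1$stitches[1]
  imgs <- lapply(ds$images[1:60], normalize_image,
                 params = normalize_params("NEH"))
  sp1 <- suppressWarnings(init_space(sp1, imgs))
  fixed <- oct_dataset(ds$images[1:16], ds$labels[1:16])
  x <- images_to_fmap(lapply(fixed$images, normalize_image,
                             params = normalize_params("NEH")), 3)
  loss0 <- focal_loss(stitched_forward(x, sp1, 0), as.integer(fixed$labels))
  sp1 <- train_stitched(sp1, fixed, iterations = 50, batch_size = 16,
                        lr = 5e-4, augment = NULL, seed = 5)
  expect_equal(unique(sp1$train_log$config_id), 0)
  loss1 <- focal_loss(stitched_forward(x, sp1, 0), as.integer(fixed$labels))
  expect_lt(loss1, loss0)
})
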