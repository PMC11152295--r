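# Shared fixtures: small conventions for desk-scale blocks, cached reduced
# anchors, a tiny synthetic dataset, and the hand-coded class detector used
# as the generator's separability oracle.

tiny_conv <- function(...) medvit_conventions(head_dim = 2L, ...)

# exact-arithmetic oracles: remove the normalization eps so an identity-state
# batch norm (running mean 0, var 1) is exactly the identity in eval mode
zero_bn_eps <- function(module) {
  octstitch:::walk_layers_of_type(module, "batchnorm", function(l) l$eps <- 0)
  module
}

.fixture_env <- new.env()

# cached builders (model construction is deterministic given the seed)
fixture_reduced_model <- function(kind = "reduced_micro", seed = 1) {
  key <- paste(kind, seed)
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- build_medvit(medvit_spec(kind), seed = seed)
  }
  .fixture_env[[key]]
}

fixture_dataset <- function(n = 90, side = 32, seed = 2,
                            proportions = c(0.4, 0.3, 0.3)) {
  key <- paste("ds", n, side, seed, paste(proportions, collapse = ","))
  if (is.null(.fixture_env[[key]])) {
    .fixture_env[[key]] <- generate_dataset(
      n, proportions, synthetic_oct_params(side = side), seed = seed
    )
  }
  .fixture_env[[key]]
}

# 3x3 box filter used by the detector
box3 <- function(img) {
  h <- nrow(img); w <- ncol(img)
  p <- matrix(0, h + 2, w + 2)
  p[2:(h + 1), 2:(w + 1)] <- img
  out <- matrix(0, h, w)
  for (di in 0:2) {
    for (dj in 0:2) out <- out + p[(1 + di):(h + di), (1 + dj):(w + dj)]
  }
  out / 9
}

# hand-coded detector: bright-column fraction (CNV lesion) and RPE
# band-deformation energy (drusen) from the bottom edge of the bright band
detect_oct_features <- function(img) {
  s <- nrow(img)
  sm <- box3(img)
  bright_cnt <- colSums(sm > 0.6)
  k <- max(3, round(0.05 * s))
  bc <- as.numeric(stats::filter(bright_cnt, rep(1 / k, k), sides = 2))
  bright <- max(bc, na.rm = TRUE) / s
  prof <- apply(sm > 0.5, 2, function(col) {
    wv <- which(col)
    if (length(wv)) max(wv) else NA_integer_
  })
  prof <- as.numeric(prof)
  if (all(is.na(prof))) return(c(bright = bright, deform = 0))
  prof[is.na(prof)] <- stats::median(prof, na.rm = TRUE)
  kk <- max(3, 2 * (round(0.025 * s) %/% 1) + 1)
  prof <- as.numeric(stats::runmed(prof, kk))
  xs <- seq_len(s)
  fit <- stats::smooth.spline(xs, prof, df = 6)
  up <- pmax(-(prof - stats::predict(fit, xs)$y), 0) / s
  deform <- unname(stats::quantile(up, 0.92))
  c(bright = bright, deform = deform)
}

classify_oct_image <- function(img) {
  f <- detect_oct_features(img)
  if (f[["bright"]] > 0.10) "cnv"
  else if (f[["deform"]] > 0.012) "drusen"
  else "normal"
}
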