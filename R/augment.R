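# Training-time augmentation: random affine -> intensity jitter -> random
# horizontal flip -> normalization, applied to unit-scaled grayscale images.

#' Augmentation parameters
#'
#' Defaults are the study's augmentation stack: rotation (-20, 20) degrees,
#' translation up to (0.05, 0.2) of the image size (horizontal, vertical),
#' shear (-10, 10) degrees, scale (0.8, 1.2), brightness/contrast/saturation
#' jitter factors in (0.8, 1.2), horizontal flip with probability 0.5.
#'
#' @param rotation rotation range in degrees.
#' @param translate maximum (horizontal, vertical) shift as image fractions.
#' @param shear shear range in degrees.
#' @param scale scale factor range.
#' @param brightness,contrast,saturation jitter factor ranges.
#' @param hflip probability of a horizontal flip.
#' @export
augment_params <- function(rotation = c(-20, 20), translate = c(0.05, 0.2),
                           shear = c(-10, 10), scale = c(0.8, 1.2),
                           brightness = c(0.8, 1.2), contrast = c(0.8, 1.2),
                           saturation = c(0.8, 1.2), hflip = 0.5) {
  list(rotation = rotation, translate = translate, shear = shear,
       scale = scale, brightness = brightness, contrast = contrast,
       saturation = saturation, hflip = hflip)
}

#' Normalization parameters
#'
#' Presets carry the per-dataset pixel statistics: NEH mean 0.13 / sd 0.194,
#' UCSD mean 0.19 / sd 0.215 (unit-scaled intensities, applied identically
#' to every channel).
#'
#' @param preset `"NEH"`, `"UCSD"` or `"none"` (mean 0, sd 1).
#' @param mean,std explicit statistics overriding the preset.
#' @export
normalize_params <- function(preset = c("NEH", "UCSD", "none"), mean = NULL,
                             std = NULL) {
  preset <- match.arg(preset)
  p <- switch(preset,
    NEH = list(mean = 0.13, std = 0.194),
    UCSD = list(mean = 0.19, std = 0.215),
    none = list(mean = 0, std = 1)
  )
  if (!is.null(mean)) p$mean <- mean
  if (!is.null(std)) p$std <- std
  if (p$std <= 0) stop("normalization std must be > 0", call. = FALSE)
  p
}

#' Normalize a unit-scaled image
#'
#' `(pixel - mean) / std`, identically per channel.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param params a [normalize_params()] list.
#' @export
normalize_image <- function(img, params = normalize_params("NEH")) {
  if (params$std <= 0) stop("normalization std must be > 0", call. = FALSE)
  (img - params$mean) / params$std
}

# inverse-mapped affine warp about the image centre with bilinear sampling;
# angles in degrees, translation in pixels, out-of-range samples are 0
affine_warp <- function(img, angle = 0, tx = 0, ty = 0, shear = 0,
                        scale = 1) {
  h <- nrow(img); w <- ncol(img)
  cx <- (w + 1) / 2; cy <- (h + 1) / 2
  a <- angle * pi / 180
  sh <- tan(shear * pi / 180)
  # forward map: scale -> shear(x) -> rotate, then translate
  M <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2) %*%
    matrix(c(1, 0, sh, 1), 2) %*% diag(c(scale, scale))
  Mi <- solve(M)
  xo <- rep(seq_len(w), each = h) - cx - tx
  yo <- rep(seq_len(h), times = w) - cy - ty
  xs <- Mi[1, 1] * xo + Mi[1, 2] * yo + cx
  ys <- Mi[2, 1] * xo + Mi[2, 2] * yo + cy
  x0 <- floor(xs); y0 <- floor(ys)
  fx <- xs - x0; fy <- ys - y0
  pix <- function(xx, yy) {
    ok <- xx >= 1 & xx <= w & yy >= 1 & yy <= h
    v <- numeric(length(xx))
    v[ok] <- img[cbind(yy[ok], xx[ok])]
    v
  }
  v <- pix(x0, y0) * (1 - fx) * (1 - fy) + pix(x0 + 1, y0) * fx * (1 - fy) +
    pix(x0, y0 + 1) * (1 - fx) * fy + pix(x0 + 1, y0 + 1) * fx * fy
  matrix(v, h, w)
}

#' Augment a grayscale image
#'
#' Applies, in order: a random affine transform (rotation, translation,
#' shear, scale sampled from the configured ranges), intensity jitter
#' (brightness, contrast, saturation), a random horizontal flip, and
#' normalization. Uses the current R random-number stream; seed the stream
#' for reproducibility. Saturation jitter is a no-op on grayscale images but
#' its factor is still drawn, keeping the random stream aligned with the
#' configured transform list.
#'
#' @param img numeric matrix in `[0, 1]`.
#' @param params an [augment_params()] list.
#' @param norm a [normalize_params()] list applied last.
#' @return the augmented, normalized image matrix (same dimensions).
#' @export
augment_image <- function(img, params = augment_params(),
                          norm = normalize_params("NEH")) {
  h <- nrow(img); w <- ncol(img)
  angle <- stats::runif(1, params$rotation[1], params$rotation[2])
  tx <- stats::runif(1, -params$translate[1], params$translate[1]) * w
  ty <- stats::runif(1, -params$translate[2], params$translate[2]) * h
  sh <- stats::runif(1, params$shear[1], params$shear[2])
  sc <- stats::runif(1, params$scale[1], params$scale[2])
  if (angle != 0 || tx != 0 || ty != 0 || sh != 0 || sc != 1) {
    img <- affine_warp(img, angle, tx, ty, sh, sc)
  }
  b <- stats::runif(1, params$brightness[1], params$brightness[2])
  ct <- stats::runif(1, params$contrast[1], params$contrast[2])
  stats::runif(1, params$saturation[1], params$saturation[2]) # grayscale no-op
  if (b != 1) img <- pmin(pmax(img * b, 0), 1)
  if (ct != 1) img <- pmin(pmax((img - mean(img)) * ct + mean(img), 0), 1)
  if (stats::runif(1) < params$hflip) img <- img[, rev(seq_len(ncol(img)))]
  normalize_image(img, norm)
}

#' Bilinear image resize
#'
#' @param img numeric matrix.
#' @param h_out,w_out output dimensions in pixels.
#' @export
resize_bilinear <- function(img, h_out, w_out = h_out) {
  h <- nrow(img); w <- ncol(img)
  if (h == h_out && w == w_out) return(img)
  ys <- (seq_len(h_out) - 0.5) * h / h_out + 0.5
  xs <- (seq_len(w_out) - 0.5) * w / w_out + 0.5
  ys <- pmin(pmax(ys, 1), h); xs <- pmin(pmax(xs, 1), w)
  y0 <- pmin(floor(ys), h - 1); x0 <- pmin(floor(xs), w - 1)
  fy <- ys - y0; fx <- xs - x0
  A <- img[y0, x0, drop = FALSE]; B <- img[y0, x0 + 1, drop = FALSE]
  C <- img[y0 + 1, x0, drop = FALSE]; D <- img[y0 + 1, x0 + 1, drop = FALSE]
  Fy <- matrix(fy, h_out, w_out); Fx <- matrix(fx, h_out, w_out, byrow = TRUE)
  A * (1 - Fy) * (1 - Fx) + B * (1 - Fy) * Fx + C * Fy * (1 - Fx) + D * Fy * Fx
}
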