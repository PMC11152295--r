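# Synthetic OCT-like B-scan generator. Renders a layered-retina morphology
# (smooth curved bands over a dark background) with class-specific
# pathology: drusen as localized upward deformations of the RPE band, CNV as
# a large hyperreflective sub-retinal lesion with an adjacent dark fluid
# pocket, and multiplicative speckle noise on top. The three classes are
# separable by construction, which is what makes end-to-end training tests
# on this data meaningful; it is a geometric phantom, not a physical
# simulation of OCT optics.

#' Synthetic OCT generator parameters
#'
#' All geometric quantities are fractions of the image side so the phantom
#' renders consistently at any resolution.
#'
#' @param side image side in pixels.
#' @param band_count number of retinal bands above the RPE.
#' @param band_thickness band thickness range (fraction of side).
#' @param curvature amplitude range of the retinal curvature.
#' @param drusen_count range of drusen bumps (inclusive).
#' @param drusen_height,drusen_width bump geometry ranges.
#' @param cnv_radius lesion semi-axis range.
#' @param cnv_brightness lesion hyperreflectivity level.
#' @param fluid_darkness intensity inside the fluid pocket.
#' @param speckle_var variance of the multiplicative gamma speckle.
#' @param background background intensity.
#' @export
synthetic_oct_params <- function(side = 224, band_count = 3,
                                 band_thickness = c(0.02, 0.05),
                                 curvature = c(0.04, 0.10),
                                 drusen_count = c(2, 6),
                                 drusen_height = c(0.07, 0.14),
                                 drusen_width = c(0.05, 0.09),
                                 cnv_radius = c(0.10, 0.18),
                                 cnv_brightness = 0.9,
                                 fluid_darkness = 0.03,
                                 speckle_var = 0.05,
                                 background = 0.08) {
  stopifnot(side >= 16, speckle_var >= 0)
  as.list(environment())
}

#' Generate one synthetic labeled B-scan
#'
#' Deterministic given the random seed: rendering consumes the current R
#' random stream.
#'
#' @param label one of `"normal"`, `"drusen"`, `"cnv"`.
#' @param params a [synthetic_oct_params()] list.
#' @param seed optional integer seed set before rendering.
#' @return a list with `pixels` (matrix in `[0, 1]`) and `label`.
#' @examples
#' img <- generate_image("drusen", synthetic_oct_params(side = 64), seed = 1)
#' range(img$pixels)
#' @export
generate_image <- function(label = c("normal", "drusen", "cnv"),
                           params = synthetic_oct_params(), seed = NULL) {
  label <- match.arg(label)
  if (!is.null(seed)) set.seed(seed)
  s <- params$side
  img <- matrix(params$background, s, s)
  xs <- seq_len(s)
  rows <- matrix(seq_len(s), s, s)            # row index per pixel
  colm <- matrix(xs, s, s, byrow = TRUE)      # column index per pixel

  # smooth retinal curvature: low-frequency sine plus tilt
  amp <- stats::runif(1, params$curvature[1], params$curvature[2]) * s
  freq <- stats::runif(1, 0.6, 1.2)
  phase <- stats::runif(1, 0, 2 * pi)
  tilt <- stats::runif(1, -0.05, 0.05)
  y_rpe <- 0.58 * s + amp * sin(2 * pi * freq * xs / s + phase) +
    tilt * (xs - s / 2)

  # drusen: localized upward bumps deforming the RPE
  elev <- numeric(s)
  if (label == "drusen") {
    nb <- sample(seq(params$drusen_count[1], params$drusen_count[2]), 1)
    for (i in seq_len(nb)) {
      cx <- stats::runif(1, 0.1, 0.9) * s
      hb <- stats::runif(1, params$drusen_height[1],
                         params$drusen_height[2]) * s
      wb <- stats::runif(1, params$drusen_width[1],
                         params$drusen_width[2]) * s
      elev <- elev + hb * exp(-(xs - cx)^2 / (2 * wb^2))
    }
  }
  y_rpe_def <- y_rpe - elev

  band_col <- function(y_top, thick, intensity) {
    # paint a band following the per-column curve y_top with given thickness
    yt <- matrix(y_top, s, s, byrow = TRUE)
    inside <- rows >= yt & rows <= yt + thick
    img[inside] <<- intensity
  }

  th <- stats::runif(params$band_count + 2, params$band_thickness[1],
                     params$band_thickness[2]) * s
  # inner retinal bands follow the smooth curve; offsets above the RPE
  offs <- seq(0.22, 0.08, length.out = params$band_count) * s
  ints <- seq(0.45, 0.35, length.out = params$band_count)
  for (b in seq_len(params$band_count)) {
    band_col(y_rpe - offs[b], th[b], ints[b])
  }
  # ILM: top surface band
  band_col(y_rpe - 0.28 * s, th[params$band_count + 1], 0.6)
  # RPE: brightest band, deformed upward by drusen; the deposits themselves
  # are hyporeflective, so only the band displacement is rendered
  band_col(y_rpe_def, pmax(th[params$band_count + 2], 0.02 * s), 0.85)
  # choroid: dim decaying texture under the RPE
  yr <- matrix(y_rpe, s, s, byrow = TRUE)
  ch <- rows > yr + th[params$band_count + 2]
  img[ch] <- pmax(img[ch], 0.25 * exp(-(rows[ch] - yr[ch]) / (0.1 * s)))

  if (label == "cnv") {
    # hyperreflective lesion breaking through beneath the RPE, with an
    # irregular (harmonically modulated) boundary
    cx <- stats::runif(1, 0.3, 0.7) * s
    rx <- stats::runif(1, params$cnv_radius[1], params$cnv_radius[2]) * s
    ry <- stats::runif(1, params$cnv_radius[1], params$cnv_radius[2]) * s * 0.7
    cy <- y_rpe[pmin(pmax(round(cx), 1), s)] + 0.6 * ry
    a1 <- stats::runif(1, 0, 0.25); p1 <- stats::runif(1, 0, 2 * pi)
    theta <- atan2((rows - cy) / ry, (colm - cx) / rx)
    rr <- sqrt(((colm - cx) / rx)^2 + ((rows - cy) / ry)^2)
    lesion <- rr <= 1 + a1 * sin(3 * theta + p1)
    img[lesion] <- params$cnv_brightness
    # adjacent dark fluid pocket above the lesion, inside the retina
    fx <- cx + stats::runif(1, -0.1, 0.1) * s
    fy <- cy - ry - 0.08 * s
    frx <- 0.6 * rx; fry <- 0.5 * ry
    pocket <- ((colm - fx) / frx)^2 + ((rows - fy) / fry)^2 <= 1
    img[pocket] <- params$fluid_darkness
  }

  # multiplicative gamma speckle (mean 1, variance speckle_var)
  if (params$speckle_var > 0) {
    k <- 1 / params$speckle_var
    noise <- matrix(stats::rgamma(s * s, shape = k, rate = k), s, s)
    img <- img * noise
  }
  img <- pmin(pmax(img, 0), 1)
  list(pixels = img, label = label)
}

#' Generate a labeled synthetic dataset
#'
#' Class counts follow `class_proportions` up to rounding (largest-remainder
#' apportionment). Consecutive samples are grouped into pseudo-patients of
#' 4 scans for the optional patient-grouped splitter. With `out_dir` the
#' images are written as PNG files in class subdirectories together with a
#' `manifest.csv` (sample_id, patient_id, label, path); the dataset is also
#' returned in memory.
#'
#' @param n number of images.
#' @param class_proportions named or ordered proportions for
#'   (normal, drusen, cnv); must sum to 1.
#' @param params a [synthetic_oct_params()] list.
#' @param seed integer seed; the same seed reproduces the dataset exactly.
#' @param out_dir optional output directory.
#' @return an `oct_dataset` (with `$manifest`).
#' @export
generate_dataset <- function(n, class_proportions = c(0.5, 0.25, 0.25),
                             params = synthetic_oct_params(), seed = 1,
                             out_dir = NULL) {
  stopifnot(n >= 3, length(class_proportions) == 3)
  if (abs(sum(class_proportions) - 1) > 1e-8) {
    stop("class proportions must sum to 1", call. = FALSE)
  }
  if (any(class_proportions < 0)) {
    stop("class proportions must be non-negative", call. = FALSE)
  }
  raw <- n * class_proportions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1
  }
  set.seed(seed)
  labels <- rep(OCT_CLASSES, times = counts)
  images <- vector("list", n)
  for (i in seq_len(n)) {
    images[[i]] <- generate_image(labels[i], params)$pixels
  }
  patient <- (seq_len(n) - 1L) %/% 4L + 1L
  manifest <- data.frame(
    sample_id = seq_len(n), patient_id = patient, label = labels,
    path = NA_character_, stringsAsFactors = FALSE
  )
  if (!is.null(out_dir)) {
    for (cl in OCT_CLASSES) {
      dir.create(file.path(out_dir, cl), recursive = TRUE,
                 showWarnings = FALSE)
    }
    for (i in seq_len(n)) {
      p <- file.path(out_dir, labels[i], sprintf("sample_%05d.png", i))
      png::writePNG(images[[i]], p)
      manifest$path[i] <- p
    }
    utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                     row.names = FALSE)
  }
  oct_dataset(images, labels, manifest)
}
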