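# Dataset container and the class-per-subdirectory image-folder reader.

OCT_CLASSES <- c("normal", "drusen", "cnv")

#' Construct an in-memory OCT dataset
#'
#' @param images list of unit-scaled grayscale matrices (equal dimensions).
#' @param labels factor (or character) of class labels, one per image.
#' @param manifest optional data frame with per-sample metadata
#'   (`sample_id`, `patient_id`, `label`, `path`).
#' @return an object of class `oct_dataset`.
#' @export
oct_dataset <- function(images, labels, manifest = NULL) {
  labels <- factor(as.character(labels), levels = OCT_CLASSES)
  stopifnot(length(images) == length(labels), !anyNA(labels))
  if (is.null(manifest)) {
    manifest <- data.frame(
      sample_id = seq_along(images),
      patient_id = seq_along(images),
      label = as.character(labels),
      path = NA_character_,
      stringsAsFactors = FALSE
    )
  }
  structure(list(images = images, labels = labels, manifest = manifest),
            class = "oct_dataset")
}

#' @export
print.oct_dataset <- function(x, ...) {
  side <- if (length(x$images)) nrow(x$images[[1]]) else 0
  cat(sprintf("<oct_dataset: %d images (%dx%d)>\n", length(x$images), side,
              side))
  print(table(x$labels))
  invisible(x)
}

#' @export
length.oct_dataset <- function(x) length(x$images)

dataset_subset <- function(ds, idx) {
  oct_dataset(ds$images[idx], ds$labels[idx], ds$manifest[idx, , drop = FALSE])
}

read_gray_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) {
    # luminance from RGB(A)
    a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  }
  a
}

#' Read a class-per-subdirectory image folder
#'
#' Every subdirectory of `dir` named after a class label is scanned for PNG
#' images; images are loaded grayscale (RGB collapsed by luminance) and
#' resized to `side` x `side` with bilinear interpolation. A manifest CSV
#' (`manifest.csv` in `dir`, as written by [generate_dataset()]) supplies
#' patient identifiers when present.
#'
#' @param dir dataset root directory.
#' @param side output image side in pixels.
#' @return an `oct_dataset`.
#' @export
read_image_folder <- function(dir, side = 224) {
  stopifnot(dir.exists(dir))
  classes <- intersect(OCT_CLASSES, list.dirs(dir, recursive = FALSE,
                                              full.names = FALSE))
  if (!length(classes)) {
    stop("no class subdirectories (normal/drusen/cnv) under ", dir,
         call. = FALSE)
  }
  paths <- character(0); labels <- character(0)
  for (cl in classes) {
    fs <- sort(list.files(file.path(dir, cl), pattern = "\\.png$",
                          full.names = TRUE))
    paths <- c(paths, fs)
    labels <- c(labels, rep(cl, length(fs)))
  }
  images <- lapply(paths, function(p) {
    img <- read_gray_png(p)
    resize_bilinear(img, side)
  })
  manifest <- data.frame(
    sample_id = seq_along(paths), patient_id = seq_along(paths),
    label = labels, path = paths, stringsAsFactors = FALSE
  )
  mf <- file.path(dir, "manifest.csv")
  if (file.exists(mf)) {
    m <- utils::read.csv(mf, stringsAsFactors = FALSE)
    key <- match(basename(paths), basename(m$path))
    if (!anyNA(key)) {
      manifest$sample_id <- m$sample_id[key]
      manifest$patient_id <- m$patient_id[key]
    }
  }
  oct_dataset(images, labels, manifest)
}

# stratified train/validation split; returns list(train, val) index vectors
stratified_split <- function(labels, val_fraction = 0.2) {
  train <- integer(0); val <- integer(0)
  for (cl in levels(labels)) {
    idx <- which(labels == cl)
    if (!length(idx)) next
    idx <- sample(idx)
    nv <- max(1L, round(length(idx) * val_fraction))
    if (nv >= length(idx)) nv <- length(idx) - 1L
    val <- c(val, idx[seq_len(nv)])
    train <- c(train, idx[(nv + 1L):length(idx)])
  }
  list(train = sort(train), val = sort(val))
}
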