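#' Feature maps
#'
#' A feature map is the activation tensor flowing through the network. It is
#' stored as a dense matrix with one row per spatial token and one column per
#' channel, plus the spatial geometry as attributes. Token rows are in raster
#' order: sample-major, then row, then column, i.e. row index
#' `(n - 1) * h * w + (i - 1) * w + j` holds pixel `(i, j)` of sample `n`.
#'
#' @param mat numeric matrix, `(n * h * w)` rows by `channels` columns.
#' @param n,h,w batch size and spatial height/width in pixels.
#' @return an object of class `fmap`.
#' @examples
#' x <- fmap(matrix(rnorm(2 * 4 * 4 * 8), ncol = 8), n = 2, h = 4, w = 4)
#' dim(x)
#' @export
fmap <- function(mat, n, h, w) {
  mat <- as.matrix(mat)
  stopifnot(n >= 1, h >= 1, w >= 1, nrow(mat) == n * h * w)
  attr(mat, "n") <- as.integer(n)
  attr(mat, "h") <- as.integer(h)
  attr(mat, "w") <- as.integer(w)
  class(mat) <- c("fmap", "matrix")
  mat
}

fmap_like <- function(mat, template) {
  fmap(mat, attr(template, "n"), attr(template, "h"), attr(template, "w"))
}

#' @export
print.fmap <- function(x, ...) {
  cat(sprintf(
    "<fmap: batch %d, %d channels, %d x %d>\n",
    attr(x, "n"), ncol(x), attr(x, "h"), attr(x, "w")
  ))
  invisible(x)
}

#' Convert a batch array to a feature map
#'
#' Accepts the conventional `(batch, channels, height, width)` array layout
#' and produces the token-matrix representation used internally.
#'
#' @param a 4-d numeric array, dimensions `(batch, channels, height, width)`.
#' @return an [fmap].
#' @export
fmap_from_array <- function(a) {
  stopifnot(length(dim(a)) == 4)
  d <- dim(a)
  n <- d[1]; c <- d[2]; h <- d[3]; w <- d[4]
  # permute to (w, h, n) raster rows x channel columns
  m <- matrix(aperm(a, c(4, 3, 1, 2)), nrow = n * h * w, ncol = c)
  fmap(m, n, h, w)
}

#' Convert a feature map back to a batch array
#'
#' @param x an [fmap].
#' @return 4-d array `(batch, channels, height, width)`.
#' @export
fmap_to_array <- function(x) {
  n <- attr(x, "n"); h <- attr(x, "h"); w <- attr(x, "w"); c <- ncol(x)
  a <- array(as.numeric(x), dim = c(w, h, n, c))
  aperm(a, c(3, 4, 2, 1))
}
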