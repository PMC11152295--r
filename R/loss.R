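# Focal loss for class-imbalanced classification.

#' Focal loss parameters
#'
#' @param gamma focusing exponent (>= 0); `gamma = 0` with uniform `alpha`
#'   reduces the loss to cross-entropy.
#' @param alpha per-class weight vector, or `NULL` for uniform weights.
#' @param reduction `"mean"` or `"sum"`.
#' @export
focal_params <- function(gamma = 2, alpha = NULL,
                         reduction = c("mean", "sum")) {
  stopifnot(gamma >= 0)
  list(gamma = gamma, alpha = alpha, reduction = match.arg(reduction))
}

#' Focal loss
#'
#' Per-sample loss `-alpha_y * (1 - p_y)^gamma * log(p_y)` where `p_y` is the
#' softmax probability of the true class: cross-entropy down-weighted on
#' easy, well-classified samples so that hard (typically minority-class)
#' samples dominate the gradient.
#'
#' @param logits numeric matrix `(batch, classes)`.
#' @param labels integer class indices in `1..classes` (or a factor).
#' @param params a [focal_params()] list.
#' @param return_grad also return the gradient with respect to the logits.
#' @return the scalar loss, or (with `return_grad`) a list `loss`, `grad`.
#' @examples
#' lg <- matrix(c(2, 0, 0, 0, 3, 0), 2, byrow = TRUE)
#' focal_loss(lg, c(1, 2), focal_params(gamma = 2))
#' @export
focal_loss <- function(logits, labels, params = focal_params(),
                       return_grad = FALSE) {
  if (is.factor(labels)) labels <- as.integer(labels)
  n <- nrow(logits); K <- ncol(logits)
  if (any(labels < 1 | labels > K | labels != round(labels))) {
    stop("labels must be integer class indices in 1..", K, call. = FALSE)
  }
  alpha <- params$alpha %||% rep(1, K)
  stopifnot(length(alpha) == K)
  z <- logits - apply(logits, 1, max)
  ez <- exp(z)
  p <- ez / rowSums(ez)
  iy <- cbind(seq_len(n), labels)
  py <- pmax(p[iy], 1e-12)
  ay <- alpha[labels]
  g <- params$gamma
  li <- -ay * (1 - py)^g * log(py)
  loss <- if (params$reduction == "mean") mean(li) else sum(li)
  if (!return_grad) return(loss)
  # d li / d py, then chain through softmax
  focusing_term <- if (g > 0) g * (1 - py)^(g - 1) * log(py) else 0
  dpy <- ay * (focusing_term - (1 - py)^g / py)
  onehot <- matrix(0, n, K)
  onehot[iy] <- 1
  grad <- dpy * py * (onehot - p)
  if (params$reduction == "mean") grad <- grad / n
  list(loss = loss, grad = grad)
}
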