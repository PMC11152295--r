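# Evaluation metrics: confusion matrix, accuracy, macro sensitivity and
# specificity, macro one-vs-rest AUC, and the 95% fold-aggregation interval.

#' Confusion matrix
#'
#' @param truth true class indices (1..K) or factor.
#' @param pred predicted class indices (1..K) or factor.
#' @param K number of classes.
#' @return K x K integer matrix, rows = true class, columns = predicted.
#' @export
confusion_matrix <- function(truth, pred, K = max(as.integer(truth))) {
  truth <- as.integer(truth); pred <- as.integer(pred)
  stopifnot(length(truth) == length(pred))
  cm <- matrix(0L, K, K)
  for (i in seq_along(truth)) cm[truth[i], pred[i]] <- cm[truth[i], pred[i]] + 1L
  cm
}

# rank-based one-vs-rest AUC (Mann-Whitney with tie correction)
auc_binary <- function(scores, positive) {
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Macro one-vs-rest AUC
#'
#' @param scores matrix `(n, K)` of class scores or probabilities.
#' @param labels true class indices (1..K) or factor.
#' @return unweighted mean of per-class one-vs-rest AUCs; classes with no
#'   positive sample are excluded with a warning.
#' @export
auc_macro_ovr <- function(scores, labels) {
  labels <- as.integer(labels)
  K <- ncol(scores)
  aucs <- vapply(seq_len(K), function(k) {
    auc_binary(scores[, k], labels == k)
  }, numeric(1))
  if (anyNA(aucs)) {
    warning("classes without positive samples excluded from macro AUC: ",
            paste(which(is.na(aucs)), collapse = ", "))
  }
  mean(aucs, na.rm = TRUE)
}

#' Classification metrics record
#'
#' Accuracy (confusion-matrix trace over total), macro-averaged sensitivity
#' (recall) and specificity (true-negative rate), and macro one-vs-rest AUC.
#' Classes with zero true samples are excluded from the macro means with a
#' warning.
#'
#' @param cm confusion matrix from [confusion_matrix()].
#' @param scores optional `(n, K)` score matrix for the AUC.
#' @param labels true labels matching `scores`.
#' @return a list of class `metrics_record` with fields `accuracy`,
#'   `sensitivity`, `specificity`, `auc`, `n`.
#' @examples
#' cm <- matrix(c(8, 0, 1, 1, 9, 0, 1, 1, 9), 3)
#' compute_metrics(cm)$accuracy # 26/30
#' @export
compute_metrics <- function(cm, scores = NULL, labels = NULL) {
  K <- nrow(cm)
  total <- sum(cm)
  stopifnot(total > 0, ncol(cm) == K)
  tp <- diag(cm)
  fn <- rowSums(cm) - tp
  fp <- colSums(cm) - tp
  tn <- total - tp - fn - fp
  present <- rowSums(cm) > 0
  if (!all(present)) {
    warning("classes with zero true samples excluded from macro averages: ",
            paste(which(!present), collapse = ", "))
  }
  sens <- mean((tp / (tp + fn))[present])
  spec <- mean((tn / (tn + fp))[present])
  auc <- if (!is.null(scores)) auc_macro_ovr(scores, labels) else NA_real_
  structure(list(
    accuracy = sum(tp) / total, sensitivity = sens, specificity = spec,
    auc = auc, n = total
  ), class = "metrics_record")
}

#' @export
print.metrics_record <- function(x, ...) {
  cat(sprintf(
    "accuracy %.4f | sensitivity %.4f | specificity %.4f | AUC %s | n=%d\n",
    x$accuracy, x$sensitivity, x$specificity,
    if (is.na(x$auc)) "NA" else sprintf("%.4f", x$auc), x$n
  ))
  invisible(x)
}

#' 95% interval over fold values
#'
#' Mean and half-width `1.96 * sd / sqrt(n)` (normal approximation over the
#' fold values, matching the printed "±" format); a t-quantile alternative is
#' available.
#'
#' @param values numeric vector of per-fold metric values (>= 2).
#' @param method `"normal"` (1.96) or `"t"` (Student quantile).
#' @return named vector `c(mean, half_width)`.
#' @examples
#' ci95(c(0.94, 0.95, 0.96, 0.95, 0.95))
#' @export
ci95 <- function(values, method = c("normal", "t")) {
  method <- match.arg(method)
  if (length(values) < 2) {
    stop("at least 2 fold values are needed for an interval", call. = FALSE)
  }
  q <- switch(method,
    normal = stats::qnorm(0.975),
    t = stats::qt(0.975, df = length(values) - 1)
  )
  c(mean = mean(values),
    half_width = q * stats::sd(values) / sqrt(length(values)))
}

#' Five-fold split
#'
#' Random image-level partition into 5 folds of near-equal size (sizes
#' differing by at most 1). Optionally grouped by patient so all scans of a
#' pseudo-patient land in the same fold.
#'
#' @param n number of samples.
#' @param seed integer seed.
#' @param patient_id optional grouping vector of length `n`.
#' @param k number of folds.
#' @return integer vector of fold assignments in `1..k`.
#' @export
five_fold_split <- function(n, seed = 1, patient_id = NULL, k = 5) {
  set.seed(seed)
  if (is.null(patient_id)) {
    return(sample(rep_len(seq_len(k), n)))
  }
  stopifnot(length(patient_id) == n)
  groups <- sample(unique(patient_id))
  gf <- rep_len(seq_len(k), length(groups))
  gf[match(patient_id, groups)]
}
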