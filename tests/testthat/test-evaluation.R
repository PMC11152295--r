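# Metrics, interval aggregation, fold splitting and the evaluation
# protocols.

test_that("metrics match direct formula evaluation on a worked matrix", {
  cm <- matrix(c(8, 0, 1, 1, 9, 0, 1, 1, 9), 3) # rows = true class
  mr <- compute_metrics(cm)
  expect_equal(mr$accuracy, 26 / 30)
  expect_equal(round(mr$sensitivity, 4), 0.8667) # mean(0.8, 0.9, 0.9)
  # specificity by direct TN/(TN+FP) per class
  spec_oracle <- mean(c(
    (30 - 10 - 1) / (30 - 10 - 1 + 1),
    (30 - 10 - 1) / (30 - 10 - 1 + 1),
    (30 - 10 - 2) / (30 - 10 - 2 + 2)
  ))
  expect_equal(mr$specificity, spec_oracle)
  expect_equal(mr$n, 30)
})

test_that("perfect predictions score 1 everywhere; chance scores 0.5 AUC", {
  labels <- rep(1:3, each = 20)
  scores <- matrix(0, 60, 3)
  scores[cbind(1:60, labels)] <- 1
  cm <- confusion_matrix(labels, max.col(scores), 3)
  mr <- compute_metrics(cm, scores, labels)
  expect_equal(mr$accuracy, 1)
  expect_equal(mr$sensitivity, 1)
  expect_equal(mr$specificity, 1)
  expect_equal(mr$auc, 1)
  # label-independent scores: macro one-vs-rest AUC near 0.5
  set.seed(70)
  n <- 2000
  labels <- sample(3, n, replace = TRUE)
  rnd <- matrix(runif(n * 3), n, 3)
  expect_lt(abs(auc_macro_ovr(rnd, labels) - 0.5), 0.05)
})

test_that("macro AUC agrees with an independent implementation", {
  set.seed(71)
  n <- 150
  labels <- sample(3, n, replace = TRUE)
  scores <- matrix(runif(n * 3), n, 3)
  scores[cbind(1:n, labels)] <- scores[cbind(1:n, labels)] + 0.3
  ours <- auc_macro_ovr(scores, labels)
  ref <- mean(vapply(1:3, function(k) {
    as.numeric(pROC::auc(pROC::roc(
      response = as.integer(labels == k), predictor = scores[, k],
      quiet = TRUE, direction = "<"
    )))
  }, numeric(1)))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("a class with no true samples is excluded with a warning", {
  cm <- matrix(c(10, 2, 0, 1, 9, 0, 0, 0, 0), 3, byrow = TRUE)
  expect_warning(mr <- compute_metrics(cm), "zero true samples")
  expect_equal(mr$sensitivity, mean(c(10 / 12, 9 / 10)))
})

test_that("ci95 matches the closed-form normal interval", {
  expect_equal(unname(ci95(rep(0.9, 5))["half_width"]), 0)
  v <- c(0.94, 0.95, 0.96, 0.95, 0.95)
  ci <- ci95(v)
  expect_equal(unname(ci["mean"]), 0.95)
  expect_equal(unname(ci["half_width"]),
               stats::qnorm(0.975) * stats::sd(v) / sqrt(5))
  expect_equal(round(unname(ci["mean"]), 3), 0.950)
  # permutation symmetry
  expect_equal(ci95(v), ci95(rev(v)))
  expect_equal(ci95(v), ci95(sample(v)))
  expect_error(ci95(0.9), "at least 2")
  # t-based alternative is wider for 5 folds
  expect_gt(unname(ci95(v, "t")["half_width"]), unname(ci["half_width"]))
  # half-widths shrink as 1/sqrt(n) at fixed SD
  v2 <- rep(c(0.94, 0.96), 10) # same SD pattern, 4x the folds
  expect_lt(unname(ci95(v2)["half_width"]),
            unname(ci95(c(0.94, 0.96, 0.94, 0.96))["half_width"]))
})

test_that("five-fold splits partition the data with near-equal sizes", {
  for (n in c(600, 601, 603)) {
    folds <- five_fold_split(n, seed = 72)
    expect_equal(length(folds), n)
    expect_equal(sort(unique(folds)), 1:5)
    sizes <- as.integer(table(folds))
    expect_lte(max(sizes) - min(sizes), 1)
  }
  # grouped splitting keeps each pseudo-patient in a single fold
  pid <- rep(1:30, each = 4)
  folds <- five_fold_split(120, seed = 73, patient_id = pid)
  expect_true(all(tapply(folds, pid, function(f) length(unique(f))) == 1))
  # reproducible
  expect_identical(five_fold_split(100, seed = 74),
                   five_fold_split(100, seed = 74))
})

test_that("zero-shot evaluation reproduces logged validation AUC", {
  ds <- fixture_dataset(90, 32, seed = 75)
  cfg <- pretrain_config(epochs = 2, batch_size = 32, lr = 2e-3,
                         milestone = 99, seed = 76, augment = NULL)
  res <- pretrain(medvit_spec("reduced_micro"), ds, cfg)
  val <- octstitch:::dataset_subset(ds, res$val_indices)
  mr <- zero_shot_evaluate(res, val, cfg$norm)
  expect_equal(mr$auc, res$best_val_auc, tolerance = 1e-6)
  # repeated calls are identical (no stochastic layers in eval mode)
  mr2 <- zero_shot_evaluate(res, val, cfg$norm)
  expect_identical(mr, mr2)
  # class-count mismatch is rejected
  ds2 <- ds
  expect_error(
    zero_shot_evaluate(build_medvit(medvit_spec("reduced_micro",
                                                num_classes = 4), seed = 1),
                       ds),
    "4-class head"
  )
})

test_that("an untrained model scores at chance on balanced data", {
  ds <- fixture_dataset(210, 32, seed = 77, proportions = c(1/3, 1/3, 1/3))
  m <- build_medvit(medvit_spec("reduced_micro"), seed = 78)
  mr <- zero_shot_evaluate(m, ds, normalize_params("NEH"))
  n <- length(ds$images)
  half <- stats::qnorm(0.995) * sqrt((1 / 3) * (2 / 3) / n)
  expect_gt(mr$accuracy, 1 / 3 - half)
  expect_lt(mr$accuracy, 1 / 3 + half)
})

test_that("the five-fold driver follows the in/out-of-distribution protocol", {
  p <- synthetic_oct_params(side = 32)
  src <- generate_dataset(60, c(0.4, 0.3, 0.3), p, seed = 80)
  tgt <- generate_dataset(60, c(0.4, 0.3, 0.3), p, seed = 81)
  cfg <- pretrain_config(epochs = 1, batch_size = 32, lr = 1e-3,
                         milestone = 99, seed = 82, augment = NULL)
  # (stage-4 cuts see fewer tokens than channels at this tiny scale, so the
  # rank-deficiency fallback of the stitch initialization fires)
  ood <- suppressWarnings(
    five_fold_run(src, tgt, pretrain_cfg = cfg, stitch_iterations = 2,
                  stitch_init_batch = 48, seed = 83)
  )
  expect_equal(ood$mode, "out_of_distribution")
  expect_equal(ood$n_anchor_pretrainings, 1L) # anchors trained once
  # partition contract: every sample tested exactly once
  expect_equal(sort(unique(ood$fold_assignments)), 1:5)
  expect_equal(length(ood$fold_assignments), 60)
  n_cfg <- length(unique(ood$per_fold$config_id))
  expect_equal(nrow(ood$per_fold), 5 * n_cfg)
  expect_true(all(c("accuracy_hw", "auc_hw") %in% names(ood$aggregate)))
  idm <- suppressWarnings(
    five_fold_run(NULL, tgt, pretrain_cfg = cfg, stitch_iterations = 2,
                  stitch_init_batch = 48, seed = 84)
  )
  expect_equal(idm$mode, "in_distribution")
  expect_equal(idm$n_anchor_pretrainings, 5L) # re-trained per fold
})
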