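# Evaluation protocols: zero-shot testing of a pre-trained model on a whole
# target dataset, and the five-fold cross-validated stitching driver.

#' Zero-shot evaluation
#'
#' Evaluates a trained model on the entire target dataset without any weight
#' update: the target normalization preset is applied, class probabilities
#' are computed in evaluation mode and the full metrics record is returned.
#'
#' @param model a trained model (or a `pretrain()` result).
#' @param dataset target `oct_dataset`.
#' @param norm target-dataset [normalize_params()].
#' @return a [metrics_record][compute_metrics()].
#' @export
zero_shot_evaluate <- function(model, dataset,
                               norm = normalize_params("NEH")) {
  if (is.list(model) && !inherits(model, "osn_layer") &&
      !is.null(model$model)) {
    model <- model$model
  }
  K <- model$spec$num_classes
  if (K != nlevels(dataset$labels)) {
    stop(sprintf(
      "checkpoint has a %d-class head but the target dataset has %d classes",
      K, nlevels(dataset$labels)
    ), call. = FALSE)
  }
  probs <- predict_probs(model, dataset$images, norm)
  labs <- as.integer(dataset$labels)
  pred <- max.col(probs, ties.method = "first")
  compute_metrics(confusion_matrix(labs, pred, K), probs, labs)
}

# evaluate one stitched configuration on a dataset; when calibration
# images are supplied, normalization statistics are recalibrated for this
# configuration first and restored afterwards
evaluate_stitched <- function(space, config_id, dataset, norm,
                              batch_size = 32, calibration_images = NULL) {
  if (!is.null(calibration_images)) {
    snap <- snapshot_bn_stats(list(space$front$model, space$back$model))
    on.exit(restore_bn_stats(snap))
    calibrate_stitched(space, config_id, calibration_images)
  }
  n <- length(dataset$images)
  K <- space$back$model$spec$num_classes
  probs <- matrix(NA_real_, n, K)
  for (start in seq(1, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1, n)
    imgs <- lapply(dataset$images[take], normalize_image, params = norm)
    x <- images_to_fmap(imgs, space$front$model$spec$input_channels)
    z <- stitched_forward(x, space, config_id, train = FALSE)
    z <- z - apply(z, 1, max)
    ez <- exp(z)
    probs[take, ] <- ez / rowSums(ez)
  }
  labs <- as.integer(dataset$labels)
  pred <- max.col(probs, ties.method = "first")
  compute_metrics(confusion_matrix(labs, pred, K), probs, labs)
}

#' Five-fold cross-validated stitching
#'
#' The target dataset is split into 5 folds. In the out-of-distribution mode
#' (`source` differs from `target`) both anchors are pre-trained once on the
#' source dataset; per fold, the stitching space is rebuilt from those
#' anchors, initialized and trained on the remaining 4/5 of the target and
#' every configuration is evaluated on the held-out fold. In the
#' in-distribution mode (`source` identical to `target`, passed as `NULL`)
#' the anchors are re-pre-trained on the remainder in every fold. Before a
#' configuration is evaluated, the normalization statistics along its path
#' are recalibrated on the training remainder (see [calibrate_stitched()])
#' and restored afterwards. Per-fold metrics are aggregated with [ci95()].
#'
#' @param source_dataset source `oct_dataset`, or `NULL` for in-distribution
#'   stitching.
#' @param target_dataset target `oct_dataset`.
#' @param front_spec,back_spec model specifications for the two anchors.
#' @param pretrain_cfg a [pretrain_config()].
#' @param stitch_iterations training iterations of the stitching phase per
#'   fold.
#' @param stitch_init_batch mini-batch size for least-squares stitch
#'   initialization.
#' @param prune prune the candidate space.
#' @param norm target [normalize_params()].
#' @param seed integer seed controlling folds and stitching.
#' @param results_path optional CSV path mirroring the results-table format
#'   (model, config_id, fold, accuracy, sensitivity, specificity, auc,
#'   params_millions; aggregate rows carry fold = NA and the "±" half-widths
#'   in *_hw columns).
#' @return list with `per_fold` (data frame), `aggregate` (data frame with
#'   half-widths), `fold_assignments`.
#' @export
five_fold_run <- function(source_dataset, target_dataset,
                          front_spec = medvit_spec("reduced_micro"),
                          back_spec = medvit_spec("reduced_tiny"),
                          pretrain_cfg = pretrain_config(),
                          stitch_iterations = 200,
                          stitch_init_batch = 100,
                          prune = TRUE,
                          norm = normalize_params("NEH"),
                          seed = 1,
                          results_path = NULL) {
  if (!is.null(source_dataset) &&
      !identical(levels(source_dataset$labels),
                 levels(target_dataset$labels))) {
    stop("source and target datasets must share the same label set",
         call. = FALSE)
  }
  in_distribution <- is.null(source_dataset)
  folds <- five_fold_split(length(target_dataset$images), seed = seed)
  front_pre <- back_pre <- NULL
  n_pretrains <- 0L # pre-trainings per anchor
  if (!in_distribution) {
    front_pre <- pretrain(front_spec, source_dataset, pretrain_cfg)
    back_pre <- pretrain(back_spec, source_dataset, pretrain_cfg)
    n_pretrains <- 1L
  }
  per_fold <- NULL
  for (f in 1:5) {
    test_idx <- which(folds == f)
    remain_idx <- which(folds != f)
    remain <- dataset_subset(target_dataset, remain_idx)
    testset <- dataset_subset(target_dataset, test_idx)
    if (in_distribution) {
      cfg_f <- pretrain_cfg
      cfg_f$seed <- pretrain_cfg$seed + f
      front_pre <- pretrain(front_spec, remain, cfg_f)
      back_pre <- pretrain(back_spec, remain, cfg_f)
      n_pretrains <- n_pretrains + 1L
    }
    front <- stitch_anchor(clone_model(front_pre$model), 1L)
    back <- stitch_anchor(clone_model(back_pre$model), 2L)
    space <- build_space(front, back, prune = prune)
    set.seed(seed * 1000 + f)
    init_idx <- sample(length(remain$images),
                       min(stitch_init_batch, length(remain$images)))
    init_imgs <- lapply(remain$images[init_idx], normalize_image,
                        params = norm)
    space <- init_space(space, init_imgs)
    space <- train_stitched(space, remain, iterations = stitch_iterations,
                            lr = pretrain_cfg$lr,
                            augment = pretrain_cfg$augment,
                            norm = norm, seed = seed * 1000 + f)
    calib <- lapply(remain$images[seq_len(min(480, length(remain$images)))],
                    normalize_image, params = norm)
    for (cid in space$configs$config_id) {
      mr <- evaluate_stitched(space, cid, testset, norm,
                              calibration_images = calib)
      per_fold <- rbind(per_fold, data.frame(
        model = sprintf("stitched %s->%s", front_spec$name, back_spec$name),
        config_id = cid, fold = f, accuracy = mr$accuracy,
        sensitivity = mr$sensitivity, specificity = mr$specificity,
        auc = mr$auc,
        params_millions = stitched_param_count(space, cid) / 1e6
      ))
    }
  }
  aggregate <- NULL
  for (cid in unique(per_fold$config_id)) {
    rows <- per_fold[per_fold$config_id == cid, ]
    agg <- data.frame(model = rows$model[1], config_id = cid, fold = NA)
    for (mcol in c("accuracy", "sensitivity", "specificity", "auc")) {
      ci <- ci95(rows[[mcol]])
      agg[[mcol]] <- ci[["mean"]]
      agg[[paste0(mcol, "_hw")]] <- ci[["half_width"]]
    }
    agg$params_millions <- rows$params_millions[1]
    aggregate <- rbind(aggregate, agg)
  }
  if (!is.null(results_path)) {
    pf <- per_fold
    for (hw in c("accuracy_hw", "sensitivity_hw", "specificity_hw",
                 "auc_hw")) {
      pf[[hw]] <- NA_real_
    }
    utils::write.csv(
      rbind(pf[, names(aggregate)], aggregate), results_path,
      row.names = FALSE
    )
  }
  list(per_fold = per_fold, aggregate = aggregate, fold_assignments = folds,
       n_anchor_pretrainings = n_pretrains,
       anchor_val_auc = c(front = front_pre$best_val_auc,
                          back = back_pre$best_val_auc),
       mode = if (in_distribution) "in_distribution" else "out_of_distribution")
}

# deep copy of a model (fresh layer environments with the same weights)
clone_model <- function(model) {
  m2 <- build_medvit(model$spec)
  load_model_state(m2, model_state(model))
  m2
}
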