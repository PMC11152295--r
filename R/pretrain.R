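# Anchor pre-training: stratified 80/20 split, focal-loss training with a
# step-decayed AdamW schedule, and best-validation-AUC checkpointing.

#' Pre-training configuration
#'
#' Defaults are the study's pre-training hyperparameters: 75 epochs, batch
#' size 32, learning rate 5e-5 decayed by 0.1 at epoch 50, AdamW, focal
#' loss.
#'
#' @param epochs number of training epochs (>= 1).
#' @param batch_size mini-batch size.
#' @param lr base learning rate.
#' @param lr_decay step-decay factor.
#' @param milestone epoch at which the decay is applied.
#' @param weight_decay AdamW decoupled weight decay.
#' @param val_fraction validation share of the stratified split.
#' @param loss [focal_params()]; `NULL` selects focal loss with gamma 2 and
#'   inverse-class-frequency weights computed from the training split.
#' @param augment [augment_params()] list, or `NULL` to disable.
#' @param norm [normalize_params()] list.
#' @param seed integer seed (model init, split, batch order, augmentation).
#' @export
pretrain_config <- function(epochs = 75, batch_size = 32, lr = 5e-5,
                            lr_decay = 0.1, milestone = 50,
                            weight_decay = 0.01, val_fraction = 0.2,
                            loss = NULL, augment = augment_params(),
                            norm = normalize_params("NEH"), seed = 1) {
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  as.list(environment())
}

# evaluation-mode class probabilities for a dataset subset
predict_probs <- function(model, images, norm, batch_size = 32) {
  n <- length(images)
  out <- matrix(NA_real_, n, model$spec$num_classes)
  for (start in seq(1, n, by = batch_size)) {
    take <- start:min(start + batch_size - 1, n)
    imgs <- lapply(images[take], normalize_image, params = norm)
    x <- images_to_fmap(imgs, model$spec$input_channels)
    z <- model$forward(x, train = FALSE)
    z <- z - apply(z, 1, max)
    ez <- exp(z)
    out[take, ] <- ez / rowSums(ez)
  }
  out
}

#' Pre-train an anchor model
#'
#' Splits the dataset into stratified 80/20 train/validation parts, trains
#' with focal loss and a step-decayed AdamW schedule, computes the macro
#' one-vs-rest validation AUC after every epoch and keeps the checkpoint
#' whenever the validation AUC is greater than or equal to the best seen so
#' far (ties favour the later epoch). The returned model carries the
#' best-epoch weights.
#'
#' @param spec a [medvit_spec()] (or a kind string accepted by it).
#' @param dataset an `oct_dataset` with unit-scaled images.
#' @param config a [pretrain_config()] list.
#' @param checkpoint_dir optional directory; when given, the best checkpoint
#'   (weights, spec sidecar, training state) is written there.
#' @param log_path optional CSV path for the per-epoch training log.
#' @return list with `model` (best weights), `history` (epoch, train_loss,
#'   val_auc, lr), `best_epoch`, `best_val_auc`, `val_indices`.
#' @export
pretrain <- function(spec, dataset, config = pretrain_config(),
                     checkpoint_dir = NULL, log_path = NULL) {
  if (is.character(spec)) spec <- medvit_spec(spec)
  labels <- dataset$labels
  if (nlevels(droplevels(labels)) < 2) {
    stop("pre-training needs at least 2 classes present", call. = FALSE)
  }
  set.seed(config$seed)
  model <- build_medvit(spec)
  split <- stratified_split(labels, config$val_fraction)
  present <- levels(labels)[tabulate(labels, nlevels(labels)) > 0]
  for (cl in present) {
    if (!any(labels[split$val] == cl)) {
      stop("class '", cl, "' is absent from the validation split",
           call. = FALSE)
    }
  }
  loss <- config$loss
  if (is.null(loss)) {
    freq <- tabulate(labels[split$train], nlevels(labels))
    alpha <- ifelse(freq > 0, 1 / pmax(freq, 1), 0)
    alpha <- alpha / sum(alpha) * sum(freq > 0)
    loss <- focal_params(gamma = 2, alpha = alpha)
  }
  opt <- adamw(model, lr = config$lr, weight_decay = config$weight_decay)
  sched <- lr_step_schedule(config$lr, config$lr_decay, config$milestone)
  train_idx <- split$train
  labs <- as.integer(labels)
  history <- data.frame(epoch = seq_len(config$epochs), train_loss = NA_real_,
                        val_auc = NA_real_, lr = NA_real_)
  best_auc <- 0
  best_state <- NULL
  best_epoch <- 0L
  for (ep in seq_len(config$epochs)) {
    lr_ep <- sched(ep)
    order_idx <- sample(train_idx)
    losses <- c()
    for (start in seq(1, length(order_idx), by = config$batch_size)) {
      take <- order_idx[start:min(start + config$batch_size - 1,
                                  length(order_idx))]
      imgs <- lapply(dataset$images[take], function(im) {
        if (is.null(config$augment)) normalize_image(im, config$norm)
        else augment_image(im, config$augment, config$norm)
      })
      x <- images_to_fmap(imgs, spec$input_channels)
      zero_grads(model)
      logits <- model$forward(x, train = TRUE)
      fl <- focal_loss(logits, labs[take], loss, return_grad = TRUE)
      model$backward(fl$grad)
      opt$step(lr = lr_ep)
      losses <- c(losses, fl$loss)
    }
    probs <- predict_probs(model, dataset$images[split$val], config$norm,
                           config$batch_size)
    val_auc <- auc_macro_ovr(probs, labs[split$val])
    history$train_loss[ep] <- mean(losses)
    history$val_auc[ep] <- val_auc
    history$lr[ep] <- lr_ep
    if (val_auc >= best_auc) {
      best_auc <- val_auc
      best_state <- model_state(model)
      best_epoch <- ep
    }
  }
  if (!is.null(best_state)) load_model_state(model, best_state)
  if (!is.null(log_path)) utils::write.csv(history, log_path,
                                           row.names = FALSE)
  if (!is.null(checkpoint_dir)) {
    save_checkpoint(model, checkpoint_dir,
                    list(epoch = best_epoch, best_val_auc = best_auc))
  }
  list(model = model, history = history, best_epoch = best_epoch,
       best_val_auc = best_auc, val_indices = split$val)
}
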