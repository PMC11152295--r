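# Stitching two anchor networks: candidate enumeration (paired sliding
# window / unpaired proportional buckets), closed-form least-squares
# initialization of the 1x1 linear stitch layers, stitched forward passes
# and random-configuration training of the whole space.

#' Register a model as a stitching anchor
#'
#' The front anchor is the smaller model (its prefix is executed before the
#' stitch), the back anchor the larger one; stitching runs in one direction,
#' smaller to larger. Cut points are the individual ECB/LTB blocks.
#'
#' @param model a built model.
#' @param anchor_id integer identifier.
#' @return an object of class `stitch_anchor` with a `cut_points` table
#'   (flat block index, stage, channels, spatial stride so far).
#' @export
stitch_anchor <- function(model, anchor_id = 1L) {
  info <- model$block_info
  cut_points <- data.frame(
    block = info$block, stage = info$stage, channels = info$dim,
    stride = 4L * 2L^(info$stage - 1L)
  )
  structure(list(anchor_id = anchor_id, model = model,
                 cut_points = cut_points),
            class = "stitch_anchor")
}

#' Paired candidate enumeration
#'
#' For two stages of equal depth a sliding window of length 2 and step 1
#' moves over the aligned positions; each window yields one candidate
#' `(n, m)`: cut after block `n` of the front anchor, enter at block
#' `m = n + 1` of the back anchor. A depth-`L` stage yields `L - 1`
#' candidates.
#'
#' @param len_a,len_b block counts of the aligned stages (must be equal).
#' @return data frame with columns `n`, `m`.
#' @examples
#' enumerate_paired(3, 3) # (1,2), (2,3)
#' @export
enumerate_paired <- function(len_a, len_b) {
  if (len_a != len_b) {
    stop("paired enumeration needs equal depths; use the unpaired strategy",
         call. = FALSE)
  }
  if (len_a < 2) return(data.frame(n = integer(0), m = integer(0)))
  data.frame(n = seq_len(len_a - 1), m = seq_len(len_a - 1) + 1L)
}

#' Unpaired candidate enumeration
#'
#' When the front stage is shallower, its blocks act as the criterion: back
#' position `j` belongs to front block `n = floor((j - 1) * len_a / len_b) + 1`
#' (proportional buckets), and each assignment yields the candidate
#' `(n, m = j + 1)` provided `m <= len_b`. With equal depths the bucket rule
#' degenerates to the one-to-one paired alignment.
#'
#' @param len_a front (smaller) block count; must not exceed `len_b`.
#' @param len_b back (larger) block count.
#' @return data frame with columns `n`, `m`.
#' @examples
#' enumerate_unpaired(2, 5) # buckets of size 3 and 2
#' @export
enumerate_unpaired <- function(len_a, len_b) {
  if (len_a > len_b) {
    stop("unpaired enumeration requires the front anchor to be the shallower one",
         call. = FALSE)
  }
  j <- seq_len(len_b)
  n <- floor((j - 1) * len_a / len_b) + 1L
  m <- j + 1L
  keep <- m <= len_b
  data.frame(n = as.integer(n[keep]), m = as.integer(m[keep]))
}

# 1x1 linear stitch layer acting per spatial position
new_stitch_layer <- function(d_in, d_out) {
  self <- new_layer("stitch")
  self$d_in <- d_in; self$d_out <- d_out
  self$params$W <- matrix(0, d_in, d_out)
  self$params$b <- numeric(d_out)
  self$initialized <- FALSE
  self$forward <- function(x, train = FALSE) {
    self$cache <- list(x = x)
    fmap_like(unclass(x) %*% self$params$W +
                rep(self$params$b, each = nrow(x)), x)
  }
  self$backward <- function(dy) {
    x <- self$cache$x
    self$grads$W <- self$grads$W + crossprod(unclass(x), unclass(dy))
    self$grads$b <- self$grads$b + colSums(unclass(dy))
    self$cache <- NULL
    fmap_like(unclass(dy) %*% t(self$params$W), x)
  }
  self
}

#' Least-squares stitch initialization
#'
#' Finds the affine map `W, b` minimizing the Frobenius residual
#' `||A W + b - B||` between front-anchor activations `A` and back-anchor
#' activations `B` collected on the same mini-batch, via the closed-form
#' normal-equations/pseudo-inverse solution. Rank-deficient inputs fall back
#' to the minimum-norm solution with a warning.
#'
#' @param acts_front matrix `(tokens, d_in)` of front-anchor activations.
#' @param acts_back matrix `(tokens, d_out)` of back-anchor activations.
#' @return an initialized stitch layer.
#' @export
init_stitch_least_squares <- function(acts_front, acts_back) {
  A <- as.matrix(acts_front); B <- as.matrix(acts_back)
  if (nrow(A) != nrow(B)) {
    stop("front and back activation matrices must have the same token count",
         call. = FALSE)
  }
  X <- cbind(A, 1)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warning("rank-deficient activations; using the minimum-norm least-squares solution")
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1]
    coef <- sv$v[, pos, drop = FALSE] %*%
      ((crossprod(sv$u[, pos, drop = FALSE], B)) / sv$d[pos])
  } else {
    coef <- qr.coef(qr_x, B)
  }
  st <- new_stitch_layer(ncol(A), ncol(B))
  st$params$W <- coef[seq_len(ncol(A)), , drop = FALSE]
  st$params$b <- as.numeric(coef[ncol(A) + 1, ])
  st$initialized <- TRUE
  st
}

#' Build the stitching space between two anchors
#'
#' Stage by stage, candidates are enumerated with the paired strategy when
#' the two anchors have the same stage depth and the unpaired strategy when
#' the front stage is shallower; only same-stage pairs are admitted, since a
#' 1x1 stitch cannot change spatial resolution. Candidates are concatenated
#' in depth order and, when `prune = TRUE`, every second candidate (odd raw
#' index, counting from 0) is removed and the survivors re-indexed from 0 -
#' consecutive candidates are near-duplicates, so this halves the space.
#'
#' @param front,back [stitch_anchor()] objects built from the same input
#'   geometry.
#' @param prune drop odd-indexed candidates.
#' @return an object of class `stitching_space`: a `configs` table
#'   (config_id, raw_id, stage, local/flat cut and entry indices, stitch
#'   dims) and one stitch layer per candidate (uninitialized).
#' @export
build_space <- function(front, back, prune = TRUE) {
  stopifnot(inherits(front, "stitch_anchor"), inherits(back, "stitch_anchor"))
  fi <- front$model$block_info
  bi <- back$model$block_info
  configs <- NULL
  for (s in sort(unique(fi$stage))) {
    fa <- which(fi$stage == s)
    ba <- which(bi$stage == s)
    la <- length(fa); lb <- length(ba)
    if (!la || !lb) next
    cand <- if (la == lb) enumerate_paired(la, lb) else enumerate_unpaired(la, lb)
    if (!nrow(cand)) next
    configs <- rbind(configs, data.frame(
      stage = s, n_local = cand$n, m_local = cand$m,
      n_flat = fa[cand$n], m_flat = ba[cand$m],
      d_in = fi$dim[fa[cand$n]], d_out = bi$dim[ba[cand$m] - 1L]
    ))
  }
  if (is.null(configs) || !nrow(configs)) {
    stop("the stitching space is empty: no compatible candidate pairs",
         call. = FALSE)
  }
  configs$raw_id <- seq_len(nrow(configs)) - 1L
  if (prune) configs <- configs[configs$raw_id %% 2L == 0L, , drop = FALSE]
  configs$config_id <- seq_len(nrow(configs)) - 1L
  rownames(configs) <- NULL
  configs <- configs[, c("config_id", "raw_id", "stage", "n_local", "m_local",
                         "n_flat", "m_flat", "d_in", "d_out")]
  stitches <- lapply(seq_len(nrow(configs)), function(i) {
    new_stitch_layer(configs$d_in[i], configs$d_out[i])
  })
  structure(list(front = front, back = back, configs = configs,
                 stitches = stitches, pruned = prune),
            class = "stitching_space")
}

#' @export
print.stitching_space <- function(x, ...) {
  cat(sprintf("<stitching_space: %d configs (%s), %s -> %s>\n",
              nrow(x$configs), if (x$pruned) "pruned" else "raw",
              x$front$model$spec$name, x$back$model$spec$name))
  print(x$configs)
  invisible(x)
}

# run a model forward (no head), collecting the outputs of selected blocks
collect_activations <- function(model, x, blocks, train = FALSE) {
  info <- model$block_info
  out <- vector("list", nrow(info))
  x <- model$stem$forward(x, train)
  top <- max(blocks)
  for (s in 1:4) {
    in_stage <- which(info$stage == s)
    if (!length(in_stage) || min(in_stage) > top) break
    x <- model$stage_pe[[s]]$forward(x, train)
    for (b in in_stage) {
      if (b > top) break
      x <- model$blocks[[b]]$forward(x, train)
      if (b %in% blocks) out[[b]] <- x
    }
  }
  out
}

#' Initialize every stitch in a space by least squares
#'
#' Runs the initialization mini-batch (default 100 samples) through both
#' anchors, collects the raw block activations at each cut/entry point and
#' solves the least-squares problem per candidate.
#'
#' @param space a [build_space()] result.
#' @param images list of image matrices (already normalized) used as the
#'   initialization batch; 100 samples by convention.
#' @return the space, with all stitch layers initialized.
#' @export
init_space <- function(space, images) {
  xf <- images_to_fmap(images, space$front$model$spec$input_channels)
  cf <- space$configs
  acts_f <- collect_activations(space$front$model, xf, unique(cf$n_flat))
  acts_b <- collect_activations(space$back$model, xf, unique(cf$m_flat - 1L))
  for (i in seq_len(nrow(cf))) {
    A <- unclass(acts_f[[cf$n_flat[i]]])
    B <- unclass(acts_b[[cf$m_flat[i] - 1L]])
    st <- init_stitch_least_squares(A, B)
    space$stitches[[i]]$params$W <- st$params$W
    space$stitches[[i]]$params$b <- st$params$b
    space$stitches[[i]]$initialized <- TRUE
  }
  space
}

config_row <- function(space, config_id) {
  i <- match(config_id, space$configs$config_id)
  if (is.na(i)) {
    stop("no configuration with config_id ", config_id, " in this space",
         call. = FALSE)
  }
  i
}

#' Forward pass through one stitched configuration
#'
#' Runs the front anchor up to its cut block, maps the activations through
#' the 1x1 stitch, and continues through the back anchor from its entry
#' block to the classifier head.
#'
#' @param x an [fmap] image batch.
#' @param space an initialized [stitching_space][build_space()].
#' @param config_id configuration index (0-based, as in the space manifest).
#' @param train logical; training mode.
#' @return logits matrix `(batch, num_classes)`.
#' @export
stitched_forward <- function(x, space, config_id, train = FALSE) {
  i <- config_row(space, config_id)
  st <- space$stitches[[i]]
  if (!isTRUE(st$initialized)) {
    stop("stitch for config_id ", config_id,
         " is not initialized; run init_space() first", call. = FALSE)
  }
  cf <- space$configs[i, ]
  a <- forward_until(space$front$model, x, cf$n_flat, train)
  a <- st$forward(a, train)
  forward_from(space$back$model, a, cf$m_flat, train)
}

# parameters of the assembled stitched network: front prefix + stitch +
# back suffix (incl. later patch embeddings and head)
stitched_param_count <- function(space, config_id) {
  i <- config_row(space, config_id)
  cf <- space$configs[i, ]
  fm <- space$front$model; bm <- space$back$model
  finfo <- fm$block_info; binfo <- bm$block_info
  n_front <- n_layer_params(fm$stem) +
    sum(vapply(seq_len(cf$n_flat),
               function(b) n_layer_params(fm$blocks[[b]]), numeric(1))) +
    sum(vapply(unique(finfo$stage[finfo$block <= cf$n_flat]),
               function(s) n_layer_params(fm$stage_pe[[s]]), numeric(1)))
  n_back <- sum(vapply(cf$m_flat:nrow(binfo),
                       function(b) n_layer_params(bm$blocks[[b]]), numeric(1))) +
    sum(vapply(setdiff(unique(binfo$stage[binfo$block >= cf$m_flat]),
                       binfo$stage[cf$m_flat]),
               function(s) n_layer_params(bm$stage_pe[[s]]), numeric(1))) +
    (if (!is.null(bm$head_norm)) n_layer_params(bm$head_norm) else 0) +
    n_layer_params(bm$fc)
  as.integer(n_front + n_layer_params(space$stitches[[i]]) + n_back)
}

#' Write the space manifest
#'
#' One CSV row per configuration: cut/entry indices, stage, stitch
#' dimensions and parameter counts of the stitch and the assembled network.
#'
#' @param space a [stitching_space][build_space()].
#' @param path output CSV path.
#' @export
write_space_manifest <- function(space, path) {
  cf <- space$configs
  cf$stitch_params <- vapply(seq_len(nrow(cf)), function(i) {
    n_layer_params(space$stitches[[i]])
  }, numeric(1))
  cf$total_params <- vapply(cf$config_id, function(id) {
    stitched_param_count(space, id)
  }, numeric(1))
  utils::write.csv(cf, path, row.names = FALSE)
  invisible(path)
}

walk_layers_of_type <- function(layer, type, fn) {
  if (layer$type == type) fn(layer)
  for (ch in layer$children) walk_layers_of_type(ch, type, fn)
  invisible(NULL)
}

snapshot_bn_stats <- function(models) {
  out <- list()
  for (m in models) {
    walk_layers_of_type(m, "batchnorm", function(l) {
      out[[length(out) + 1]] <<- list(layer = l, mean = l$running_mean,
                                      var = l$running_var)
    })
  }
  out
}

restore_bn_stats <- function(snapshot) {
  for (e in snapshot) {
    e$layer$running_mean <- e$mean
    e$layer$running_var <- e$var
  }
  invisible(NULL)
}

#' Recalibrate normalization statistics for one configuration
#'
#' The anchors' blocks are shared between stitched configurations, but each
#' configuration feeds them a different activation distribution, so a single
#' set of batch-normalization running statistics cannot serve every
#' configuration at evaluation time. This runs one training-mode forward
#' pass of the whole calibration set (as a single batch, with update
#' momentum 1 and stochastic depth disabled) through the configuration's
#' path: the batch statistics then equal the population statistics, which
#' makes the update exact and self-consistent with evaluation-mode
#' normalization. Statistics of layers off the path are untouched.
#'
#' Call it (or let [five_fold_run()] call it) before evaluating a
#' configuration; snapshot and restore around it when evaluating several
#' configurations against the same anchors.
#'
#' @param space an initialized [stitching_space][build_space()].
#' @param config_id configuration to calibrate.
#' @param images list of image matrices (already normalized), the
#'   calibration set.
#' @return the space, invisibly (statistics are updated in place).
#' @export
calibrate_stitched <- function(space, config_id, images) {
  models <- list(space$front$model, space$back$model)
  dp_saved <- list()
  for (m in models) {
    walk_layers_of_type(m, "droppath", function(l) {
      dp_saved[[length(dp_saved) + 1]] <<- list(layer = l, p = l$p)
      l$p <- 0
    })
  }
  for (m in models) {
    walk_layers_of_type(m, "batchnorm", function(l) l$momentum <- 1)
  }
  x <- images_to_fmap(images, space$front$model$spec$input_channels)
  invisible(stitched_forward(x, space, config_id, train = TRUE))
  for (m in models) {
    walk_layers_of_type(m, "batchnorm", function(l) l$momentum <- 0.1)
  }
  for (e in dp_saved) e$layer$p <- e$p
  invisible(space)
}

# layers on the active path of one configuration (for the optimizer step)
active_path_modules <- function(space, config_id, freeze_anchors = FALSE) {
  i <- config_row(space, config_id)
  if (freeze_anchors) return(list(space$stitches[[i]]))
  cf <- space$configs[i, ]
  fm <- space$front$model; bm <- space$back$model
  finfo <- fm$block_info; binfo <- bm$block_info
  mods <- list(fm$stem)
  for (s in unique(finfo$stage[finfo$block <= cf$n_flat])) {
    mods <- c(mods, list(fm$stage_pe[[s]]))
  }
  mods <- c(mods, fm$blocks[seq_len(cf$n_flat)], list(space$stitches[[i]]))
  mods <- c(mods, bm$blocks[cf$m_flat:nrow(binfo)])
  for (s in setdiff(unique(binfo$stage[binfo$block >= cf$m_flat]),
                    binfo$stage[cf$m_flat])) {
    mods <- c(mods, list(bm$stage_pe[[s]]))
  }
  if (!is.null(bm$head_norm)) mods <- c(mods, list(bm$head_norm))
  c(mods, list(bm$fc))
}

#' Train a stitching space by random-configuration sampling
#'
#' Each iteration draws one configuration uniformly at random, runs the next
#' mini-batch through that stitched path with focal loss and updates all
#' parameters on the active path (anchor prefix/suffix and stitch, or only
#' the stitch when `freeze_anchors`) with AdamW under a cosine-annealed
#' learning rate. Parameters off the active path are untouched that step.
#' Fully reproducible given `seed`.
#'
#' @param space an initialized [stitching_space][build_space()].
#' @param dataset an `oct_dataset` (images already unit-scaled; normalization
#'   applied here).
#' @param iterations number of training iterations.
#' @param batch_size mini-batch size.
#' @param lr base learning rate, scaled linearly with `batch_size / 32`.
#' @param weight_decay AdamW decoupled weight decay.
#' @param loss [focal_params()] list; `NULL` selects focal loss with gamma 2
#'   and inverse-class-frequency weights computed from `dataset` (the same
#'   recipe anchor pre-training uses).
#' @param augment [augment_params()] list, or `NULL` to disable.
#' @param norm [normalize_params()] list.
#' @param freeze_anchors train only the stitch layers.
#' @param seed integer seed for configuration sampling, batch order and
#'   augmentation.
#' @return the space, with a `train_log` data frame attached
#'   (iteration, config_id, loss, lr).
#' @export
train_stitched <- function(space, dataset, iterations = 200, batch_size = 32,
                           lr = 5e-5, weight_decay = 0.01,
                           loss = NULL,
                           augment = augment_params(),
                           norm = normalize_params("NEH"),
                           freeze_anchors = FALSE, seed = 1) {
  if (!nrow(space$configs)) stop("empty stitching space", call. = FALSE)
  for (st in space$stitches) {
    if (!isTRUE(st$initialized)) {
      stop("all stitches must be initialized before training; run init_space()",
           call. = FALSE)
    }
  }
  if (is.null(loss)) {
    freq <- tabulate(dataset$labels, nlevels(dataset$labels))
    alpha <- ifelse(freq > 0, 1 / pmax(freq, 1), 0)
    alpha <- alpha / sum(alpha) * sum(freq > 0)
    loss <- focal_params(gamma = 2, alpha = alpha)
  }
  set.seed(seed)
  n <- length(dataset$images)
  base_lr <- lr * batch_size / 32
  sched <- lr_cosine_schedule(base_lr, iterations)
  all_modules <- c(list(space$front$model, space$back$model), space$stitches)
  opt <- adamw(all_modules, lr = base_lr, weight_decay = weight_decay)
  ids <- space$configs$config_id
  order_idx <- sample(n)
  pos <- 1L
  log <- data.frame(iteration = seq_len(iterations),
                    config_id = NA_integer_, loss = NA_real_, lr = NA_real_)
  labs <- as.integer(dataset$labels)
  for (it in seq_len(iterations)) {
    cid <- ids[sample.int(length(ids), 1)]
    if (pos + batch_size - 1L > n) {
      order_idx <- sample(n)
      pos <- 1L
    }
    take <- order_idx[pos:(pos + batch_size - 1L)]
    pos <- pos + batch_size
    imgs <- lapply(dataset$images[take], function(im) {
      if (is.null(augment)) normalize_image(im, norm)
      else augment_image(im, augment, norm)
    })
    x <- images_to_fmap(imgs, space$front$model$spec$input_channels)
    for (mod in all_modules) zero_grads(mod)
    logits <- stitched_forward(x, space, cid, train = TRUE)
    fl <- focal_loss(logits, labs[take], loss, return_grad = TRUE)
    i <- config_row(space, cid)
    cf <- space$configs[i, ]
    dy <- backward_from(space$back$model, fl$grad, cf$m_flat)
    dy <- space$stitches[[i]]$backward(dy)
    backward_until(space$front$model, dy, cf$n_flat)
    lr_it <- sched(it)
    opt$step(lr = lr_it,
             modules = active_path_modules(space, cid, freeze_anchors))
    log$config_id[it] <- cid; log$loss[it] <- fl$loss; log$lr[it] <- lr_it
  }
  space$train_log <- log
  space
}
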