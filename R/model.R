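# Model builder: stem -> 4 stages (patch embedding + ECB/LTB blocks) ->
# global average pool -> classifier, plus the block-indexed access paths the
# stitching module cuts along.

#' Build a runnable model from a specification
#'
#' Materializes the declarative specification into a network with allocated
#' weights: a 4-convolution stem with total spatial stride 4, four stages
#' (average-pool + 1x1 patch embedding, then the stage's block groups), a
#' global average pool and a linear classifier head. With 224x224 input the
#' stage outputs have spatial sizes 56, 28, 14 and 7. Stochastic depth rates
#' increase linearly with block depth up to `spec$path_dropout`.
#'
#' @param spec a [medvit_spec()].
#' @param seed optional integer; when given, weight initialization is
#'   reproducible.
#' @return an object of class `medvit_model`.
#' @examples
#' m <- build_medvit(medvit_spec("reduced_micro"), seed = 1)
#' count_parameters(m)
#' @export
build_medvit <- function(spec, seed = NULL) {
  validate_medvit_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  conv <- spec$conventions
  self <- new_layer("medvit")
  self$spec <- spec

  # stem
  stem_layers <- list()
  cin <- spec$input_channels
  for (cs in spec$stem) {
    stem_layers <- c(stem_layers, list(
      conv2d(cin, cs$out_channels, kernel = cs$kernel, stride = cs$stride,
             bias = conv$conv_bias),
      batchnorm(cs$out_channels),
      act_layer("relu")
    ))
    cin <- cs$out_channels
  }
  self$stem <- do.call(sequential, stem_layers)

  # enumerate blocks first to scale stochastic depth linearly with depth
  plan <- list()
  for (s in seq_along(spec$stages)) {
    st <- spec$stages[[s]]
    for (rep_g in seq_len(st$group_repeat)) {
      for (g in st$groups) {
        for (r in seq_len(g$repeat_)) {
          plan[[length(plan) + 1]] <- list(stage = s, kind = g$block_kind,
                                           dim = g$dim,
                                           esa_pool = st$esa_pool_stride)
        }
      }
    }
  }
  nb <- length(plan)
  dpr <- if (nb > 1) spec$path_dropout * (seq_len(nb) - 1) / (nb - 1) else 0

  self$stage_pe <- vector("list", 4)
  self$blocks <- vector("list", nb)
  info <- data.frame(
    block = seq_len(nb), stage = NA_integer_, kind = NA_character_,
    cin = NA_integer_, dim = NA_integer_, stringsAsFactors = FALSE
  )
  bi <- 0L
  for (s in seq_along(spec$stages)) {
    st <- spec$stages[[s]]
    self$stage_pe[[s]] <- patch_embed(cin, st$channels, st$pool_stride,
                                      conv$conv_bias)
    cin <- st$channels
    for (p in plan) {
      if (p$stage != s) next
      bi <- bi + 1L
      blk <- if (p$kind == "ECB") {
        ecb_block(cin, p$dim, conv, dpr[bi])
      } else {
        ltb_block(cin, p$dim, p$esa_pool, conv, dpr[bi])
      }
      self$blocks[[bi]] <- blk
      info$stage[bi] <- s; info$kind[bi] <- p$kind
      info$cin[bi] <- cin; info$dim[bi] <- p$dim
      cin <- p$dim
    }
  }
  self$block_info <- info
  self$final_dim <- cin

  self$head_norm <- if (conv$head_norm) batchnorm(cin) else NULL
  self$gap <- global_avgpool()
  self$fc <- linear(cin, spec$num_classes)
  self$children <- c(list(self$stem), self$stage_pe, self$blocks,
                     if (!is.null(self$head_norm)) list(self$head_norm),
                     list(self$gap, self$fc))
  class(self) <- c("medvit_model", "osn_layer")

  self$forward <- function(x, train = FALSE) {
    x <- self$stem$forward(x, train)
    for (s in 1:4) {
      x <- self$stage_pe[[s]]$forward(x, train)
      for (b in which(info$stage == s)) {
        x <- self$blocks[[b]]$forward(x, train)
      }
    }
    head_forward(self, x, train)
  }
  self$backward <- function(dy) {
    dy <- head_backward(self, dy)
    for (s in 4:1) {
      for (b in rev(which(info$stage == s))) {
        dy <- self$blocks[[b]]$backward(dy)
      }
      dy <- self$stage_pe[[s]]$backward(dy)
    }
    self$stem$backward(dy)
  }
  self
}

head_forward <- function(model, x, train = FALSE) {
  if (!is.null(model$head_norm)) x <- model$head_norm$forward(x, train)
  model$fc$forward(model$gap$forward(x, train), train)
}

head_backward <- function(model, dlogits) {
  dy <- model$gap$backward(model$fc$backward(dlogits))
  if (!is.null(model$head_norm)) dy <- model$head_norm$backward(dy)
  dy
}

# run stem + patch embeddings + blocks 1..n_cut (inclusive, flat block index)
forward_until <- function(model, x, n_cut, train = FALSE) {
  info <- model$block_info
  stopifnot(n_cut >= 1, n_cut <= nrow(info))
  x <- model$stem$forward(x, train)
  for (s in 1:4) {
    blocks_s <- which(info$stage == s)
    if (!length(blocks_s) || min(blocks_s) > n_cut) break
    x <- model$stage_pe[[s]]$forward(x, train)
    for (b in blocks_s) {
      if (b > n_cut) break
      x <- model$blocks[[b]]$forward(x, train)
    }
  }
  x
}

backward_until <- function(model, dy, n_cut) {
  info <- model$block_info
  last_stage <- info$stage[n_cut]
  for (s in last_stage:1) {
    for (b in rev(which(info$stage == s & info$block <= n_cut))) {
      dy <- model$blocks[[b]]$backward(dy)
    }
    dy <- model$stage_pe[[s]]$backward(dy)
  }
  model$stem$backward(dy)
}

# run blocks m_entry..end (flat index), later patch embeddings, and the head
forward_from <- function(model, x, m_entry, train = FALSE) {
  info <- model$block_info
  stopifnot(m_entry >= 1, m_entry <= nrow(info))
  entry_stage <- info$stage[m_entry]
  for (s in entry_stage:4) {
    if (s > entry_stage) x <- model$stage_pe[[s]]$forward(x, train)
    for (b in which(info$stage == s & info$block >= m_entry)) {
      x <- model$blocks[[b]]$forward(x, train)
    }
  }
  head_forward(model, x, train)
}

backward_from <- function(model, dlogits, m_entry) {
  info <- model$block_info
  entry_stage <- info$stage[m_entry]
  dy <- head_backward(model, dlogits)
  for (s in 4:entry_stage) {
    for (b in rev(which(info$stage == s & info$block >= m_entry))) {
      dy <- model$blocks[[b]]$backward(dy)
    }
    if (s > entry_stage) dy <- model$stage_pe[[s]]$backward(dy)
  }
  dy
}

#' Count trainable parameters
#'
#' The exact number of trainable scalar parameters (convolution and linear
#' weights and biases, normalization scales and shifts). Normalization
#' running statistics are buffers, not parameters, and are excluded.
#'
#' @param model a built model (or any layer/module of this package).
#' @return integer parameter count.
#' @examples
#' count_parameters(build_medvit(medvit_spec("reduced_micro"), seed = 1))
#' @export
count_parameters <- function(model) {
  as.integer(n_layer_params(model))
}

#' @export
print.medvit_model <- function(x, ...) {
  cat(sprintf(
    "<medvit_model '%s': %d blocks, %s parameters (%.2fM)>\n",
    x$spec$name, nrow(x$block_info),
    format(count_parameters(x), big.mark = ","), count_parameters(x) / 1e6
  ))
  invisible(x)
}

# ---- weight state ----------------------------------------------------------

model_state <- function(model) {
  lapply(collect_layers(model), function(l) {
    st <- list(params = l$params)
    if (l$type == "batchnorm") {
      st$running_mean <- l$running_mean
      st$running_var <- l$running_var
    }
    st
  })
}

load_model_state <- function(model, state) {
  layers <- collect_layers(model)
  stopifnot(length(layers) == length(state))
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    stopifnot(identical(lapply(l$params, length),
                        lapply(state[[i]]$params, length)))
    l$params <- state[[i]]$params
    if (l$type == "batchnorm") {
      l$running_mean <- state[[i]]$running_mean
      l$running_var <- state[[i]]$running_var
    }
  }
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' A checkpoint directory holds the weights, a JSON sidecar with the model
#' specification (round-trippable through [spec_from_json()]) and a JSON
#' training-state record (epoch, best validation AUC).
#'
#' @param model a built model.
#' @param dir checkpoint directory (created if missing).
#' @param state named list with at least `epoch` and `best_val_auc`.
#' @return the checkpoint directory, invisibly.
#' @export
save_checkpoint <- function(model, dir, state = list(epoch = 0L,
                                                     best_val_auc = NA_real_)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  saveRDS(model_state(model), file.path(dir, "weights.rds"))
  spec_to_json(model$spec, file.path(dir, "spec.json"))
  jsonlite::write_json(state, file.path(dir, "training_state.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(dir) {
  spec <- spec_from_json(file.path(dir, "spec.json"))
  model <- build_medvit(spec)
  load_model_state(model, readRDS(file.path(dir, "weights.rds")))
  state <- jsonlite::read_json(file.path(dir, "training_state.json"),
                               simplifyVector = TRUE)
  list(model = model, state = state)
}

#' Stack grayscale images into a feature map
#'
#' Unit-scaled grayscale image matrices are replicated across the model's
#' input channels.
#'
#' @param images list of equal-sized numeric matrices in `[0, 1]` (or already
#'   normalized values).
#' @param channels number of input channels to replicate to.
#' @return an [fmap] with `length(images)` samples.
#' @export
images_to_fmap <- function(images, channels = 3) {
  stopifnot(length(images) >= 1)
  h <- nrow(images[[1]]); w <- ncol(images[[1]])
  one <- function(img) as.numeric(t(img)) # raster order: rows, then columns
  v <- unlist(lapply(images, one), use.names = FALSE)
  fmap(matrix(rep(v, times = channels), ncol = channels), length(images), h, w)
}
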