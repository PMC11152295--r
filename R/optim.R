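# AdamW optimizer with decoupled weight decay, plus the two learning-rate
# schedules used by pre-training (step decay) and stitching (cosine).

#' AdamW optimizer
#'
#' Adaptive-moment estimation with decoupled weight decay. State (first and
#' second moments, step counter) is held per parameter; `step()` applies one
#' update to the supplied modules (or to all registered modules) from the
#' gradients currently accumulated in the layers.
#'
#' @param modules list of modules whose parameters are optimized.
#' @param lr base learning rate.
#' @param betas exponential decay rates of the moment estimates.
#' @param eps numerical stabilizer.
#' @param weight_decay decoupled weight-decay coefficient.
#' @return an optimizer object with `$step(lr = NULL, modules = NULL)`.
#' @export
adamw <- function(modules, lr = 5e-5, betas = c(0.9, 0.999), eps = 1e-8,
                  weight_decay = 0.01) {
  if (inherits(modules, "osn_layer")) modules <- list(modules)
  self <- new.env(parent = emptyenv())
  self$lr <- lr; self$betas <- betas; self$eps <- eps
  self$weight_decay <- weight_decay
  self$layers <- unlist(lapply(modules, collect_layers), recursive = FALSE)
  self$state <- new.env(parent = emptyenv())
  key_of <- function(l) format.default(l) # environment address is stable
  for (l in self$layers) {
    self$state[[key_of(l)]] <- list(
      m = lapply(l$params, function(p) p * 0),
      v = lapply(l$params, function(p) p * 0),
      t = 0L
    )
  }
  self$step <- function(lr = NULL, modules = NULL) {
    lr <- lr %||% self$lr
    layers <- if (is.null(modules)) {
      self$layers
    } else {
      if (inherits(modules, "osn_layer")) modules <- list(modules)
      unlist(lapply(modules, collect_layers), recursive = FALSE)
    }
    b1 <- self$betas[1]; b2 <- self$betas[2]
    for (l in layers) {
      k <- key_of(l)
      st <- self$state[[k]]
      if (is.null(st)) next # layer not registered with this optimizer
      st$t <- st$t + 1L
      bc1 <- 1 - b1^st$t
      bc2 <- 1 - b2^st$t
      for (pn in names(l$params)) {
        g <- l$grads[[pn]]
        if (is.null(g)) next
        st$m[[pn]] <- b1 * st$m[[pn]] + (1 - b1) * g
        st$v[[pn]] <- b2 * st$v[[pn]] + (1 - b2) * g * g
        mhat <- st$m[[pn]] / bc1
        vhat <- st$v[[pn]] / bc2
        l$params[[pn]] <- l$params[[pn]] -
          lr * (mhat / (sqrt(vhat) + self$eps) +
                  self$weight_decay * l$params[[pn]])
      }
      self$state[[k]] <- st
    }
    invisible(NULL)
  }
  class(self) <- "osn_optimizer"
  self
}

#' Learning-rate schedules
#'
#' `lr_step_schedule` multiplies the base rate by `factor` once the milestone
#' epoch is reached (pre-training). `lr_cosine_schedule` anneals from the
#' base rate to zero over `total` iterations without restarts (stitching).
#'
#' @param base base learning rate.
#' @param factor decay multiplier.
#' @param milestone epoch (1-based) at which the decay is applied.
#' @return a function of the epoch / iteration returning the learning rate.
#' @export
lr_step_schedule <- function(base, factor = 0.1, milestone = 50) {
  function(epoch) if (epoch >= milestone + 1) base * factor else base
}

#' @rdname lr_step_schedule
#' @param total total number of iterations of the cosine annealing.
#' @export
lr_cosine_schedule <- function(base, total) {
  function(iter) base * 0.5 * (1 + cos(pi * min(iter - 1, total) / total))
}
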