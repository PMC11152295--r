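# Declarative model specifications: the printed architecture table (stem,
# four stages of ECB/LTB groups) plus the block-internal conventions the
# table does not fix.

#' Block-internal conventions
#'
#' The architecture table fixes channel widths, strides, block kinds and
#' repeats; everything inside the blocks (feed-forward expansion ratios, head
#' size, the transformer/convolution channel split of the LTB, use of
#' squeeze-excitation, bias and normalization placement) follows the
#' conventions of this block family. The defaults below are the package's
#' reference convention; the micro and tiny parameter counts of 24.50 and
#' 31.14 million are obtained under exactly these settings.
#'
#' @param ecb_mlp_ratio LFFN expansion ratio inside ECB blocks.
#' @param ltb_mlp_ratio LFFN expansion ratio inside LTB blocks.
#' @param head_dim channels per attention head (MHCA and ESA).
#' @param mix_ratio fraction of LTB channels given to the self-attention path
#'   (rounded to a multiple of `head_dim`).
#' @param se use a squeeze-excitation gate in the LFFN.
#' @param attn_bias biases on the ESA query/key/value/output projections.
#' @param conv_bias biases on convolutions.
#' @param mhca_proj_norm batch normalization after the MHCA output projection.
#' @param pool_kv_norm batch normalization on ESA's pooled keys/values.
#' @param head_norm batch normalization before the classifier pooling.
#' @return a named list of conventions.
#' @export
medvit_conventions <- function(ecb_mlp_ratio = 3, ltb_mlp_ratio = 2,
                               head_dim = 32L, mix_ratio = 0.625, se = TRUE,
                               attn_bias = FALSE, conv_bias = TRUE,
                               mhca_proj_norm = TRUE, pool_kv_norm = TRUE,
                               head_norm = TRUE) {
  list(
    ecb_mlp_ratio = as.numeric(ecb_mlp_ratio),
    ltb_mlp_ratio = as.numeric(ltb_mlp_ratio),
    head_dim = as.integer(head_dim), mix_ratio = as.numeric(mix_ratio),
    se = se,
    attn_bias = attn_bias, conv_bias = conv_bias,
    mhca_proj_norm = mhca_proj_norm, pool_kv_norm = pool_kv_norm,
    head_norm = head_norm
  )
}

#' Convolution layer specification
#' @param kernel kernel edge length in pixels (1 or 3).
#' @param out_channels output channels.
#' @param stride stride (1 or 2).
#' @param depthwise depthwise convolution flag.
#' @export
conv_spec <- function(kernel, out_channels, stride = 1, depthwise = FALSE) {
  stopifnot(kernel %in% c(1, 3), out_channels >= 1, stride %in% c(1, 2))
  list(kernel = as.integer(kernel), out_channels = as.integer(out_channels),
       stride = as.integer(stride), depthwise = isTRUE(depthwise))
}

#' Block-group specification
#' @param block_kind "ECB" or "LTB".
#' @param dim output channels of the blocks in the group.
#' @param repeat_ number of consecutive blocks of this kind.
#' @export
block_group_spec <- function(block_kind = c("ECB", "LTB"), dim, repeat_ = 1) {
  block_kind <- match.arg(block_kind)
  stopifnot(dim >= 1, repeat_ >= 1)
  list(block_kind = block_kind, dim = as.integer(dim),
       repeat_ = as.integer(repeat_))
}

#' Stage specification
#' @param channels channels after the stage's 1x1 patch-embedding projection.
#' @param pool_stride stride of the patch-embedding average pool (1 = none).
#' @param groups ordered list of [block_group_spec()] entries.
#' @param group_repeat repetition count of the whole bracketed group.
#' @param esa_pool_stride key/value pooling stride of ESA blocks in the stage.
#' @export
stage_spec <- function(channels, pool_stride, groups, group_repeat = 1,
                       esa_pool_stride = 1) {
  stopifnot(group_repeat >= 1, length(groups) >= 1)
  list(channels = as.integer(channels), pool_stride = as.integer(pool_stride),
       groups = groups, group_repeat = as.integer(group_repeat),
       esa_pool_stride = as.integer(esa_pool_stride))
}

#' Model specification for the micro/tiny hybrid backbones
#'
#' Returns the declarative description of a model variant: the 4-convolution
#' stem, the four stages with their patch embeddings and ECB/LTB block
#' groups, the stochastic-depth rate and the classifier width. `"micro"` and
#' `"tiny"` reproduce the printed architecture table (identical except that
#' tiny repeats the stage-3 group twice and uses path dropout 0.1 instead of
#' 0.05). The `"reduced_*"` variants shrink all channels by 8x and all
#' repeats to 1 for desk-scale experiments on small images.
#'
#' @param kind one of "micro", "tiny", "reduced_micro", "reduced_tiny".
#' @param num_classes classifier outputs (3: normal / drusen / CNV).
#' @param input_channels input image channels (grayscale replicated to 3).
#' @param conventions block-internal conventions, see [medvit_conventions()].
#' @return an object of class `medvit_spec`.
#' @examples
#' spec <- medvit_spec("micro")
#' spec$stages[[3]]$group_repeat
#' @export
medvit_spec <- function(kind = c("micro", "tiny", "reduced_micro",
                                 "reduced_tiny"),
                        num_classes = 3, input_channels = 3,
                        conventions = NULL) {
  kind <- match.arg(kind)
  reduced <- grepl("^reduced", kind)
  tiny <- grepl("tiny$", kind)
  div <- if (reduced) 8L else 1L
  rep1 <- function(r) if (reduced) 1L else as.integer(r)
  if (is.null(conventions)) {
    conventions <- if (reduced) {
      medvit_conventions(head_dim = 4L)
    } else {
      medvit_conventions()
    }
  }
  ch <- function(c) as.integer(c / div)
  stem <- list(
    conv_spec(3, ch(64), 2), conv_spec(3, ch(32), 1),
    conv_spec(3, ch(64), 1), conv_spec(3, ch(64), 2)
  )
  stages <- list(
    stage_spec(ch(96), 1, list(block_group_spec("ECB", ch(96), rep1(3)))),
    stage_spec(ch(192), 2, list(
      block_group_spec("ECB", ch(192), rep1(3)),
      block_group_spec("LTB", ch(256), 1L)
    ), esa_pool_stride = 4),
    stage_spec(ch(384), 2, list(
      block_group_spec("ECB", ch(384), rep1(4)),
      block_group_spec("LTB", ch(512), 1L)
    ), group_repeat = if (tiny) 2L else 1L, esa_pool_stride = 2),
    stage_spec(ch(768), 2, list(
      block_group_spec("ECB", ch(768), rep1(2)),
      block_group_spec("LTB", ch(1024), 1L)
    ), esa_pool_stride = 1)
  )
  new_medvit_spec(
    name = kind, stem = stem, stages = stages,
    path_dropout = if (tiny) 0.1 else 0.05,
    num_classes = as.integer(num_classes),
    input_channels = as.integer(input_channels),
    conventions = conventions
  )
}

new_medvit_spec <- function(name, stem, stages, path_dropout, num_classes,
                            input_channels, conventions) {
  spec <- list(
    name = name, stem = stem, stages = stages, path_dropout = path_dropout,
    num_classes = num_classes, input_channels = input_channels,
    conventions = conventions
  )
  class(spec) <- "medvit_spec"
  validate_medvit_spec(spec)
  spec
}

validate_medvit_spec <- function(spec) {
  if (length(spec$stages) != 4) {
    stop("a model specification must have exactly 4 stages", call. = FALSE)
  }
  if (length(spec$stem) != 4) {
    stop("the stem must consist of 4 convolutions", call. = FALSE)
  }
  if (spec$path_dropout < 0 || spec$path_dropout > 1) {
    stop("path_dropout must lie in [0, 1]", call. = FALSE)
  }
  if (spec$num_classes < 2) stop("num_classes must be >= 2", call. = FALSE)
  for (s in spec$stages) {
    if (s$group_repeat < 1 || !length(s$groups)) {
      stop("every stage needs a non-empty block group", call. = FALSE)
    }
    for (g in s$groups) {
      if (!g$block_kind %in% c("ECB", "LTB")) {
        stop("block kind must be ECB or LTB", call. = FALSE)
      }
    }
  }
  invisible(spec)
}

#' @export
print.medvit_spec <- function(x, ...) {
  cat(sprintf("<medvit_spec '%s': %d classes, path dropout %.2f>\n",
              x$name, x$num_classes, x$path_dropout))
  for (i in seq_along(x$stages)) {
    s <- x$stages[[i]]
    gg <- paste(vapply(s$groups, function(g) {
      sprintf("%s%d x%d", g$block_kind, g$dim, g$repeat_)
    }, character(1)), collapse = " ")
    cat(sprintf("  stage %d: C=%d pool=%d [%s] x%d\n",
                i, s$channels, s$pool_stride, gg, s$group_repeat))
  }
  invisible(x)
}

#' Serialize / deserialize a model specification as JSON
#'
#' The JSON sidecar written next to every checkpoint; round-trippable.
#'
#' @param spec a `medvit_spec`.
#' @param path file path.
#' @export
spec_to_json <- function(spec, path) {
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname spec_to_json
#' @export
spec_from_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  fix_int <- function(x) {
    if (is.list(x)) return(lapply(x, fix_int))
    x
  }
  raw <- fix_int(raw)
  stem <- lapply(raw$stem, function(s) {
    conv_spec(s$kernel, s$out_channels, s$stride, isTRUE(s$depthwise))
  })
  stages <- lapply(raw$stages, function(s) {
    stage_spec(
      s$channels, s$pool_stride,
      lapply(s$groups, function(g) {
        block_group_spec(g$block_kind, g$dim, g$repeat_)
      }),
      s$group_repeat, s$esa_pool_stride
    )
  })
  conv <- do.call(medvit_conventions, raw$conventions)
  new_medvit_spec(raw$name, stem, stages, raw$path_dropout, raw$num_classes,
                  raw$input_channels, conv)
}
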