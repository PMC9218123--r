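#' Model configuration for the nested U-shaped density-map network
#'
#' The network is a two-level nested U: the top level is a U-shaped
#' encoder--decoder of residual U blocks (RSU), and each block contains its own
#' inner encoder--decoder. Every decoder block (and the bottleneck) emits a
#' side logit map, upsampled bilinearly to output resolution; the side maps
#' are fused by a 1x1 convolution into the final logit map. Probability maps
#' are `sigmoid(beta * S_i)`; in `"dm"` mode `beta` is fixed at 1, in
#' `"sndm"` mode it is predicted per image by a bypass head (global average
#' pooling of the deepest encoder block, two fully connected layers, and a
#' scaled-sigmoid activation `lambda * sigmoid(z)` bounding `beta` to
#' `(0, lambda)`).
#'
#' @param mode `"dm"` (plain density map) or `"sndm"` (self-normalized).
#' @param input_size square input side in pixels; must be divisible by
#'   `2^(stage + rsu_depth)` at every stage.
#' @param n_stages number of top-level encoder stages including the
#'   bottleneck; the model has `2 * n_stages - 1` blocks and `n_stages` side
#'   outputs. The full-scale layout uses 6 stages (11 blocks, 6 side outputs).
#' @param base_channels channels of the first stage; deeper stages double up
#'   to `channel_cap`.
#' @param rsu_depths inner-U depth per block (length `2 * n_stages - 1`,
#'   encoders first, then decoders shallow-to-deep); a scalar is recycled.
#' @param dropout_rate spatial dropout rate applied inside every block (after
#'   the inner bottleneck and the inner decoder output); identical in both
#'   modes so Monte Carlo dropout is available for either.
#' @param beta_activation `"scaled_sigmoid"` (default, bound `lambda`) or
#'   `"relu"` (unbounded above).
#' @param lambda scale of the beta activation; default 1.5.
#' @param beta_hidden width of the bypass head's hidden layer.
#' @param beta_lr_scale learning-rate multiplier for the bypass head's
#'   parameters once training has warmed up (default 1). Together with
#'   [train_config()]'s `beta_freeze_epochs` this keeps `beta` at its
#'   no-correction initialization while the logit maps are still badly
#'   scaled (early gradients otherwise slam `beta` into the activation's
#'   saturation, where recovery is slow), then lets the head learn its
#'   per-image correction at full rate.
#' @param channel_cap upper bound on per-stage channels.
#' @param seed integer seed for parameter initialization.
#' @return object of class `model_config`.
#' @export
model_config <- function(mode = c("dm", "sndm"), input_size = 96L,
                         n_stages = 3L, base_channels = 4L,
                         rsu_depths = 1L, dropout_rate = 0.1,
                         beta_activation = c("scaled_sigmoid", "relu"),
                         lambda = 1.5, beta_hidden = 32L,
                         beta_lr_scale = 1,
                         channel_cap = 512L, seed = 1L) {
  mode <- match.arg(mode)
  beta_activation <- match.arg(beta_activation)
  if (n_stages < 2) stop_sndm("`n_stages` must be >= 2")
  assert_scalar_number(lambda, "lambda", lower = 1e-8)
  assert_scalar_number(dropout_rate, "dropout_rate", 0, 0.999)
  n_blocks <- 2L * n_stages - 1L
  if (length(rsu_depths) == 1L) rsu_depths <- rep(as.integer(rsu_depths), n_blocks)
  if (length(rsu_depths) != n_blocks) {
    stop_sndm("`rsu_depths` must have length %d (one per block)", n_blocks)
  }
  structure(list(mode = mode, input_size = as.integer(input_size),
                 n_stages = as.integer(n_stages),
                 base_channels = as.integer(base_channels),
                 rsu_depths = as.integer(rsu_depths),
                 dropout_rate = dropout_rate,
                 beta_activation = beta_activation, lambda = lambda,
                 beta_hidden = as.integer(beta_hidden),
                 beta_lr_scale = beta_lr_scale,
                 channel_cap = as.integer(channel_cap),
                 seed = as.integer(seed)),
            class = "model_config")
}

#' Full-scale stage layout
#'
#' The configuration mirroring the published architecture scale: 6 encoder
#' stages and 5 decoder stages (11 blocks), 6 side outputs plus the fused map.
#' Inputs at this scale are high-resolution dish photographs resized to
#' `input_size`; the output map has the same side. Intended for structure
#' inspection and (GPU-scale) training outside this package's desk-scale
#' tests.
#'
#' @inheritParams model_config
#' @return a `model_config` with 11 blocks.
#' @export
full_scale_config <- function(mode = "sndm", input_size = 1024L,
                              base_channels = 64L, seed = 1L) {
  model_config(mode = mode, input_size = input_size, n_stages = 6L,
               base_channels = base_channels,
               rsu_depths = c(5L, 4L, 3L, 2L, 2L, 1L, 2L, 2L, 3L, 4L, 5L),
               seed = seed)
}

#' Build a density-map model
#'
#' Allocates and deterministically initializes the network described by a
#' [model_config()]. The same seed always yields bit-identical parameters;
#' the shared trunk (everything except the beta head) is initialized from the
#' same RNG draws in both modes, so a `"dm"` and an `"sndm"` model built with
#' one seed share trunk weights exactly.
#'
#' @param config a [model_config()].
#' @return object of class `sndm_model` (external model handle plus config).
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "model_config"))
  ptr <- with_seed(config$seed, cpp_net_create(unclass(config)))
  structure(list(ptr = ptr, config = config), class = "sndm_model")
}

#' @export
print.sndm_model <- function(x, ...) {
  d <- cpp_net_describe(x$ptr)
  cat(sprintf("<sndm_model> mode=%s, %d blocks, %d side outputs, %s params, input %dpx\n",
              d$mode, d$n_blocks, d$n_side_outputs,
              format(d$n_params, big.mark = ","), x$config$input_size))
  invisible(x)
}

#' Structural description of a model
#' @param model an `sndm_model`.
#' @return list with `n_blocks`, `n_side_outputs`, `n_params`, `channels`,
#'   `mode`.
#' @export
describe_model <- function(model) {
  stopifnot(inherits(model, "sndm_model"))
  cpp_net_describe(model$ptr)
}

#' Get or set the flat parameter vector of a model
#'
#' Useful for checkpointing, checksums and weight surgery in tests.
#' @param model an `sndm_model`.
#' @param theta numeric vector as returned by `model_weights()`.
#' @return `model_weights()` returns a numeric vector.
#' @export
model_weights <- function(model) {
  as.numeric(cpp_net_get_params(model$ptr))
}

#' @rdname model_weights
#' @export
set_model_weights <- function(model, theta) {
  cpp_net_set_params(model$ptr, theta)
  invisible(model)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the serialized weights together with
#' the embedded [model_config()], so `load_model()` rebuilds the exact model.
#'
#' @param model an `sndm_model`.
#' @param path checkpoint file path.
#' @export
save_model <- function(model, path) {
  saveRDS(list(config = model$config, weights = model_weights(model)), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  ck <- readRDS(path)
  m <- build_model(ck$config)
  set_model_weights(m, ck$weights)
  m
}

#' Forward pass: image to density outputs
#'
#' Runs the network on one RGB image and returns the fused probability map
#' `P0`, the per-image normalization `beta` (exactly 1 in `"dm"` mode), and
#' the predicted count (the pixel sum of `P0`). With `return_maps = TRUE` the
#' side logit maps `S_1..S_K`, the fused logit `S_0` and all probability maps
#' are returned as well (fused first).
#'
#' @param model an `sndm_model`.
#' @param image `H x W x 3` array in `[0, 1]` matching the configured input
#'   size (a `petri_scene` is also accepted).
#' @param dropout_active keep dropout layers active (Monte Carlo dropout)?
#' @param beta_override optional positive scalar pinning `beta` (bypassing
#'   the head); used for diagnostics such as the `beta = 1` equivalence check.
#' @param return_maps also return all logit and probability maps?
#' @return object of class `density_outputs` with fields `P0`, `beta`,
#'   `predicted_count`, and optionally `S` and `P` lists.
#' @export
predict_density <- function(model, image, dropout_active = FALSE,
                            beta_override = NULL, return_maps = FALSE) {
  stopifnot(inherits(model, "sndm_model"))
  if (inherits(image, "petri_scene")) image <- image$image
  if (!is.null(beta_override)) {
    assert_scalar_number(beta_override, "beta_override", lower = 1e-12)
  }
  out <- cpp_net_forward(model$ptr, image, isTRUE(dropout_active),
                         beta_override %||% -1, isTRUE(return_maps))
  structure(list(P0 = out$P0, beta = out$beta, predicted_count = out$count,
                 S = out$S, P = out$P),
            class = "density_outputs")
}

#' @export
print.density_outputs <- function(x, ...) {
  cat(sprintf("<density_outputs> count %.3f, beta %.4f, map %dx%d\n",
              x$predicted_count, x$beta, nrow(x$P0), ncol(x$P0)))
  invisible(x)
}

#' Self-normalized sigmoid rescaling
#'
#' Applies `sigmoid(beta * S)` elementwise to a logit map. For small
#' `|beta * S|` the sigmoid is approximately linear,
#' `sigmoid(x) = 1/2 + x/4 + O(x^3)`, so rescaling the logits rescales the
#' map's departure from 1/2 almost linearly -- the mechanism the
#' self-normalization head exploits to correct the density-map normalization.
#'
#' @param S numeric matrix of logits.
#' @param beta positive scalar.
#' @return matrix with entries in `(0, 1)`.
#' @export
apply_normalization <- function(S, beta) {
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta <= 0) {
    stop_sndm("`beta` must be a positive scalar")
  }
  cpp_apply_normalization(as.matrix(S), beta)
}

#' Beta-head output activation
#'
#' Maps the head's pre-activation `z` to the normalization parameter:
#' `lambda * sigmoid(z)` (bounded in `(0, lambda)`) or `relu(z)`.
#'
#' @param z pre-activation value(s).
#' @param lambda activation scale (default 1.5).
#' @param type `"scaled_sigmoid"` or `"relu"`.
#' @return beta value(s).
#' @export
beta_activation_value <- function(z, lambda = 1.5,
                                  type = c("scaled_sigmoid", "relu")) {
  type <- match.arg(type)
  vapply(z, cpp_beta_activation, numeric(1), lambda = lambda, type = type)
}

#' Pin the beta head to a constant pre-activation
#'
#' Zeroes the final fully connected weights of the bypass head and sets its
#' bias to `z`, so every forward pass yields `beta = activation(z)`
#' regardless of the input. Diagnostic surgery; errors in `"dm"` mode.
#'
#' @param model an `sndm_model` in `"sndm"` mode.
#' @param z pre-activation constant.
#' @export
fix_beta_preactivation <- function(model, z) {
  cpp_net_fix_beta_preactivation(model$ptr, z)
  invisible(model)
}

#' Zero all model parameters (diagnostic)
#' @param model an `sndm_model`.
#' @export
zero_model_weights <- function(model) {
  cpp_net_zero_params(model$ptr)
  invisible(model)
}
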