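#' Training configuration
#'
#' Defaults follow the published protocol: Adam with learning rate 0.0001,
#' weight decay 0.0005, mini-batches of two, and model selection on the
#' validation subset. Full-scale runs train for at least 100 epochs;
#' desk-scale tests use far fewer.
#'
#' @param learning_rate Adam learning rate.
#' @param weight_decay L2 weight decay coefficient (mu).
#' @param batch_size mini-batch size.
#' @param max_epochs maximum number of epochs.
#' @param early_stopping_metric `"val_count_mae"` or `"val_loss"`; the
#'   checkpoint with the best value on the validation set is returned.
#' @param patience epochs without improvement before stopping.
#' @param penalty_weight relative weight of the beta penalty `1/2 (1-beta)^2`
#'   (the published loss has no extra hyperparameter, i.e. weight 1).
#' @param beta_freeze_epochs epochs during which the self-normalization head
#'   is frozen at its `beta = 1` initialization before training at
#'   `beta_lr_scale` (default 5; ignored in `"dm"` mode). Early logit maps
#'   are badly scaled and would drive `beta` into saturation.
#' @param seed integer seed governing shuffling and dropout.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.0001, weight_decay = 0.0005,
                         batch_size = 2L, max_epochs = 100L,
                         early_stopping_metric = c("val_count_mae", "val_loss"),
                         patience = 10L, penalty_weight = 1,
                         beta_freeze_epochs = 5L, seed = 1L) {
  early_stopping_metric <- match.arg(early_stopping_metric)
  assert_scalar_number(learning_rate, "learning_rate",
                       lower = .Machine$double.xmin)
  assert_scalar_number(weight_decay, "weight_decay", lower = 0)
  assert_scalar_number(batch_size, "batch_size", lower = 1)
  assert_scalar_number(max_epochs, "max_epochs", lower = 1)
  assert_scalar_number(patience, "patience", lower = 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stopping_metric = early_stopping_metric,
                 patience = as.integer(patience),
                 penalty_weight = penalty_weight,
                 beta_freeze_epochs = as.integer(beta_freeze_epochs),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Binary cross entropy between two maps (pixel sum)
#'
#' `-sum(P_G * ln(P) + (1 - P_G) * ln(1 - P))` over all pixels -- the sum, not
#' the mean, so per-map losses scale with map area.
#'
#' @param P predicted probability map, entries strictly inside `(0, 1)`.
#' @param P_G target map, entries in `[0, 1]` (use [loss_view()] for density
#'   targets).
#' @return non-negative scalar.
#' @export
bce_map_loss <- function(P, P_G) {
  P <- as.matrix(P); P_G <- as.matrix(P_G)
  if (!all(dim(P) == dim(P_G))) stop_sndm("`P` and `P_G` shapes differ")
  if (any(P <= 0) || any(P >= 1)) stop_sndm("`P` entries must lie strictly in (0, 1)")
  if (any(P_G < 0) || any(P_G > 1)) stop_sndm("`P_G` entries must lie in [0, 1]")
  -sum(P_G * log(P) + (1 - P_G) * log(1 - P))
}

#' Deep-supervised loss with the beta penalty
#'
#' The total loss is the sum of per-map binary cross entropies over the fused
#' map and every side map, plus the self-normalization penalty
#' `1/2 (1 - beta)^2` per image. The penalty expresses the prior that the
#' network should work without correction (`beta = 1`).
#'
#' @param outputs a `density_outputs` with probability maps (forward with
#'   `return_maps = TRUE`), or a bare list of probability maps (fused first).
#' @param target_loss_view clipped target map from [loss_view()].
#' @param beta normalization value; defaults to `outputs$beta` when present.
#' @param penalty_weight relative weight of the penalty (default 1).
#' @return object of class `loss_breakdown`: `per_map_bce` (one entry per
#'   map, fused first), `penalty`, `total`.
#' @export
total_loss <- function(outputs, target_loss_view, beta = NULL,
                       penalty_weight = 1) {
  maps <- if (inherits(outputs, "density_outputs")) {
    if (is.null(outputs$P)) stop_sndm("forward the model with `return_maps = TRUE` to compute the loss")
    outputs$P
  } else {
    outputs
  }
  beta <- beta %||% (if (inherits(outputs, "density_outputs")) outputs$beta else 1)
  per_map <- vapply(maps, bce_map_loss, numeric(1), P_G = target_loss_view)
  penalty <- 0.5 * penalty_weight * (1 - beta)^2
  structure(list(per_map_bce = unname(per_map), penalty = penalty,
                 total = sum(per_map) + penalty),
            class = "loss_breakdown")
}

#' @export
print.loss_breakdown <- function(x, ...) {
  cat(sprintf("<loss_breakdown> total %.4f = bce %.4f (x%d maps) + penalty %.6f\n",
              x$total, sum(x$per_map_bce), length(x$per_map_bce), x$penalty))
  invisible(x)
}

#' Prepare scenes for training
#'
#' Renders the density target of each scene, takes its loss view, and bundles
#' image + target + truth count.
#'
#' @param scenes list of `petri_scene` objects.
#' @param kernel a [kernel_spec()].
#' @param eps clipping margin for the loss view.
#' @return list of records `(image, target_view, count, annotation)`.
#' @export
prepare_training_set <- function(scenes, kernel = kernel_spec(), eps = 1e-6) {
  purrr::map(scenes, function(sc) {
    shape <- dim(sc$image)[1:2]
    tgt <- density_target_from_annotation(sc$annotation, shape, kernel)
    view <- withCallingHandlers(
      loss_view(tgt, eps),
      sndm_clip_warning = function(w) invokeRestart("muffleWarning"))
    list(image = sc$image, target_view = view,
         count = annotation_count(sc$annotation), annotation = sc$annotation,
         coverage = sc$coverage, mean_colony_size = sc$mean_colony_size)
  })
}

validate_model_count <- function(model, records) {
  counts <- vapply(records, function(r) {
    predict_density(model, r$image)$predicted_count
  }, numeric(1))
  truth <- vapply(records, `[[`, numeric(1), "count")
  mean(abs(counts - truth))
}

#' Train a density-map model
#'
#' Mini-batch Adam on the deep-supervised BCE loss (plus the beta penalty in
#' `"sndm"` mode), with per-epoch validation and early stopping; returns the
#' checkpoint with the best validation metric restored into the model.
#'
#' @param model an `sndm_model` (modified in place; also returned inside the
#'   fit object).
#' @param train,val lists of training records from [prepare_training_set()];
#'   `val` may be `NULL` to skip validation-based selection.
#' @param config a [train_config()].
#' @param penalty_only optimize only the beta penalty (trunk receives no BCE
#'   gradient); diagnostic mode.
#' @param verbose print one line per epoch?
#' @return object of class `sndm_fit`: `model`, `history` tibble (epoch,
#'   train_loss, val_loss, val_count_mae, mean_beta), `best_epoch`, `config`.
#' @export
fit_sndm <- function(model, train, val = NULL, config = train_config(),
                     penalty_only = FALSE, verbose = FALSE) {
  stopifnot(inherits(model, "sndm_model"), inherits(config, "train_config"))
  if (length(train) == 0L) stop_sndm("empty training set")
  with_seed(config$seed, {
    n <- length(train)
    best_metric <- Inf
    best_weights <- model_weights(model)
    best_epoch <- 0L
    since_best <- 0L
    hist <- vector("list", config$max_epochs)
    sndm_mode <- model$config$mode == "sndm"
    for (epoch in seq_len(config$max_epochs)) {
      if (sndm_mode) {
        cpp_net_set_beta_lr_scale(
          model$ptr,
          if (epoch <= (config$beta_freeze_epochs %||% 0L)) 0 else
            model$config$beta_lr_scale)
      }
      idx <- sample.int(n)
      tot <- 0
      beta_acc <- 0
      n_batches <- 0L
      for (start in seq(1, n, by = config$batch_size)) {
        b_idx <- idx[start:min(n, start + config$batch_size - 1L)]
        imgs <- lapply(train[b_idx], `[[`, "image")
        tgts <- lapply(train[b_idx], `[[`, "target_view")
        res <- cpp_net_train_batch(model$ptr, imgs, tgts,
                                   config$learning_rate, config$weight_decay,
                                   config$penalty_weight, penalty_only, TRUE)
        tot <- tot + res$total
        beta_acc <- beta_acc + res$mean_beta
        n_batches <- n_batches + 1L
      }
      val_loss <- NA_real_
      val_mae <- NA_real_
      if (!is.null(val) && length(val) > 0L) {
        vl <- 0
        err <- 0
        for (r in val) {
          out <- predict_density(model, r$image, return_maps = TRUE)
          lb <- total_loss(out, r$target_view,
                           penalty_weight = config$penalty_weight)
          vl <- vl + lb$total
          err <- err + abs(out$predicted_count - r$count)
        }
        val_loss <- vl
        val_mae <- err / length(val)
      }
      hist[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = tot, val_loss = val_loss,
        val_count_mae = val_mae, mean_beta = beta_acc / n_batches)
      if (verbose) {
        message(sprintf("[%s] epoch %3d  train %.1f  val %.1f  val-MAE %.3f  beta %.4f",
                        format(Sys.time(), "%H:%M:%S"), epoch, tot, val_loss,
                        val_mae, beta_acc / n_batches))
      }
      metric <- switch(config$early_stopping_metric,
                       val_count_mae = val_mae, val_loss = val_loss)
      if (is.null(val)) metric <- tot
      if (is.finite(metric) && metric < best_metric) {
        best_metric <- metric
        best_weights <- model_weights(model)
        best_epoch <- epoch
        since_best <- 0L
      } else {
        since_best <- since_best + 1L
        if (since_best >= config$patience) break
      }
    }
    set_model_weights(model, best_weights)
    structure(list(model = model,
                   history = dplyr::bind_rows(hist[!vapply(hist, is.null, logical(1))]),
                   best_epoch = best_epoch, best_metric = best_metric,
                   config = config),
              class = "sndm_fit")
  })
}

#' @export
print.sndm_fit <- function(x, ...) {
  cat(sprintf("<sndm_fit> %s, %d epochs run, best epoch %d (%s = %.4f)\n",
              x$model$config$mode, nrow(x$history), x$best_epoch,
              x$config$early_stopping_metric, x$best_metric))
  invisible(x)
}
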