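#' Bootstrap ensemble configuration
#'
#' Pairs-sampling bootstrap: `B` training subsets are drawn from the training
#' pairs with replacement, each of exactly `b = round(subset_fraction * N)`
#' draws. Defaults follow the published protocol, `B = 20` subsets of
#' `b ~ 0.63 N` images.
#'
#' @param B number of subsets / ensemble members.
#' @param subset_fraction `b / N` in `(0, 1]`.
#' @param seed master seed; member seeds are derived from it.
#' @return object of class `bootstrap_config`.
#' @export
bootstrap_config <- function(B = 20L, subset_fraction = 0.63, seed = 1L) {
  if (B < 1) stop_sndm("`B` must be >= 1")
  assert_scalar_number(subset_fraction, "subset_fraction",
                       lower = 1e-9, upper = 1)
  structure(list(B = as.integer(B), subset_fraction = subset_fraction,
                 seed = as.integer(seed)),
            class = "bootstrap_config")
}

#' Monte Carlo dropout inference configuration
#'
#' @param r number of stochastic forward passes (default 20).
#' @param seed integer seed for the dropout draws.
#' @return object of class `dropout_config`.
#' @export
dropout_config <- function(r = 20L, seed = 1L) {
  if (r < 1) stop_sndm("`r` must be >= 1")
  structure(list(r = as.integer(r), dropout_active = TRUE,
                 seed = as.integer(seed)),
            class = "dropout_config")
}

#' Draw bootstrap training subsets
#'
#' @param dataset_ids vector of `N` ids (any atomic type).
#' @param config a [bootstrap_config()].
#' @return list of `B` id vectors (multisets; duplicates permitted), each of
#'   length `b = round(subset_fraction * N)`.
#' @export
bootstrap_subsets <- function(dataset_ids, config = bootstrap_config()) {
  N <- length(dataset_ids)
  if (N < 1) stop_sndm("need at least one dataset id")
  b <- round(config$subset_fraction * N)
  if (b == 0) stop_sndm("subset size b = round(%.3f * %d) is zero", config$subset_fraction, N)
  with_seed(config$seed, {
    lapply(seq_len(config$B), function(i) {
      dataset_ids[sample.int(N, b, replace = TRUE)]
    })
  })
}

#' Train a bootstrap ensemble
#'
#' Trains `B` independently initialized models, each on its own
#' with-replacement subset of the training records, each selected on the
#' shared validation set. Reproducible: member initialization and training
#' seeds are derived from `config$seed`.
#'
#' @param train,val training records ([prepare_training_set()]).
#' @param model_cfg a [model_config()] (member seeds override its seed).
#' @param train_cfg a [train_config()].
#' @param config a [bootstrap_config()].
#' @param verbose print per-member progress?
#' @return object of class `sndm_ensemble`: list of member `sndm_fit`s plus
#'   the configs.
#' @export
bootstrap_train <- function(train, val, model_cfg, train_cfg,
                            config = bootstrap_config(), verbose = FALSE) {
  subsets <- bootstrap_subsets(seq_along(train), config)
  seeds <- derive_seeds(config$seed + 1L, 2L * config$B)
  members <- vector("list", config$B)
  for (i in seq_len(config$B)) {
    m_cfg <- model_cfg
    m_cfg$seed <- seeds[2L * i - 1L]
    t_cfg <- train_cfg
    t_cfg$seed <- seeds[2L * i]
    model <- build_model(m_cfg)
    if (verbose) message(sprintf("bootstrap member %d/%d", i, config$B))
    members[[i]] <- fit_sndm(model, train[subsets[[i]]], val, t_cfg)
  }
  structure(list(members = members, config = config, model_cfg = model_cfg,
                 train_cfg = train_cfg),
            class = "sndm_ensemble")
}

#' @export
print.sndm_ensemble <- function(x, ...) {
  cat(sprintf("<sndm_ensemble> %d bootstrap members (%s mode)\n",
              length(x$members), x$model_cfg$mode))
  invisible(x)
}

new_ensemble_prediction <- function(counts, maps, betas, method) {
  B <- length(counts)
  mean_count <- mean(counts)
  sigma_count <- sqrt(sum((mean_count - counts)^2) / B) # population divisor
  mean_map <- NULL
  sigma_map <- NULL
  if (!is.null(maps)) {
    mean_map <- Reduce(`+`, maps) / B
    sigma_map <- sqrt(Reduce(`+`, lapply(maps, function(m) (m - mean_map)^2)) / B)
  }
  structure(list(mean_count = mean_count, sigma_count = sigma_count,
                 mean_map = mean_map, sigma_map = sigma_map,
                 member_counts = counts,
                 mean_beta = if (is.null(betas)) NA_real_ else mean(betas),
                 method = method),
            class = "ensemble_prediction")
}

#' @export
print.ensemble_prediction <- function(x, ...) {
  cat(sprintf("<ensemble_prediction> %s: count %.2f +- %.3f (1 sigma, %d members)\n",
              x$method, x$mean_count, x$sigma_count, length(x$member_counts)))
  invisible(x)
}

#' Aggregate member predictions into mean and 1-sigma uncertainty
#'
#' The ensemble prediction is the mean over member outcomes; the variance
#' over members (population divisor `B`, not `B - 1`) gives the squared
#' 1-sigma uncertainty. Scalar count statistics are computed on the
#' per-member counts (each the pixel sum of that member's `P0`), never by
#' aggregating the per-pixel sigma map, whose pixels are correlated. The
#' mean and sigma maps use the same formulas pixelwise.
#'
#' @param members list of `density_outputs` (or a bare numeric vector of
#'   member counts).
#' @param method label stored on the result (`"bootstrap"` or
#'   `"mc_dropout"`).
#' @return object of class `ensemble_prediction` with `mean_count`,
#'   `sigma_count`, `mean_map`, `sigma_map`, `member_counts`.
#' @export
ensemble_predict <- function(members, method = "bootstrap") {
  if (is.numeric(members)) {
    if (length(members) == 0L) stop_sndm("empty member list")
    return(new_ensemble_prediction(members, NULL, NULL, method))
  }
  if (length(members) == 0L) stop_sndm("empty member list")
  counts <- vapply(members, `[[`, numeric(1), "predicted_count")
  maps <- lapply(members, `[[`, "P0")
  betas <- vapply(members, `[[`, numeric(1), "beta")
  new_ensemble_prediction(counts, maps, betas, method)
}

#' Bootstrap-ensemble prediction for one image
#'
#' Runs every trained member on the image (dropout off) and aggregates with
#' [ensemble_predict()].
#'
#' @param ensemble an `sndm_ensemble` from [bootstrap_train()].
#' @param image input image (or `petri_scene`).
#' @return an `ensemble_prediction` with `method = "bootstrap"`.
#' @export
predict_bootstrap <- function(ensemble, image) {
  stopifnot(inherits(ensemble, "sndm_ensemble"))
  outs <- lapply(ensemble$members, function(f) predict_density(f$model, image))
  ensemble_predict(outs, method = "bootstrap")
}

#' Monte Carlo dropout prediction for one image
#'
#' Runs `r` stochastic forward passes with dropout layers kept active and
#' aggregates exactly like [ensemble_predict()] with divisor `r`. With a
#' dropout rate of 0 all passes coincide and the uncertainty is zero (a
#' warning is emitted).
#'
#' @param model a trained `sndm_model` containing dropout layers.
#' @param image input image (or `petri_scene`).
#' @param config a [dropout_config()].
#' @return an `ensemble_prediction` with `method = "mc_dropout"`.
#' @export
mc_dropout_predict <- function(model, image, config = dropout_config()) {
  stopifnot(inherits(model, "sndm_model"), inherits(config, "dropout_config"))
  if (model$config$dropout_rate == 0 && config$r > 1) {
    rlang::warn("dropout rate is 0: all passes are identical and sigma will be 0",
                class = "sndm_no_dropout_warning")
  }
  with_seed(config$seed, {
    outs <- lapply(seq_len(config$r), function(i) {
      predict_density(model, image, dropout_active = TRUE)
    })
    ensemble_predict(outs, method = "mc_dropout")
  })
}
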