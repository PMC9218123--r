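#' Default run configuration
#'
#' One nested list gathering every tunable of the pipeline; section defaults
#' are taken from the module constructors, so the printed protocol constants
#' (learning rate 0.0001, weight decay 0.0005, batch size 2, B = 20 bootstrap
#' subsets of fraction 0.63, r = 20 dropout passes, beta bound lambda = 1.5)
#' appear here exactly once each. The `smoke` section sizes the end-to-end
#' smoke workflow only.
#'
#' @return nested named list of class `run_config`.
#' @export
default_run_config <- function() {
  tc <- train_config()
  bc <- bootstrap_config()
  dc <- dropout_config()
  mc <- model_config()
  structure(list(
    seed = 1L,
    scene = list(image_size = 96L, p_low = 0.85, mu = 15, size = 1.6,
                 illumination = "random", overlap_allowed = TRUE,
                 noise_sd = 0.01),
    kernel = list(sigma_blur = NULL, adaptive = TRUE),
    model = list(input_size = mc$input_size, n_stages = mc$n_stages,
                 base_channels = mc$base_channels,
                 dropout_rate = mc$dropout_rate,
                 beta_activation = mc$beta_activation, lambda = mc$lambda,
                 beta_hidden = mc$beta_hidden),
    train = list(learning_rate = tc$learning_rate,
                 weight_decay = tc$weight_decay, batch_size = tc$batch_size,
                 max_epochs = tc$max_epochs,
                 early_stopping_metric = tc$early_stopping_metric,
                 patience = tc$patience, penalty_weight = tc$penalty_weight),
    bootstrap = list(B = bc$B, subset_fraction = bc$subset_fraction),
    dropout = list(r = dc$r),
    evaluation = list(strata_threshold = 50),
    smoke = list(n_images = 24L, image_size = 48L, max_epochs = 3L,
                 bootstrap_B = 2L, bootstrap_epochs = 2L, dropout_r = 3L)
  ), class = "run_config")
}

merge_config <- function(defaults, override, path = "") {
  if (is.null(override)) return(defaults)
  if (!is.list(override)) {
    stop_sndm("config section '%s' must be a mapping", path)
  }
  unknown <- setdiff(names(override), names(defaults))
  if (length(unknown) > 0L) {
    stop_sndm("unknown config key%s: %s",
              if (length(unknown) > 1) "s" else "",
              paste0(sub("^\\.", "", paste0(path, ".", unknown)),
                     collapse = ", "))
  }
  for (k in names(override)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], override[[k]],
                                    paste0(path, ".", k))
    } else {
      defaults[[k]] <- override[[k]]
    }
  }
  defaults
}

#' Load a run configuration from YAML
#'
#' Reads a YAML file, fills every missing key from [default_run_config()],
#' and rejects unknown keys by name. An empty file yields the full default
#' configuration.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param echo message the resolved configuration (JSON) to the log?
#' @return a `run_config` list.
#' @export
load_run_config <- function(path = NULL, echo = FALSE) {
  defaults <- default_run_config()
  override <- NULL
  if (!is.null(path)) {
    if (!file.exists(path)) stop_sndm("config file not found: %s", path)
    override <- yaml::read_yaml(path)
  }
  cfg <- merge_config(unclass(defaults), override)
  class(cfg) <- "run_config"
  if (echo) {
    message("resolved run config: ",
            jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, null = "null"))
  }
  cfg
}

run_stage <- function(stage, code) {
  tryCatch(force(code), error = function(e) {
    stop_sndm("stage '%s' failed: %s", stage, conditionMessage(e))
  })
}

scene_params_from_config <- function(cfg, image_size = NULL) {
  scene_params(
    image_size = image_size %||% cfg$scene$image_size,
    count_distribution = count_mixture(p_low = cfg$scene$p_low,
                                       mu = cfg$scene$mu,
                                       size = cfg$scene$size),
    illumination = cfg$scene$illumination,
    overlap_allowed = cfg$scene$overlap_allowed,
    noise_sd = cfg$scene$noise_sd,
    seed = cfg$seed)
}

#' End-to-end smoke workflow
#'
#' Ties every module together at miniature scale: generates a small synthetic
#' dataset, trains a plain density-map model and a self-normalized one, runs
#' single-pass, bootstrap and Monte Carlo dropout prediction, evaluates both
#' models, and writes a comparison summary. Every stage failure is reported
#' with its stage name. Deterministic under the config seed.
#'
#' @param config a `run_config` (see [load_run_config()]); the `smoke`
#'   section sets the problem sizes.
#' @param workdir writable working directory for artifacts.
#' @param verbose log progress?
#' @return summary list: per-mode `metrics_report`s, the DM-vs-SNDM MAE
#'   comparison (overall and per stratum), mean-beta trajectory, and artifact
#'   paths.
#' @export
smoke_pipeline <- function(config = default_run_config(), workdir,
                           verbose = FALSE) {
  sm <- config$smoke
  seeds <- derive_seeds(config$seed, 8L)

  data_dir <- file.path(workdir, "data")
  manifest <- run_stage("generate", {
    if (!dir.exists(workdir) && !dir.create(workdir, recursive = TRUE,
                                            showWarnings = FALSE)) {
      stop_sndm("workdir not writable: %s", workdir)
    }
    if (file.access(workdir, 2) != 0) stop_sndm("workdir not writable: %s", workdir)
    params <- scene_params_from_config(config, image_size = sm$image_size)
    params$count_distribution <- count_nbinom(mu = 6, size = 2, max_count = 20L)
    generate_dataset(sm$n_images, params, data_dir, seed = seeds[1])
  })

  sets <- run_stage("targets", {
    params <- scene_params_from_config(config, image_size = sm$image_size)
    params$count_distribution <- count_nbinom(mu = 6, size = 2, max_count = 20L)
    scene_seeds <- derive_seeds(seeds[1], sm$n_images)
    scenes <- lapply(scene_seeds, function(s) generate_scene(params, seed = s))
    recs <- prepare_training_set(scenes)
    split <- manifest$images$split
    list(train = recs[split == "train"], val = recs[split == "val"],
         test_scenes = scenes[split == "test"])
  })

  t_cfg <- train_config(learning_rate = config$train$learning_rate,
                        weight_decay = config$train$weight_decay,
                        batch_size = config$train$batch_size,
                        max_epochs = sm$max_epochs,
                        patience = config$train$patience,
                        penalty_weight = config$train$penalty_weight,
                        seed = seeds[2])
  fits <- list()
  for (mode in c("dm", "sndm")) {
    fits[[mode]] <- run_stage(paste0("train_", mode), {
      m_cfg <- model_config(mode = mode, input_size = sm$image_size,
                            n_stages = config$model$n_stages,
                            base_channels = config$model$base_channels,
                            dropout_rate = config$model$dropout_rate,
                            beta_activation = config$model$beta_activation,
                            lambda = config$model$lambda,
                            beta_hidden = config$model$beta_hidden,
                            seed = seeds[3])
      fit_sndm(build_model(m_cfg), sets$train, sets$val, t_cfg,
               verbose = verbose)
    })
  }

  boot <- run_stage("bootstrap", {
    b_tc <- t_cfg
    b_tc$max_epochs <- sm$bootstrap_epochs
    bootstrap_train(sets$train, sets$val, fits$sndm$model$config, b_tc,
                    bootstrap_config(B = sm$bootstrap_B, seed = seeds[4]),
                    verbose = verbose)
  })

  preds <- run_stage("predict", {
    sc <- sets$test_scenes[[1]]
    list(single = predict_density(fits$sndm$model, sc),
         bootstrap = predict_bootstrap(boot, sc),
         mc_dropout = mc_dropout_predict(fits$sndm$model, sc,
                                         dropout_config(r = sm$dropout_r,
                                                        seed = seeds[5])))
  })

  evals <- run_stage("evaluate", {
    lapply(fits, function(f) {
      evaluate_model(f, sets$test_scenes, method = "single",
                     strata_threshold = config$evaluation$strata_threshold)
    })
  })

  summary <- run_stage("summarise", {
    cmp <- dplyr::full_join(
      evals$dm$report$stratified |>
        dplyr::select("stratum", dm_mae = "mae"),
      evals$sndm$report$stratified |>
        dplyr::select("stratum", sndm_mae = "mae"),
      by = "stratum")
    s <- list(reports = lapply(evals, `[[`, "report"),
              comparison = cmp,
              mean_beta_trajectory = fits$sndm$history$mean_beta,
              predictions = lapply(preds, function(p) {
                if (inherits(p, "ensemble_prediction")) {
                  list(mean_count = p$mean_count, sigma_count = p$sigma_count)
                } else {
                  list(mean_count = p$predicted_count, sigma_count = 0)
                }
              }),
              data_dir = data_dir)
    jsonlite::write_json(
      list(comparison = cmp, mean_beta = fits$sndm$history$mean_beta,
           predictions = s$predictions),
      file.path(workdir, "smoke_summary.json"), auto_unbox = TRUE, digits = NA)
    s
  })
  summary
}
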