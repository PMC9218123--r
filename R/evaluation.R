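#' Count records: one row per evaluated image
#'
#' @param image_id character ids.
#' @param n true counts (`>= 0`).
#' @param n_hat predicted counts (reals; kept unrounded for metrics).
#' @param sigma 1-sigma uncertainties (0 when unavailable).
#' @param beta per-image normalization (1 for plain density maps).
#' @param coverage dish coverage fractions.
#' @param mean_colony_size mean equivalent diameters (NA when undefined).
#' @return a tibble of class `count_records`.
#' @export
count_records <- function(image_id, n, n_hat, sigma = 0, beta = 1,
                          coverage = NA_real_, mean_colony_size = NA_real_) {
  if (any(n < 0) || any(sigma < 0)) {
    stop_sndm("true counts and sigmas must be non-negative")
  }
  out <- tibble::tibble(image_id = as.character(image_id), n = as.numeric(n),
                        n_hat = as.numeric(n_hat), sigma = as.numeric(sigma),
                        beta = as.numeric(beta),
                        coverage = as.numeric(coverage),
                        mean_colony_size = as.numeric(mean_colony_size))
  class(out) <- c("count_records", class(out))
  out
}

as_records <- function(records) {
  if (!is.data.frame(records) || nrow(records) == 0L) {
    stop_sndm("`records` must be a non-empty data frame of count records")
  }
  records
}

#' Mean absolute counting error
#'
#' `MAE = (1/N) * sum(|n_i - n_hat_i|)` over the records.
#'
#' @param records a data frame with columns `n` (true count) and `n_hat`
#'   (predicted count).
#' @return non-negative scalar.
#' @export
count_mae <- function(records) {
  r <- as_records(records)
  mean(abs(r$n - r$n_hat))
}

#' Symmetric mean absolute percentage counting error
#'
#' `sMAPE = (100/N) * sum(|n_i - n_hat_i| / |n_i + n_hat_i|)`, in percent.
#' An empty dish predicted empty (`n = n_hat = 0`) contributes 0 under the
#' documented 0/0 convention. Bounded in `[0, 100]` for non-negative counts.
#'
#' @inheritParams count_mae
#' @return percentage in `[0, 100]`.
#' @export
count_smape <- function(records) {
  r <- as_records(records)
  num <- abs(r$n - r$n_hat)
  den <- abs(r$n + r$n_hat)
  term <- ifelse(den == 0, 0, num / den)
  100 * mean(term)
}

#' Fraction of records covered at k sigma
#'
#' The fraction of images whose true count lies within `k * sigma` of the
#' predicted count. Records with `sigma = 0` count as covered only when the
#' prediction is exact.
#'
#' @inheritParams count_mae
#' @param k coverage multiple (default 1 for 1-sigma calibration).
#' @return fraction in `[0, 1]`.
#' @export
within_sigma_fraction <- function(records, k = 1) {
  r <- as_records(records)
  mean(abs(r$n - r$n_hat) <= k * r$sigma)
}

#' Bin uncertainty diagnostics by an image feature
#'
#' Averages the per-image uncertainty (and the uncertainty per colony,
#' `sigma / n`, defined only for `n > 0`) within bins of a feature: mean
#' colony size, dish coverage, or true count. Empty bins are kept and
#' flagged, never dropped silently.
#'
#' @inheritParams count_mae
#' @param feature `"mean_colony_size"`, `"coverage"` or `"n"`.
#' @param bin_edges strictly increasing numeric vector of bin boundaries.
#' @return tibble with one row per bin: `bin`, `lower`, `upper`,
#'   `n_records`, `mean_sigma`, `mean_sigma_per_colony`, `empty`.
#' @export
bin_by_feature <- function(records, feature = c("mean_colony_size", "coverage", "n"),
                           bin_edges) {
  feature <- match.arg(feature)
  r <- as_records(records)
  if (any(diff(bin_edges) <= 0)) stop_sndm("`bin_edges` must be strictly increasing")
  x <- r[[feature]]
  idx <- cut(x, bin_edges, include.lowest = TRUE, right = FALSE)
  levels_tbl <- tibble::tibble(
    bin = levels(idx),
    lower = bin_edges[-length(bin_edges)],
    upper = bin_edges[-1])
  r$.bin <- as.character(idx)
  per_colony <- ifelse(r$n > 0, r$sigma / r$n, NA_real_)
  r$.spc <- per_colony
  agg <- r |>
    dplyr::filter(!is.na(.data$.bin)) |>
    dplyr::group_by(bin = .data$.bin) |>
    dplyr::summarise(n_records = dplyr::n(),
                     mean_sigma = mean(.data$sigma),
                     mean_sigma_per_colony = mean(.data$.spc, na.rm = TRUE),
                     .groups = "drop")
  out <- dplyr::left_join(levels_tbl, agg, by = "bin") |>
    dplyr::mutate(n_records = dplyr::coalesce(.data$n_records, 0L),
                  empty = .data$n_records == 0L)
  tibble::as_tibble(out)
}

#' Linear beta-versus-coverage fits per colony-size group
#'
#' Within groups of mean colony size, the normalization parameter depends
#' approximately linearly on the dish coverage; this fits an ordinary
#' least-squares line `beta ~ coverage` in each group. Groups with fewer
#' than 2 points or zero coverage variance are flagged unfit rather than
#' erroring.
#'
#' @inheritParams count_mae
#' @param size_group_edges strictly increasing edges over mean colony size.
#' @return tibble with `group`, `slope`, `intercept`, `n`, `fit_ok`.
#' @export
beta_coverage_fit <- function(records, size_group_edges) {
  r <- as_records(records)
  if (any(diff(size_group_edges) <= 0)) {
    stop_sndm("`size_group_edges` must be strictly increasing")
  }
  r$.grp <- cut(r$mean_colony_size, size_group_edges, include.lowest = TRUE,
                right = FALSE)
  groups <- levels(r$.grp)
  purrr::map_dfr(groups, function(g) {
    sub <- r[!is.na(r$.grp) & r$.grp == g, ]
    if (nrow(sub) < 2L || stats::var(sub$coverage) == 0) {
      return(tibble::tibble(group = g, slope = NA_real_,
                            intercept = NA_real_, n = nrow(sub),
                            fit_ok = FALSE))
    }
    fit <- stats::lm(beta ~ coverage, data = sub)
    tibble::tibble(group = g, slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]), n = nrow(sub),
                   fit_ok = TRUE)
  })
}

#' Summarise count records into a metrics report
#'
#' Overall MAE, sMAPE and 1-sigma coverage, stratified into less and more
#' crowded dishes (`n <= threshold` and `n > threshold`, default 50) plus the
#' overall row. An empty stratum is flagged.
#'
#' @inheritParams count_mae
#' @param strata_threshold count boundary between the strata.
#' @return object of class `metrics_report`.
#' @export
metrics_report <- function(records, strata_threshold = 50) {
  r <- as_records(records)
  strata <- list(
    le = r[r$n <= strata_threshold, ],
    gt = r[r$n > strata_threshold, ],
    overall = r)
  labels <- c(sprintf("<=%g colonies", strata_threshold),
              sprintf(">%g colonies", strata_threshold), "overall")
  tab <- purrr::map2_dfr(strata, labels, function(s, lab) {
    if (nrow(s) == 0L) {
      tibble::tibble(stratum = lab, n_images = 0L, mae = NA_real_,
                     smape = NA_real_, mean_sigma = NA_real_,
                     within_1sigma = NA_real_, empty = TRUE)
    } else {
      tibble::tibble(stratum = lab, n_images = nrow(s), mae = count_mae(s),
                     smape = count_smape(s), mean_sigma = mean(s$sigma),
                     within_1sigma = within_sigma_fraction(s, 1),
                     empty = FALSE)
    }
  })
  structure(list(N = nrow(r), mae = count_mae(r), smape = count_smape(r),
                 within_1sigma = within_sigma_fraction(r, 1),
                 stratified = tab),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> N=%d  MAE %.3f  sMAPE %.3f%%  within 1-sigma %.2f\n",
              x$N, x$mae, x$smape, x$within_1sigma))
  print(x$stratified)
  invisible(x)
}

#' Evaluate a model or ensemble on annotated scenes
#'
#' Runs prediction on every scene (single pass, bootstrap ensemble, or Monte
#' Carlo dropout), assembles per-image count records, and summarises them
#' into a [metrics_report()]. Deterministic under a fixed seed.
#'
#' @param object an `sndm_model`, `sndm_fit` or `sndm_ensemble`.
#' @param scenes list of `petri_scene` objects (the test set).
#' @param method `"single"`, `"bootstrap"` or `"mc_dropout"`.
#' @param dropout_cfg a [dropout_config()] (mc_dropout method).
#' @param strata_threshold stratification boundary (default 50 colonies).
#' @param csv optional path; when given the per-image records are written as
#'   CSV.
#' @return object of class `sndm_eval`: `records` tibble, `report`, `method`.
#' @export
evaluate_model <- function(object, scenes,
                           method = c("single", "bootstrap", "mc_dropout"),
                           dropout_cfg = dropout_config(),
                           strata_threshold = 50, csv = NULL) {
  method <- match.arg(method)
  if (inherits(object, "sndm_fit")) object <- object$model
  if (method == "bootstrap" && !inherits(object, "sndm_ensemble")) {
    stop_sndm("bootstrap evaluation needs an `sndm_ensemble`")
  }
  dropout_seeds <- derive_seeds(dropout_cfg$seed, length(scenes))
  rows <- purrr::imap(scenes, function(sc, i) {
    truth <- annotation_count(sc$annotation)
    if (method == "single") {
      out <- predict_density(object, sc$image)
      n_hat <- out$predicted_count; sigma <- 0; beta <- out$beta
    } else if (method == "bootstrap") {
      out <- predict_bootstrap(object, sc$image)
      n_hat <- out$mean_count; sigma <- out$sigma_count; beta <- out$mean_beta
    } else {
      cfg_i <- dropout_cfg; cfg_i$seed <- dropout_seeds[[i]]
      out <- mc_dropout_predict(object, sc$image, cfg_i)
      n_hat <- out$mean_count; sigma <- out$sigma_count; beta <- out$mean_beta
    }
    tibble::tibble(image_id = sc$annotation$image_id, n = truth,
                   n_hat = n_hat, sigma = sigma, beta = beta,
                   coverage = sc$coverage,
                   mean_colony_size = sc$mean_colony_size)
  })
  records <- dplyr::bind_rows(rows)
  class(records) <- c("count_records", class(records))
  if (!is.null(csv)) utils::write.csv(records, csv, row.names = FALSE)
  structure(list(records = records,
                 report = metrics_report(records, strata_threshold),
                 method = method),
            class = "sndm_eval")
}

#' @export
print.sndm_eval <- function(x, ...) {
  cat(sprintf("<sndm_eval> method %s\n", x$method))
  print(x$report)
  invisible(x)
}
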