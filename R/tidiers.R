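#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted density-map model
#'
#' Returns the per-epoch training history as a tibble (epoch, train loss,
#' validation loss, validation count-MAE, mean beta).
#'
#' @param x an `sndm_fit`.
#' @param ... unused.
#' @return a tibble with one row per epoch.
#' @export
tidy.sndm_fit <- function(x, ...) {
  x$history
}

#' @rdname tidy.sndm_fit
#' @export
glance.sndm_fit <- function(x, ...) {
  tibble::tibble(mode = x$model$config$mode,
                 epochs_run = nrow(x$history),
                 best_epoch = x$best_epoch,
                 best_metric = x$best_metric,
                 metric = x$config$early_stopping_metric,
                 final_mean_beta = x$history$mean_beta[nrow(x$history)])
}

#' Tidy an evaluation
#'
#' `tidy()` returns the per-image count records; `glance()` the one-row
#' overall metrics.
#'
#' @param x an `sndm_eval`.
#' @param ... unused.
#' @return a tibble.
#' @export
tidy.sndm_eval <- function(x, ...) {
  x$records
}

#' @rdname tidy.sndm_eval
#' @export
glance.sndm_eval <- function(x, ...) {
  tibble::tibble(method = x$method, N = x$report$N, mae = x$report$mae,
                 smape = x$report$smape,
                 within_1sigma = x$report$within_1sigma)
}
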