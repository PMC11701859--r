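# broom-style tidiers and ggplot2 autoplot methods for evaluation reports,
# fitted models and differential-connectivity objects.

#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
#' @importFrom rlang .data
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy an evaluation report
#'
#' Per-fold metrics in long-friendly wide form (one row per fold).
#'
#' @param x a `fusegnn_eval`.
#' @param ... unused.
#' @return tibble of per-fold metrics.
#' @method tidy fusegnn_eval
#' @export
tidy.fusegnn_eval <- function(x, ...) x$fold_metrics

#' @describeIn tidy.fusegnn_eval one-row pooled summary.
#' @method glance fusegnn_eval
#' @export
glance.fusegnn_eval <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(scheme = x$scheme,
                                  folds = nrow(x$fold_metrics),
                                  n = nrow(x$predictions)),
                   x$pooled)
}

#' @method tidy fusegnn_fit
#' @export
tidy.fusegnn_fit <- function(x, ...) {
  x$loss_log |>
    tidyr::pivot_longer(-"epoch", names_to = "component", values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
}

#' @method glance fusegnn_fit
#' @export
glance.fusegnn_fit <- function(x, ...) {
  dplyr::bind_cols(tibble::tibble(mode = x$config$mode,
                                  epochs = nrow(x$loss_log),
                                  n_train = length(x$train_idx),
                                  n_test = length(x$test_idx)),
                   x$metrics)
}

#' @method tidy differential_fc
#' @export
tidy.differential_fc <- function(x, ...) {
  ut <- which(upper.tri(x$diff), arr.ind = TRUE)
  tibble::tibble(roi_a = x$roi_labels[ut[, 1L]],
                 roi_b = x$roi_labels[ut[, 2L]],
                 delta = x$diff[ut],
                 abs_delta = x$abs_diff[ut])
}

#' Plot an evaluation report
#'
#' Calibration curve (observed positive fraction against mean predicted
#' probability per bin) with the identity diagonal for reference.
#'
#' @param object a `fusegnn_eval`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot fusegnn_eval
#' @export
autoplot.fusegnn_eval <- function(object, ...) {
  cal <- dplyr::filter(object$calibration, .data$count > 0)
  ggplot2::ggplot(cal, ggplot2::aes(x = .data$mean_pred, y = .data$obs_freq)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(colour = "#2c7fb8") +
    ggplot2::geom_point(ggplot2::aes(size = .data$count), colour = "#2c7fb8") +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Mean predicted probability",
                  y = "Observed positive fraction",
                  size = "Subjects",
                  title = sprintf("Calibration (%s, pooled AUROC %.3f)",
                                  object$scheme, object$pooled$auroc)) +
    ggplot2::theme_minimal()
}

#' @method autoplot fusegnn_fit
#' @export
autoplot.fusegnn_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$value,
                               colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Loss component",
                  title = sprintf("Training losses (%s)", object$config$mode)) +
    ggplot2::theme_minimal()
}

#' @method autoplot differential_fc
#' @export
autoplot.differential_fc <- function(object, ...) {
  df <- expand.grid(roi_a = object$roi_labels, roi_b = object$roi_labels,
                    stringsAsFactors = FALSE)
  df$delta <- as.vector(object$diff)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$roi_a, y = .data$roi_b,
                                   fill = .data$delta)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "case - control",
                  title = "Differential learned connectivity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}
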