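# broom-style accessors and ggplot2 autoplot methods for the fitted
# objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training history of a fitted model
#'
#' @param x An `fpgnn_model`.
#' @param ... Unused.
#' @return Tibble with `epoch`, `loss` and `val_mean_ba`.
#' @export
tidy.fpgnn_model <- function(x, ...) {
  x$history %||% tibble::tibble(epoch = integer(), loss = numeric(),
                                val_mean_ba = numeric())
}

#' One-row summary of a fitted model
#'
#' @inheritParams tidy.fpgnn_model
#' @return Tibble with task count, parameter count, best epoch and best
#'   validation mean balanced accuracy.
#' @export
glance.fpgnn_model <- function(x, ...) {
  tibble::tibble(n_tasks = x$config$n_tasks,
                 n_parameters = sum(vapply(x$params, length, integer(1))),
                 best_epoch = x$best_epoch %||% NA_integer_,
                 best_val_ba = x$best_val_ba %||% NA_real_)
}

#' Tidy a multi-seed run result
#'
#' @param x An `fpgnn_run_result`.
#' @param ... Unused.
#' @return The summary tibble (`split`, `task_id`, `metric`, `mean`,
#'   `sd`, `formatted`).
#' @export
tidy.fpgnn_run_result <- function(x, ...) x$summary

#' @rdname tidy.fpgnn_run_result
#' @export
glance.fpgnn_run_result <- function(x, ...) {
  avg <- dplyr::filter(x$summary, .data$task_id == ".average",
                       .data$split == "test")
  out <- tidyr::pivot_wider(avg[c("metric", "mean")],
                            names_from = "metric", values_from = "mean")
  dplyr::bind_cols(tibble::tibble(n_seeds = length(x$seeds)), out)
}

#' Tidy an applicability-domain model
#'
#' @param x An `ad_model`.
#' @param ... Unused.
#' @return Tibble of per-training-molecule mean k-NN distances.
#' @export
tidy.ad_model <- function(x, ...) {
  tibble::tibble(molecule = seq_along(x$per_molecule),
                 knn_distance = x$per_molecule)
}

#' @rdname tidy.ad_model
#' @export
glance.ad_model <- function(x, ...) {
  tibble::tibble(k = x$k, Z = x$Z, d_ave = x$d_ave, theta = x$theta,
                 D_T = x$D_T, n_train = nrow(x$train_fps))
}

#' Plot the training history
#'
#' @param object An `fpgnn_model`.
#' @param ... Unused.
#' @return A ggplot: loss and validation mean balanced accuracy per
#'   epoch.
#' @export
autoplot.fpgnn_model <- function(object, ...) {
  hist <- tidy.fpgnn_model(object)
  long <- tidyr::pivot_longer(hist, cols = c("loss", "val_mean_ba"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(ggplot2::vars(.data$series), scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL,
                  title = "Training loss and validation mean BA") +
    ggplot2::theme_minimal()
}

#' Plot per-metric means with seed variability
#'
#' @param object An `fpgnn_run_result`.
#' @param split Which split to show (default `"test"`).
#' @param ... Unused.
#' @return A ggplot of mean +/- sd per metric and task.
#' @export
autoplot.fpgnn_run_result <- function(object, split = "test", ...) {
  dat <- dplyr::filter(object$summary, .data$split == !!split)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$metric, y = .data$mean,
                                    colour = .data$task_id)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = NULL, y = "value",
                  title = paste("Metrics on the", split, "set")) +
    ggplot2::theme_minimal()
}

#' Plot the k-NN distance distribution and threshold of a domain model
#'
#' @param object An `ad_model`.
#' @param ... Unused.
#' @return A ggplot: histogram of per-molecule k-NN distances with the
#'   D_T threshold marked.
#' @export
autoplot.ad_model <- function(object, ...) {
  dat <- tidy.ad_model(object)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$knn_distance)) +
    ggplot2::geom_histogram(bins = 30) +
    ggplot2::geom_vline(xintercept = object$D_T, linetype = "dashed") +
    ggplot2::labs(x = "mean k-NN Euclidean distance", y = "count",
                  title = sprintf("Applicability domain (k = %d, Z = %.2f, D_T = %.2f)",
                                  object$k, object$Z, object$D_T)) +
    ggplot2::theme_minimal()
}

#' Heatmap of out-of-domain counts over the (k, Z) grid
#'
#' @param grid Tibble from [ad_grid_search()].
#' @return A ggplot tile map of `n_OD`.
#' @export
plot_ad_grid <- function(grid) {
  ggplot2::ggplot(grid, ggplot2::aes(x = factor(.data$Z),
                                     y = factor(.data$k),
                                     fill = .data$n_OD)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_OD), colour = "white") +
    ggplot2::labs(x = "Z", y = "k", fill = "n OD") +
    ggplot2::theme_minimal()
}
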