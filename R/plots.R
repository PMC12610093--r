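#' @importFrom Rcpp evalCpp
#' @useDynLib eegcca, .registration = TRUE
NULL

#' Tidiers for cross-validation reports
#'
#' `tidy()` returns the per-fold results; `glance()` a one-row summary.
#'
#' @param x A `metrics_report` from [cross_validate()] or [run_pipeline()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.metrics_report <- function(x, ...) x$per_fold

#' @rdname tidy.metrics_report
#' @export
glance.metrics_report <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, n_folds = nrow(x$per_fold),
                 mean_accuracy = x$mean, sd_accuracy = x$sd, f1 = x$f1)
}

#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @export
glance <- function(x, ...) UseMethod("glance")

#' Plot a training history
#'
#' Loss and training accuracy per epoch.
#'
#' @param object A `training_history` tibble from [train_model()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.training_history <- function(object, ...) {
  df <- rbind(
    data.frame(epoch = object$epoch, value = object$loss, metric = "loss"),
    data.frame(epoch = object$epoch, value = object$accuracy, metric = "training accuracy")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the pooled confusion matrix of a report
#'
#' @param object A `metrics_report`.
#' @param normalise Show row-normalised proportions instead of counts.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.metrics_report <- function(object, normalise = TRUE, ...) {
  cm <- object$confusion
  if (normalise) cm <- cm / pmax(1, rowSums(cm))
  df <- expand.grid(true = seq_len(nrow(cm)), pred = seq_len(ncol(cm)))
  df$value <- as.vector(cm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pred, y = .data$true,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$value)),
                       colour = "white") +
    ggplot2::scale_y_reverse(breaks = seq_len(nrow(cm))) +
    ggplot2::scale_x_continuous(breaks = seq_len(ncol(cm))) +
    ggplot2::labs(x = "predicted class", y = "true class",
                  fill = if (normalise) "proportion" else "count") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
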