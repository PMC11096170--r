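# ggplot2 visual summaries for the main result types.

#' Plot per-phantom MAPE by model
#'
#' @param object A `phantom_study`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.phantom_study <- function(object, ...) {
  ggplot2::ggplot(
    object$report,
    ggplot2::aes(x = .data$phantom, y = .data$mape, fill = .data$model)
  ) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y") +
    ggplot2::labs(
      x = NULL, y = "MAPE (%)",
      title = sprintf("Per-phantom error, Model %s", object$schema$name)
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot FCNN training and validation loss curves
#'
#' @param object An `fcnn_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fcnn_fit <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = .data$epoch, y = .data$mse, colour = .data$partition)
  ) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      y = "MSE loss",
      title = sprintf("FCNN loss (%s)", object$target)
    ) +
    ggplot2::theme_minimal()
}

#' Plot line profiles from one or more models
#'
#' @param profiles Named list of [line_profile()] tibbles (one per model) or
#'   a single tibble.
#' @return A ggplot.
#' @export
plot_line_profiles <- function(profiles) {
  if (is.data.frame(profiles)) profiles <- list(profile = profiles)
  df <- dplyr::bind_rows(profiles, .id = "model")
  ggplot2::ggplot(
    df,
    ggplot2::aes(x = .data$position_mm, y = .data$value, colour = .data$model)
  ) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "position (mm)", y = "value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
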