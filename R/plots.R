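#' Plot loss landscape curves
#'
#' One panel per abscissa (`p_t` for cross entropy-family components, `mTI`
#' for Tversky-family components), one curve per loss component.
#'
#' @param object A [loss_landscape()] table.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.landscape_table <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$x, y = .data$value,
                               colour = .data$loss,
                               linetype = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~abscissa, scales = "free",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "p_t  /  (modified) Tversky index",
                  y = "per-position / per-class loss term") +
    ggplot2::theme_minimal()
}

#' Plot benchmark results per loss
#'
#' Shows the chosen metric on the rarest class for every (loss, seed) run,
#' with per-loss means.
#'
#' @param object A [run_benchmark()] result.
#' @param metric One of `"dsc"`, `"iou"`, `"recall"`, `"precision"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.benchmark_result <- function(object, metric = "dsc", ...) {
  rare <- max(object$class)
  d <- dplyr::filter(tibble::as_tibble(object), .data$class == rare)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$loss, y = .data[[metric]])) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18, size = 4,
                          colour = "red") +
    ggplot2::labs(x = NULL, y = paste("foreground", metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a gamma stability sweep
#'
#' @param object A [gamma_sweep()] result.
#' @param metric Metric column to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gamma_sweep <- function(object, metric = "dsc", ...) {
  rare <- max(object$class)
  d <- dplyr::filter(tibble::as_tibble(object), .data$class == rare)
  d <- dplyr::summarise(dplyr::group_by(d, .data$gamma, .data$variant),
                        value = mean(.data[[metric]], na.rm = TRUE),
                        .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$gamma, y = .data$value,
                                  colour = .data$variant)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "gamma", y = paste("foreground", metric)) +
    ggplot2::theme_minimal()
}

#' Plot an image/mask pair from a synthetic task
#'
#' @param object A [generate_task()] result (2D tasks only).
#' @param index Which image to show.
#' @param ... Unused.
#' @return A ggplot with image and mask panels.
#' @export
autoplot.synthetic_task <- function(object, index = 1, ...) {
  if (length(object$spec$shape) != 2) {
    stop("autoplot is only available for 2D tasks", call. = FALSE)
  }
  H <- object$spec$shape[1]; W <- object$spec$shape[2]
  d <- tidyr::expand_grid(col = seq_len(W), row = seq_len(H))
  d <- dplyr::bind_rows(
    dplyr::mutate(d, value = as.vector(object$images[index, , , 1]),
                  panel = "image"),
    dplyr::mutate(d, value = as.vector(object$masks[index, , ]) /
                    max(1, object$num_classes - 1), panel = "mask"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = .data$row,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~panel) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::theme(legend.position = "none")
}
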