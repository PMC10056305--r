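#' Plot a phase portrait
#'
#' Renders the binary occupancy image with the conventional orientation
#' (y increasing upward; the origin of phase space at the bottom left).
#'
#' @param object A `phase_portrait`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot phase_portrait
#' @export
autoplot.phase_portrait <- function(object, ...) {
  img <- object$image
  p <- nrow(img)
  df <- tidyr::expand_grid(row = seq_len(p), col = seq_len(p))
  df$occupied <- as.vector(img)[(df$col - 1) * p + df$row]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = p + 1 - .data$row,
                                   fill = factor(.data$occupied))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "white", `1` = "black"),
                               guide = "none") +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(
      title = sprintf("%s: tau = %g ms, %d x %d grid", object$subject_id,
                      object$tau_ms, object$partitions, object$partitions),
      x = "x(t)", y = "x(t + tau)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' Plot the validation-accuracy trace of a fitted model
#'
#' @param object A `psr_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psr_model
#' @export
autoplot.psr_model <- function(object, ...) {
  ggplot2::ggplot(object$trace,
                  ggplot2::aes(x = .data$epoch, y = .data$val_accuracy)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Epoch", y = "Validation accuracy (%)") +
    ggplot2::theme_minimal()
}

#' Heatmap of stage-averaged sweep accuracy
#'
#' One tile per (time delay, grid density) cell, facetted by training
#' stage — the standard view of the factorial sweep.
#'
#' @param object A `psr_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot psr_sweep
#' @export
autoplot.psr_sweep <- function(object, ...) {
  st <- object$stages
  ggplot2::ggplot(st, ggplot2::aes(x = factor(.data$tau_ms),
                                   y = factor(.data$grid),
                                   fill = .data$mean_accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$mean_accuracy)), size = 2.6) +
    ggplot2::facet_wrap(~ epochs) +
    ggplot2::scale_fill_viridis_c(name = "Accuracy (%)") +
    ggplot2::labs(x = "Time delay (ms)", y = "Grid partitions") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
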