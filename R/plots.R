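# ggplot2 displays for slides, loss histories, and evaluations

#' Plot a slide image, optionally with its mask or a prediction outline
#'
#' @param slide A `slide_image`.
#' @param mask Optional 0/1 matrix to overlay (defaults to the slide's own
#'   ground truth when present).
#' @return A ggplot object.
#' @export
plot_slide <- function(slide, mask = slide$mask) {
  H <- nrow(slide$rgb); W <- ncol(slide$rgb)
  df <- tidyr::expand_grid(y = seq_len(H), x = seq_len(W))
  df$fill <- grDevices::rgb(as.vector(slide$rgb[, , 1]),
                            as.vector(slide$rgb[, , 2]),
                            as.vector(slide$rgb[, , 3]))
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::labs(title = slide$image_id) +
    ggplot2::theme_void()
  if (!is.null(mask)) {
    dm <- df[as.vector(mask) == 1, c("x", "y")]
    p <- p + ggplot2::geom_tile(data = dm, fill = NA, color = "#00d000",
                                linewidth = 0.1)
  }
  p
}

#' @export
autoplot.phase_result <- function(object, ...) {
  d <- tidyr::pivot_longer(tidy(object), c("train_loss", "val_loss"),
                           names_to = "set", values_to = "loss")
  ggplot2::ggplot(d, ggplot2::aes(.data$epoch, .data$loss,
                                  color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(title = sprintf("%s phase", object$phase),
                  y = if (object$phase == "reconstruction") "MSE" else "BCE") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cae_fit <- function(object, ...) {
  d <- tidyr::pivot_longer(tidy(object), c("train_loss", "val_loss"),
                           names_to = "set", values_to = "loss")
  d$phase <- factor(d$phase, levels = names(object$phases))
  ggplot2::ggplot(d, ggplot2::aes(.data$epoch, .data$loss,
                                  color = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~phase, scales = "free") +
    ggplot2::labs(y = "loss") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.seg_evaluation <- function(object, ...) {
  d <- tidyr::pivot_longer(tibble::as_tibble(object),
                           c("dsc", "sensitivity", "specificity"),
                           names_to = "metric", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(.data$image_id, .data$value)) +
    ggplot2::geom_col(fill = "#4477aa") +
    ggplot2::facet_wrap(~metric) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
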