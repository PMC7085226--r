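# ggplot2 displays for the pipeline's result objects.

raster_df <- function(m) {
  tibble::tibble(
    row = rep(seq_len(nrow(m)), times = ncol(m)),
    col = rep(seq_len(ncol(m)), each = nrow(m)),
    value = as.vector(m)
  )
}

#' @describeIn segment_nuclei Display the preprocessed image with superpixel
#'   boundaries and segmented-nucleus centroids.
#' @param object A `nucleus_segmentation` object.
#' @method autoplot nucleus_segmentation
#' @export
autoplot.nucleus_segmentation <- function(object, ...) {
  df <- raster_df(object$prep)
  lab <- object$labeling$labels
  # superpixel boundary: label differs from the right or lower neighbour
  edge <- matrix(FALSE, nrow(lab), ncol(lab))
  edge[-nrow(lab), ] <- edge[-nrow(lab), ] | (lab[-nrow(lab), ] != lab[-1L, ])
  edge[, -ncol(lab)] <- edge[, -ncol(lab)] | (lab[, -ncol(lab)] != lab[, -1L])
  df$edge <- as.vector(edge)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::geom_point(
      data = dplyr::filter(df, .data$edge),
      color = "yellow", size = 0.01, alpha = 0.4
    ) +
    ggplot2::scale_fill_gradient(low = "black", high = "red", name = "TPAF") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("%d nuclei segmented", nrow(object$nuclei)),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
  if (nrow(object$nuclei) > 0L) {
    p <- p + ggplot2::geom_point(
      data = object$nuclei,
      ggplot2::aes(x = .data$centroid_col, y = .data$centroid_row),
      color = "cyan", shape = 3, size = 2
    )
  }
  p
}

#' @describeIn quantify_collagen Display the binarized collagen mask.
#' @param object A `collagen_result`.
#' @method autoplot collagen_result
#' @export
autoplot.collagen_result <- function(object, ...) {
  df <- raster_df(object$mask)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value == 255)) +
    ggplot2::scale_fill_manual(
      values = c(`FALSE` = "black", `TRUE` = "green3"),
      name = "collagen", labels = c("background", "fiber")
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = sprintf("collagen content %.1f%%", object$content_pct),
      x = NULL, y = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn compare_groups Group means with +/- SD error bars per metric.
#' @param object An `mpm_comparison` tibble.
#' @param ... Unused.
#' @method autoplot mpm_comparison
#' @export
autoplot.mpm_comparison <- function(object, ...) {
  long <- dplyr::bind_rows(
    tibble::tibble(
      metric = object$metric, group = "pre",
      mean = object$mean_pre, sd = object$sd_pre, p_bin = object$p_bin
    ),
    tibble::tibble(
      metric = object$metric, group = "post",
      mean = object$mean_post, sd = object$sd_post, p_bin = object$p_bin
    )
  )
  long$group <- factor(long$group, levels = c("pre", "post"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$group), width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.2
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::geom_text(
      data = dplyr::distinct(long, .data$metric, .data$p_bin),
      ggplot2::aes(label = paste("p", .data$p_bin)),
      x = 1.5, y = Inf, vjust = 1.5, inherit.aes = FALSE
    ) +
    ggplot2::labs(x = NULL, y = "mean ± SD") +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Show a red/green overlay as a ggplot
#'
#' @param tpaf,shg Same-shape [mpm_image()] pair.
#' @return A ggplot object of the pseudo-colored composite (TPAF in red,
#'   SHG in green).
#' @export
plot_overlay <- function(tpaf, shg) {
  ov <- render_overlay(tpaf, shg)
  df <- tibble::tibble(
    row = rep(seq_len(nrow(tpaf)), times = ncol(tpaf)),
    col = rep(seq_len(ncol(tpaf)), each = nrow(tpaf)),
    hex = grDevices::rgb(as.vector(ov[, , 1L]), as.vector(ov[, , 2L]), 0,
      maxColorValue = 255
    )
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$hex)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_void()
}
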