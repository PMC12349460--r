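#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

mask_to_df <- function(mask, label) {
  m <- as_mask_matrix(mask)
  idx <- which(m == 1L)
  tibble::tibble(
    x = (idx - 1L) %/% nrow(m),
    y = (idx - 1L) %% nrow(m),
    class = label
  )
}

#' Plot a segmentation result with optional picking points
#'
#' Renders corolla and stem foreground pixels in image orientation (y axis
#' pointing down) and overlays located picking points and/or ground-truth
#' calyx points when supplied.
#'
#' @param object a [segmentation_result()].
#' @param points optional tibble from [process_image()].
#' @param truth optional tibble with `calyx_x` / `calyx_y` columns.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.segmentation_result <- function(object, points = NULL, truth = NULL,
                                         ...) {
  dfs <- c(
    purrr::imap(object$corolla_instances,
                function(m, i) mask_to_df(m, sprintf("corolla %d", i))),
    purrr::imap(object$stem_instances,
                function(m, i) mask_to_df(m, sprintf("stem %d", i)))
  )
  df <- dplyr::bind_rows(dfs)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$class)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(
      xlim = c(0, object$image_shape[2L] - 1L),
      ylim = c(object$image_shape[1L] - 1L, 0)
    ) +
    ggplot2::labs(x = "x (px)", y = "y (px)", fill = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    p <- p + ggplot2::geom_point(
      data = truth,
      ggplot2::aes(x = .data$calyx_x, y = .data$calyx_y),
      shape = 3, size = 3, colour = "black", stroke = 1.2
    )
  }
  if (!is.null(points)) {
    found <- points[points$status == "found", , drop = FALSE]
    if (nrow(found) > 0L) {
      p <- p + ggplot2::geom_point(
        data = found, ggplot2::aes(x = .data$x, y = .data$y),
        shape = 21, size = 3, fill = "yellow", colour = "red"
      )
    }
  }
  p
}

#' Plot a per-module complexity breakdown
#'
#' @param object a [model_summary()].
#' @param metric `"params"` or `"gflops"`.
#' @param ... unused.
#' @export
autoplot.model_summary <- function(object, metric = c("params", "gflops"),
                                   ...) {
  metric <- match.arg(metric)
  df <- object[object$module != "total", , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$module, y = .data[[metric]], fill = .data$module
  )) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::labs(
      x = NULL,
      y = if (metric == "params") "trainable parameters" else "GFLOPs"
    ) +
    ggplot2::theme_minimal()
}
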