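#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_path geom_raster
#'   scale_fill_gradient scale_color_gradientn coord_fixed labs theme_minimal
#'   scale_y_reverse
#' @export
ggplot2::autoplot

matrix_to_df <- function(img) {
  tibble::tibble(
    x = rep(seq_len(ncol(img)), each = nrow(img)),
    y = rep(seq_len(nrow(img)), ncol(img)),
    value = as.vector(img)
  )
}

#' Plot a normalized angular distribution
#'
#' @param object an `angular_histogram` from [angular_distribution()].
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot angular_histogram
#' @export
autoplot.angular_histogram <- function(object, ...) {
  ggplot(object, aes(x = (.data$bin_start + .data$bin_end) / 2,
                     y = .data$normalized)) +
    geom_col(width = (object$bin_end[1] - object$bin_start[1]) * 0.92,
             fill = "steelblue") +
    labs(x = "orientation (degrees from image horizontal)",
         y = "normalized fiber count") +
    theme_minimal()
}

#' Plot extracted fibers colored by orientation
#'
#' @param object an `ft_fibers` tibble.
#' @param image optional background image matrix.
#' @param ... unused.
#' @return a ggplot (y axis reversed to match image row order).
#' @method autoplot ft_fibers
#' @export
autoplot.ft_fibers <- function(object, image = NULL, ...) {
  p <- ggplot()
  if (!is.null(image)) {
    p <- p + geom_raster(data = matrix_to_df(image),
                         aes(x = .data$x, y = .data$y, fill = .data$value)) +
      scale_fill_gradient(low = "black", high = "white", guide = "none")
  }
  if (nrow(object)) {
    df <- dplyr::bind_rows(lapply(seq_len(nrow(object)), function(i)
      tibble::tibble(fiber_id = object$fiber_id[i],
                     theta = object$theta_deg[i],
                     x = object$pixels[[i]][, 1], y = object$pixels[[i]][, 2])))
    p <- p + geom_path(data = df,
                       aes(x = .data$x, y = .data$y,
                           group = .data$fiber_id, color = .data$theta),
                       linewidth = 0.7) +
      scale_color_gradientn(colors = grDevices::hsv(seq(0, 1, length.out = 13)),
                            limits = c(0, 180), name = "theta (deg)")
  }
  p + coord_fixed() + scale_y_reverse() + theme_minimal() +
    labs(x = "x (px)", y = "y (px)")
}

#' Plot a synthetic scene composite
#'
#' @param object a `synthetic_scene`.
#' @param which `"composite"`, `"truth_image"`, `"artifacts_image"` or
#'   `"truth_mask"`.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot synthetic_scene
#' @export
autoplot.synthetic_scene <- function(object, which = "composite", ...) {
  img <- object[[which]]
  if (is.logical(img)) img <- img * 1
  ggplot(matrix_to_df(img), aes(x = .data$x, y = .data$y, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", name = which) +
    coord_fixed() + scale_y_reverse() + theme_minimal() +
    labs(x = "x (px)", y = "y (px)")
}

#' @importFrom rlang .data
NULL
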