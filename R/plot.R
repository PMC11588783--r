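# Visualization: ggplot2 autoplot methods for the result objects and a
# PNG heatmap-overlay writer for CAM maps. Display normalization (dividing
# a CAM by its maximum) happens only here, never in quantitative code.

grid_df <- function(m, value_name = "value") {
  d <- dim(m)
  tibble::tibble(
    y = rep(seq_len(d[1]), times = d[2]),
    x = rep(seq_len(d[2]), each = d[1]),
    !!value_name := as.vector(m)
  )
}

mid_slice <- function(arr) {
  if (length(dim(arr)) == 3L) arr[ceiling(dim(arr)[1] / 2), , ] else arr
}

#' @export
autoplot.us_phantom <- function(object, ...) {
  img <- mid_slice(object$image$data)
  df <- grid_df(img, "intensity")
  df$border <- dplyr::case_when(
    as.vector(mid_slice(object$designed_distinct)) ~ "distinct",
    as.vector(mid_slice(object$designed_completed)) ~ "completed",
    TRUE ~ NA_character_
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_point(
      data = dplyr::filter(df, !is.na(.data$border)),
      ggplot2::aes(colour = .data$border), size = 0.3) +
    ggplot2::scale_colour_manual(
      values = c(distinct = "red", completed = "deepskyblue")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "Phantom with designed border split",
                  fill = "intensity", colour = "border") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.us_edge_map <- function(object, ...) {
  df <- grid_df(mid_slice(object$mask) * 1, "edge")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = factor(.data$edge))) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = c(`0` = "black", `1` = "yellow"),
                               labels = c("background", "edge"),
                               name = NULL) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Edge map (%s threshold %.3g)",
                                  object$params$threshold_method,
                                  object$threshold)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.us_border_split <- function(object, ...) {
  df <- grid_df(mid_slice(object$border) * 1, "b")
  df$part <- dplyr::case_when(
    as.vector(mid_slice(object$distinct)) ~ "distinct",
    as.vector(mid_slice(object$completed)) ~ "completed",
    TRUE ~ NA_character_
  )
  ggplot2::ggplot(dplyr::filter(df, !is.na(.data$part)),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               colour = .data$part)) +
    ggplot2::geom_point(size = 0.5) +
    ggplot2::scale_colour_manual(
      values = c(distinct = "red", completed = "deepskyblue")) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Border split, class %d",
                                  object$class_id),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.us_cam <- function(object, ...) {
  img <- object$image
  gray <- if (diff(range(img)) > 0) {
    (img - min(img)) / diff(range(img))
  } else img * 0
  camn <- object$upsampled
  if (max(camn) > 0) camn <- camn / max(camn)
  df <- grid_df(gray, "gray")
  df$cam <- as.vector(camn)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$gray)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_raster(
      data = dplyr::filter(df, .data$cam > 0.05),
      ggplot2::aes(alpha = .data$cam), fill = "red") +
    ggplot2::scale_alpha(range = c(0, 0.8), name = "CAM") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Seg-Grad-CAM, layer %s, class %d",
                                  object$layer, object$target$class_id)) +
    ggplot2::theme_minimal()
}

heat_rgb <- function(t) {
  # simple black-red-yellow-white colormap on [0,1]
  r <- pmin(1, 3 * t)
  g <- pmin(1, pmax(0, 3 * t - 1))
  b <- pmin(1, pmax(0, 3 * t - 2))
  list(r = r, g = g, b = b)
}

#' Write a CAM heatmap blended over the grayscale image
#'
#' Produces a PNG of the image with the (display-normalized) CAM as a
#' heat-colored overlay and an optional white border contour. 3D inputs
#' are rendered at the mid-slice of the first axis. An all-zero CAM yields
#' a pure grayscale image.
#'
#' @param image an [image_volume()].
#' @param cam a `us_cam` with an `upsampled` map.
#' @param out output PNG path.
#' @param contour optional logical mask drawn in white (e.g. a predicted
#'   border).
#' @param alpha maximal heat opacity in `[0, 1]`.
#' @return `out`, invisibly.
#' @export
render_overlay <- function(image, cam, out, contour = NULL, alpha = 0.6) {
  stopifnot(inherits(cam, "us_cam"))
  if (is.null(cam$upsampled)) {
    stop("render_overlay: CAM has no upsampled map", call. = FALSE)
  }
  img <- mid_slice(if (inherits(image, "us_volume")) image$data
                   else as.array(image))
  check_same_shape(img, cam$upsampled, "image slice and CAM")
  gray <- if (diff(range(img)) > 0) {
    (img - min(img)) / diff(range(img))
  } else img * 0
  camn <- cam$upsampled
  if (max(camn) > 0) camn <- camn / max(camn)    # display only
  hk <- heat_rgb(camn)
  w <- alpha * camn
  rgb <- array(0, c(dim(img), 3L))
  rgb[, , 1] <- (1 - w) * gray + w * hk$r
  rgb[, , 2] <- (1 - w) * gray + w * hk$g
  rgb[, , 3] <- (1 - w) * gray + w * hk$b
  if (!is.null(contour)) {
    cm <- mid_slice(contour)
    for (k in 1:3) {
      ch <- rgb[, , k]; ch[cm] <- 1; rgb[, , k] <- ch
    }
  }
  png::writePNG(pmin(pmax(rgb, 0), 1), out)
  invisible(out)
}
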