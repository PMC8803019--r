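#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an axis-offset search
#'
#' @param x An `rnfb_offset_search` object.
#' @param ... Unused.
#' @return `tidy()` returns the objective curve (tibble `offset`, `ssd`);
#'   `glance()` a one-row tibble with `ofs` and `n_pixels`.
#' @exportS3Method generics::tidy
tidy.rnfb_offset_search <- function(x, ...) x$objective_curve

#' @rdname tidy.rnfb_offset_search
#' @exportS3Method generics::glance
glance.rnfb_offset_search <- function(x, ...) {
  tibble::tibble(ofs = x$ofs, n_pixels = x$n_pixels,
                 ssd_min = min(x$objective_curve$ssd))
}

#' Tidy a model fit
#'
#' @param x An `rnfb_model_fit`.
#' @param ... Unused.
#' @return One-row tibble with the similarity-transform terms.
#' @exportS3Method generics::tidy
tidy.rnfb_model_fit <- function(x, ...) {
  tibble::tibble(
    term = c("fovea_x_um", "fovea_y_um", "rotation_deg", "scale_um_per_deg"),
    estimate = c(x$fovea_um[1], x$fovea_um[2], x$rotation * 180 / pi,
                 x$scale)
  )
}

#' Tidy a trace
#'
#' @param x An `rnfb_trace`.
#' @param ... Unused.
#' @return `tidy()` returns the point tibble with a step index;
#'   `glance()` a one-row summary.
#' @exportS3Method generics::tidy
tidy.rnfb_trace <- function(x, ...) {
  dplyr::mutate(x$points, step = dplyr::row_number() - 1L)
}

#' @rdname tidy.rnfb_trace
#' @exportS3Method generics::glance
glance.rnfb_trace <- function(x, ...) {
  tibble::tibble(n_points = nrow(x$points), step_px = x$step_px,
                 direction_mode = x$direction_mode,
                 termination = x$termination)
}

#' Plot an orientation map
#'
#' Renders an [axial_map()] as a hue wheel over the half-circle of axial
#' angles (invalid pixels blank), with optional ONH/fovea landmarks.
#'
#' @param m An [axial_map()].
#' @param geometry Optional [retinal_geometry()] to overlay landmarks.
#' @param stride Subsampling stride for large maps (default 1).
#' @return A ggplot object.
#' @export
plot_axial_map <- function(m, geometry = NULL, stride = 1) {
  nr <- nrow(m$values); nc <- ncol(m$values)
  ys <- seq(1, nr, by = stride); xs <- seq(1, nc, by = stride)
  df <- tidyr::expand_grid(y = ys, x = xs)
  df$angle <- m$values[cbind(df$y, df$x)] * 180 / pi
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        fill = .data$angle)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colours = c("#d73027", "#fee090", "#1a9850", "#4575b4", "#d73027"),
      limits = c(0, 180), na.value = "grey90",
      name = "orientation (deg)"
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(ratio = m$spacing_y / m$spacing_x) +
    ggplot2::theme_minimal()
  if (!is.null(geometry)) {
    lm <- tibble::tibble(
      x = c(geometry$fovea_xy[1], geometry$onh_xy[1]),
      y = c(geometry$fovea_xy[2], geometry$onh_xy[2]),
      what = c("fovea", "ONH")
    )
    p <- p + ggplot2::geom_point(
      data = lm, ggplot2::aes(.data$x, .data$y, shape = .data$what),
      inherit.aes = FALSE, size = 3
    )
  }
  p
}

#' Plot traces over an optional background map
#'
#' @param traces List of `rnfb_trace` objects.
#' @param geometry Optional [retinal_geometry()] for landmark overlay.
#' @return A ggplot object.
#' @export
plot_traces <- function(traces, geometry = NULL) {
  df <- purrr::imap(traces, function(tr, nm) {
    dplyr::mutate(tr$points, trace = nm)
  }) |> dplyr::bind_rows()
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x_px, .data$y_px,
                                        group = .data$trace)) +
    ggplot2::geom_path(alpha = 0.7, linewidth = 0.3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
  if (!is.null(geometry)) {
    circ <- tibble::tibble(
      t = seq(0, 2 * pi, length.out = 200),
      x = geometry$onh_xy[1] + cos(t) * geometry$onh_radius_deg *
        geometry$um_per_deg / geometry$spacing_x,
      y = geometry$onh_xy[2] + sin(t) * geometry$onh_radius_deg *
        geometry$um_per_deg / geometry$spacing_y
    )
    p <- p + ggplot2::geom_path(
      data = circ, ggplot2::aes(.data$x, .data$y), inherit.aes = FALSE,
      color = "red"
    )
  }
  p
}

#' @importFrom rlang .data
NULL
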