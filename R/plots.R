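#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Maximum-intensity projection of a stack
#'
#' Projects each channel along z and renders the projections as facetted
#' raster panels — the quick-look view of an acquisition or phantom.
#'
#' @param object an [image_stack()].
#' @param channels channels to show (default all).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.image_stack <- function(object, channels = NULL, ...) {
  channels <- channels %||% object$channel_names
  sp <- unclass(object$spacing)
  dfs <- lapply(channels, function(ch) {
    arr <- get_channel(object, ch)
    mip <- apply(arr, c(2, 3), max)
    d <- dim(mip)
    tibble(
      channel = ch,
      y = rep((seq_len(d[1]) - 1) * sp[["dy"]], times = d[2]),
      x = rep((seq_len(d[2]) - 1) * sp[["dx"]], each = d[1]),
      intensity = as.vector(mip)
    )
  })
  df <- bind_rows(dfs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::facet_wrap(~channel) +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  title = "maximum-intensity projection") +
    ggplot2::theme_minimal()
}

#' Plot a vessel network projection coloured by tortuosity
#'
#' Projects each centreline polyline onto the x-y plane.
#'
#' @param object a `skeleton_graph`.
#' @param colour_by edge column used for colour (default tortuosity).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.skeleton_graph <- function(object, colour_by = "tortuosity", ...) {
  dfs <- lapply(seq_along(object$polylines), function(e) {
    pl <- object$polylines[[e]]
    tibble(edge_id = e, x = pl[, 3], y = pl[, 2],
           value = object$edges[[colour_by]][e])
  })
  df <- bind_rows(dfs)
  nodes <- dplyr::filter(object$nodes, .data$kind == "branchpoint")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                        group = .data$edge_id,
                                        colour = .data$value)) +
    ggplot2::geom_path(linewidth = 1) +
    ggplot2::scale_colour_viridis_c(name = colour_by) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  title = "vessel centreline network") +
    ggplot2::theme_minimal()
  if (nrow(nodes)) {
    p <- p + ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$cx, y = .data$cy),
      inherit.aes = FALSE, shape = 21, fill = "white", size = 2
    )
  }
  p
}

#' Per-group metric panels of a morphometry report
#'
#' Jittered points with group medians for each of the eight canonical
#' metrics — the summary figure of a multi-group run.
#'
#' @param object a `morphometry_report` from [run_quantification()].
#' @param metrics metric columns to show (default all eight).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.morphometry_report <- function(object, metrics = NULL, ...) {
  metrics <- metrics %||% intersect(report_metric_columns(), names(object))
  df <- tidyr::pivot_longer(
    as_tibble(object)[, c("image_id", "group", metrics)],
    dplyr::all_of(metrics), names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$value)) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.8) +
    ggplot2::stat_summary(fun = stats::median, geom = "crossbar",
                          width = 0.4, linewidth = 0.3) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Knot shape scatter: elongation vs flatness
#'
#' EI-FI scatter of detected knots; spheres sit at (1, 1), elongated
#' knots at low EI, plate-like knots at low FI.
#'
#' @param knots knot records from [detect_knots()].
#' @return a ggplot.
#' @export
plot_knot_shape <- function(knots) {
  ggplot2::ggplot(knots, ggplot2::aes(x = .data$EI, y = .data$FI,
                                      size = .data$volume_um3)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::xlim(0, 1) + ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "elongation index (EI)", y = "flatness index (FI)",
                  size = expression(volume ~ (mu * m^3))) +
    ggplot2::theme_minimal()
}
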