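#' Tidy chart, mapping, connection and legend objects
#'
#' `tidy()` returns one row per primitive (slice, color assignment,
#' node-row link, legend element); `glance()` a one-row summary.
#'
#' @param x The object.
#' @param ... Unused.
#' @return A tibble.
#' @name ovglyph-tidiers
NULL

#' @rdname ovglyph-tidiers
#' @export
tidy.ov_chart <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$rings, function(ring, r) {
    dplyr::mutate(ring, node = x$node, ring = r, slice = dplyr::row_number(),
                  .before = 1)
  }))
}

#' @rdname ovglyph-tidiers
#' @export
glance.ov_chart <- function(x, ...) {
  tibble(node = x$node, style = x$style, n_rings = length(x$rings),
         n_slices = sum(vapply(x$rings, nrow, integer(1))),
         arc_start = x$arc_start)
}

#' @rdname ovglyph-tidiers
#' @export
tidy.ov_discrete_mapping <- function(x, ...) x$assignments

#' @rdname ovglyph-tidiers
#' @export
tidy.ov_continuous_mapping <- function(x, ...) {
  tibble(anchor = c("min", "mid", "max"),
         value = c(x$min_value, x$mid_value, x$max_value),
         color = c(x$min_color, x$mid_color, x$max_color))
}

#' @rdname ovglyph-tidiers
#' @export
tidy.ov_connection <- function(x, ...) {
  tibble(node = rep(names(x$rows_per_node), lengths(x$rows_per_node)),
         row = unlist(x$rows_per_node, use.names = FALSE))
}

#' @rdname ovglyph-tidiers
#' @export
glance.ov_connection <- function(x, ...) {
  tibble(table = x$table$name, network = x$network$name,
         net_key = x$net_key, table_key = x$table_key,
         n_nodes = length(x$rows_per_node),
         n_connected_rows = sum(lengths(x$rows_per_node)))
}

#' @rdname ovglyph-tidiers
#' @export
tidy.ov_legend <- function(x, ...) {
  dplyr::bind_rows(purrr::imap(x$elements, function(el, i) {
    tibble(element = i, type = el$type,
           text = el$text %||% el$label %||%
             (if (!is.null(el$columns)) paste(el$columns, collapse = " < ")
              else NA_character_),
           color = el$color %||% NA_character_)
  }))
}

#' Plot a chart glyph
#'
#' Draws the pie or donut as rings of equal-angle slices with their mapped
#' colors, using polar coordinates; a quick visual check of a single node's
#' glyph.
#'
#' @param object An `ov_chart`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ov_chart <- function(object, ...) {
  slices <- tidy(object)
  inner <- if (object$style == "pie") 0 else 1
  slices <- dplyr::mutate(slices,
    r0 = inner + .data$ring - 1, r1 = inner + .data$ring)
  ggplot2::ggplot(slices) +
    ggplot2::geom_rect(ggplot2::aes(
      xmin = .data$start, xmax = .data$end,
      ymin = .data$r0, ymax = .data$r1), fill = slices$color,
      color = "white", linewidth = 0.3) +
    ggplot2::coord_polar(theta = "x", start = pi / 2, direction = 1) +
    ggplot2::scale_x_continuous(limits = object$arc_start + c(0, 360)) +
    ggplot2::ylim(if (object$style == "pie") 0 else -1.5, NA) +
    ggplot2::theme_void() +
    ggplot2::ggtitle(object$node)
}

#' Plot a continuous mapping as a gradient strip
#'
#' @param object An `ov_continuous_mapping`.
#' @param n Number of gradient steps.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ov_continuous_mapping <- function(object, n = 256, ...) {
  v <- seq(object$min_value, object$max_value, length.out = n)
  strip <- tibble(value = v, color = ov_continuous_color(v, object))
  ggplot2::ggplot(strip) +
    ggplot2::geom_tile(ggplot2::aes(x = .data$value, y = 1),
                       fill = strip$color, height = 1) +
    ggplot2::scale_x_continuous(
      breaks = c(object$min_value, object$mid_value, object$max_value)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.title = ggplot2::element_blank(),
                   axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
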