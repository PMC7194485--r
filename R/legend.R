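OV_LEGEND_POSITIONS <- c("EAST_TOP", "EAST", "EAST_BOTTOM",
                         "WEST_TOP", "WEST", "WEST_BOTTOM",
                         "NORTH", "SOUTH")

# reserved group identifier distinguishing legend primitives from any other
# annotation; renamed groups would no longer be recognized as the legend
OV_LEGEND_GROUP <- "ov-legend"

#' Build a grouped legend from the active visualizations
#'
#' One legend block per visualization: the value column name(s) above the
#' color legend; for a donut additionally an ordered list of the ring
#' columns (innermost first). A discrete mapping contributes one color
#' swatch with its label per value; a continuous mapping contributes a
#' gradient bar annotated with the minimum, middle and maximum values
#' (formatted to at most 4 significant digits, otherwise verbatim). Every
#' element is a separate drawing primitive; all primitives share one group
#' identifier so the whole legend can be moved or deleted in one step.
#'
#' @param configs A single [ov_viz_config()] or a list of them (pie and/or
#'   donut).
#' @param title Legend title (may be empty).
#' @param font Font family name.
#' @param font_size Font size in points.
#' @param position One of `EAST_TOP`, `EAST`, `EAST_BOTTOM`, `WEST_TOP`,
#'   `WEST`, `WEST_BOTTOM`, `NORTH`, `SOUTH`.
#' @return An `ov_legend`: list with `elements`, `title`, `font`,
#'   `font_size`, `position` and the reserved `group_name`.
#' @export
ov_build_legend <- function(configs, title = "", font = "Helvetica",
                            font_size = 12, position = "EAST_TOP") {
  if (inherits(configs, "ov_viz_config")) configs <- list(configs)
  if (length(configs) == 0) {
    ov_abort("no active visualization to build a legend from", "input_error")
  }
  ok <- vapply(configs, inherits, logical(1), what = "ov_viz_config")
  if (!all(ok)) ov_abort("configs must be ov_viz_config objects", "input_error")
  position <- match.arg(position, OV_LEGEND_POSITIONS)
  elements <- list()
  add <- function(el) elements[[length(elements) + 1L]] <<- el
  if (nzchar(title)) add(list(type = "text", role = "title", text = title))
  for (config in configs) {
    add(list(type = "text", role = "header",
             text = paste(config$value_columns, collapse = ", ")))
    if (config$style == "donut") {
      add(list(type = "ring_list", columns = config$value_columns))
    }
    m <- config$mapping
    if (inherits(m, "ov_discrete_mapping")) {
      for (i in seq_len(nrow(m$assignments))) {
        add(list(type = "swatch", color = m$assignments$color[i],
                 label = m$assignments$value[i]))
      }
    } else {
      add(list(type = "gradient",
               min_color = m$min_color, mid_color = m$mid_color,
               max_color = m$max_color,
               min_value = m$min_value, mid_value = m$mid_value,
               max_value = m$max_value))
    }
  }
  structure(
    list(elements = elements, title = title, font = font,
         font_size = as.numeric(font_size), position = position,
         group_name = OV_LEGEND_GROUP),
    class = "ov_legend"
  )
}

#' @export
print.ov_legend <- function(x, ...) {
  cat(sprintf("<ov_legend> %d element(s), position %s, title '%s'\n",
              length(x$elements), x$position, x$title))
  invisible(x)
}

ov_fmt_tick <- function(v) {
  s <- signif(v, 4)
  if (is.finite(s) && s == trunc(s) && abs(s) < 1e15) sprintf("%.0f", s)
  else format(s, trim = TRUE, scientific = FALSE)
}

#' Render a decorated network to SVG
#'
#' Draws edges as lines, nodes as circles, pie slices as wedge paths inside
#' the node, donut rings as annulus-sector paths around the node (innermost
#' ring closest to the node), slice labels at the outermost ring, and the
#' legend at its configured position. Every chart slice corresponds to
#' exactly one `<path>` element of class `"slice"`. Output is deterministic:
#' the same inputs and seed give byte-identical SVG.
#'
#' @param network An [ov_network()].
#' @param charts Named list of `ov_chart` objects (names = node ids), or a
#'   list of such lists to overlay several glyph sets (e.g. a pie inside and
#'   a donut outside), or `NULL` for an undecorated network.
#' @param legend An [ov_build_legend()] result, or `NULL`.
#' @param layout Data frame with columns `id`, `x`, `y` giving node
#'   positions; `NULL` uses positions stored in the node table (`x`/`y`
#'   columns) when present, else a deterministic seeded force-directed
#'   layout when `auto_layout` is `TRUE`.
#' @param auto_layout Compute missing positions (default `TRUE`); when
#'   `FALSE`, missing positions are an error.
#' @param seed Seed for the automatic layout.
#' @param path File to write; `NULL` returns the SVG text.
#' @param width,height Canvas size in pixels.
#' @param node_radius Node circle radius in pixels.
#' @return The SVG document as a single string (invisibly when written to
#'   `path`).
#' @export
ov_render_svg <- function(network, charts = NULL, legend = NULL,
                          layout = NULL, auto_layout = TRUE, seed = 42L,
                          path = NULL, width = 800, height = 600,
                          node_radius = 18) {
  stopifnot(inherits(network, "ov_network"))
  chart_sets <- if (is.null(charts)) list()
    else if (all(vapply(charts, inherits, logical(1), what = "ov_chart"))) {
      list(charts)
    } else charts
  pos <- ov_node_positions(network, layout, auto_layout, seed, width, height,
                           node_radius)
  fmt <- function(x) sprintf("%.3f", x)
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  out <- character()
  emit <- function(...) out[[length(out) + 1L]] <<- paste0(...)
  emit(sprintf(paste0(
    '<svg xmlns="http://www.w3.org/2000/svg" version="1.1" ',
    'width="%d" height="%d" viewBox="0 0 %d %d">'),
    round(width), round(height), round(width), round(height)))
  emit('<rect width="100%" height="100%" fill="#FFFFFF"/>')
  # edges
  if (nrow(network$edges) > 0 && nrow(pos) > 0) {
    emit('<g class="edges" stroke="#999999" stroke-width="1">')
    for (i in seq_len(nrow(network$edges))) {
      a <- pos[pos$id == network$edges$source[i], ]
      b <- pos[pos$id == network$edges$target[i], ]
      emit(sprintf('<line x1="%s" y1="%s" x2="%s" y2="%s"/>',
                   fmt(a$x), fmt(a$y), fmt(b$x), fmt(b$y)))
    }
    emit("</g>")
  }
  # nodes and their glyphs
  if (nrow(pos) > 0) {
    emit('<g class="nodes">')
    for (i in seq_len(nrow(pos))) {
      id <- pos$id[i]
      cx <- pos$x[i]; cy <- pos$y[i]
      emit(sprintf(
        '<circle class="node" cx="%s" cy="%s" r="%s" fill="#E8E8E8" stroke="#555555"/>',
        fmt(cx), fmt(cy), fmt(node_radius)))
      for (set in chart_sets) {
        chart <- set[[id]]
        if (!is.null(chart)) {
          emit(ov_svg_chart(chart, cx, cy, node_radius, fmt, esc))
        }
      }
      label <- network$nodes[["display name"]]
      if (!is.null(label) && !is.na(label[network$nodes$id == id][1])) {
        emit(sprintf(
          '<text class="node-label" x="%s" y="%s" font-size="9" text-anchor="middle" font-family="Helvetica">%s</text>',
          fmt(cx), fmt(cy + node_radius + 34), esc(label[network$nodes$id == id][1])))
      }
    }
    emit("</g>")
  }
  if (!is.null(legend)) {
    emit(ov_svg_legend(legend, width, height, fmt, esc))
  }
  emit("</svg>")
  svg <- paste(out, collapse = "\n")
  # validate well-formedness before handing it out
  xml2::read_xml(svg)
  if (is.null(path)) return(svg)
  writeLines(svg, path, sep = "\n")
  invisible(svg)
}

ov_node_positions <- function(network, layout, auto_layout, seed,
                              width, height, node_radius) {
  ids <- network$nodes$id
  if (length(ids) == 0) return(tibble(id = character(), x = numeric(), y = numeric()))
  if (!is.null(layout)) {
    layout <- as_tibble(layout)
    if (!all(c("id", "x", "y") %in% names(layout))) {
      ov_abort("layout must have columns id, x, y", "layout_error")
    }
    missing_ids <- setdiff(ids, layout$id)
    if (length(missing_ids) > 0) {
      ov_abort(sprintf("no position for node(s): %s",
                       paste0("'", utils::head(missing_ids, 5), "'",
                              collapse = ", ")), "layout_error")
    }
    m <- match(ids, layout$id)
    xy <- tibble(id = ids, x = as.numeric(layout$x[m]), y = as.numeric(layout$y[m]))
  } else if (all(c("x", "y") %in% names(network$nodes)) &&
             !anyNA(network$nodes$x) && !anyNA(network$nodes$y)) {
    xy <- tibble(id = ids, x = as.numeric(network$nodes$x),
                 y = as.numeric(network$nodes$y))
  } else if (auto_layout) {
    g <- igraph::graph_from_data_frame(
      network$edges[, c("source", "target")], directed = FALSE,
      vertices = data.frame(name = ids))
    coords <- withr::with_seed(as.integer(seed),
                               igraph::layout_with_fr(g))
    xy <- tibble(id = ids, x = coords[, 1], y = coords[, 2])
  } else {
    ov_abort("node positions missing and auto_layout is disabled",
             "layout_error")
  }
  # scale into the canvas, leaving room for glyph rings and labels
  margin <- node_radius * 3 + 40
  rescale <- function(v, lo, hi) {
    if (max(v) == min(v)) return(rep((lo + hi) / 2, length(v)))
    lo + (v - min(v)) / (max(v) - min(v)) * (hi - lo)
  }
  xy$x <- rescale(xy$x, margin, width - margin)
  xy$y <- rescale(xy$y, margin, height - margin)
  xy
}

# angle in degrees, 0 = 3 o'clock, increasing clockwise; SVG y axis points
# down, so the screen position is (cx + r cos, cy + r sin)
ov_arc_point <- function(cx, cy, r, deg) {
  rad <- deg * pi / 180
  c(cx + r * cos(rad), cy + r * sin(rad))
}

# arc command(s) from angle a to b (clockwise); spans >= 180 are split so
# the large-arc flag is never needed and full circles render correctly
ov_arc_path <- function(cx, cy, r, a, b, fmt) {
  span <- b - a
  n_seg <- max(1L, ceiling(span / 180 - 1e-9))
  cuts <- a + span * seq_len(n_seg) / n_seg
  segs <- vapply(cuts, function(ang) {
    p <- ov_arc_point(cx, cy, r, ang)
    sprintf("A %s %s 0 0 1 %s %s", fmt(r), fmt(r), fmt(p[1]), fmt(p[2]))
  }, character(1))
  paste(segs, collapse = " ")
}

ov_arc_path_rev <- function(cx, cy, r, b, a, fmt) {
  span <- b - a
  n_seg <- max(1L, ceiling(span / 180 - 1e-9))
  cuts <- b - span * seq_len(n_seg) / n_seg
  segs <- vapply(cuts, function(ang) {
    p <- ov_arc_point(cx, cy, r, ang)
    sprintf("A %s %s 0 0 0 %s %s", fmt(r), fmt(r), fmt(p[1]), fmt(p[2]))
  }, character(1))
  paste(segs, collapse = " ")
}

ov_svg_chart <- function(chart, cx, cy, node_radius, fmt, esc) {
  out <- character()
  emit <- function(...) out[[length(out) + 1L]] <<- paste0(...)
  ring_width <- 9
  ring_gap <- 3
  emit(sprintf('<g class="chart chart-%s" data-node="%s">', chart$style,
               esc(chart$node)))
  n_rings <- length(chart$rings)
  outer_r <- if (chart$style == "pie") node_radius
             else node_radius + ring_gap + n_rings * ring_width
  for (r in seq_len(n_rings)) {
    ring <- chart$rings[[r]]
    if (chart$style == "pie") {
      for (s in seq_len(nrow(ring))) {
        p0 <- ov_arc_point(cx, cy, node_radius, ring$start[s])
        d <- sprintf("M %s %s L %s %s %s Z", fmt(cx), fmt(cy),
                     fmt(p0[1]), fmt(p0[2]),
                     ov_arc_path(cx, cy, node_radius, ring$start[s],
                                 ring$end[s], fmt))
        emit(sprintf('<path class="slice" d="%s" fill="%s" stroke="#FFFFFF" stroke-width="0.5"/>',
                     d, ring$color[s]))
      }
    } else {
      r_in <- node_radius + ring_gap + (r - 1) * ring_width
      r_out <- r_in + ring_width
      for (s in seq_len(nrow(ring))) {
        pA <- ov_arc_point(cx, cy, r_out, ring$start[s])
        pD <- ov_arc_point(cx, cy, r_in, ring$end[s])
        d <- sprintf("M %s %s %s L %s %s %s Z",
                     fmt(pA[1]), fmt(pA[2]),
                     ov_arc_path(cx, cy, r_out, ring$start[s], ring$end[s], fmt),
                     fmt(pD[1]), fmt(pD[2]),
                     ov_arc_path_rev(cx, cy, r_in, ring$end[s], ring$start[s], fmt))
        emit(sprintf('<path class="slice" d="%s" fill="%s" stroke="#FFFFFF" stroke-width="0.5"/>',
                     d, ring$color[s]))
      }
    }
  }
  # labels once per slice of the outermost ring, at the slice mid-angle
  outer <- chart$rings[[n_rings]]
  lab_size <- chart$label_size %||% 11
  for (s in seq_len(nrow(outer))) {
    if (is.na(outer$label[s])) next
    mid <- (outer$start[s] + outer$end[s]) / 2
    p <- ov_arc_point(cx, cy, outer_r + 4 + lab_size / 2, mid)
    emit(sprintf(
      '<text class="slice-label" x="%s" y="%s" font-size="%s" text-anchor="middle" font-family="Helvetica">%s</text>',
      fmt(p[1]), fmt(p[2]), fmt(lab_size), esc(outer$label[s])))
  }
  emit("</g>")
  paste(out, collapse = "\n")
}

ov_svg_legend <- function(legend, width, height, fmt, esc) {
  sw <- 14          # swatch edge
  pad <- 6
  line_h <- legend$font_size + 8
  grad_w <- 120
  block_w <- 170
  n_lines <- 0
  for (el in legend$elements) {
    n_lines <- n_lines + switch(el$type,
      text = 1, swatch = 1, gradient = 2.6,
      ring_list = length(el$columns))
  }
  block_h <- pad * 2 + n_lines * line_h
  xy <- switch(legend$position,
    EAST_TOP = c(width - block_w - 10, 10),
    EAST = c(width - block_w - 10, (height - block_h) / 2),
    EAST_BOTTOM = c(width - block_w - 10, height - block_h - 10),
    WEST_TOP = c(10, 10),
    WEST = c(10, (height - block_h) / 2),
    WEST_BOTTOM = c(10, height - block_h - 10),
    NORTH = c((width - block_w) / 2, 10),
    SOUTH = c((width - block_w) / 2, height - block_h - 10))
  x <- xy[1] + pad
  y <- xy[2] + pad
  out <- character()
  emit <- function(...) out[[length(out) + 1L]] <<- paste0(...)
  emit(sprintf('<g class="legend" id="%s" font-family="%s">',
               esc(legend$group_name), esc(legend$font)))
  grad_id <- 0L
  for (el in legend$elements) {
    if (el$type == "text") {
      weight <- if (identical(el$role, "title")) ' font-weight="bold"' else ''
      emit(sprintf(
        '<text class="legend-%s" x="%s" y="%s" font-size="%s"%s>%s</text>',
        el$role, fmt(x), fmt(y + legend$font_size), fmt(legend$font_size),
        weight, esc(el$text)))
      y <- y + line_h
    } else if (el$type == "swatch") {
      emit(sprintf(
        '<rect class="legend-swatch" x="%s" y="%s" width="%s" height="%s" fill="%s" stroke="#555555"/>',
        fmt(x), fmt(y + (line_h - sw) / 2), fmt(sw), fmt(sw), el$color))
      emit(sprintf(
        '<text class="legend-label" x="%s" y="%s" font-size="%s">%s</text>',
        fmt(x + sw + 6), fmt(y + legend$font_size), fmt(legend$font_size),
        esc(el$label)))
      y <- y + line_h
    } else if (el$type == "gradient") {
      grad_id <- grad_id + 1L
      gid <- sprintf("%s-grad%d", legend$group_name, grad_id)
      emit(sprintf(paste0(
        '<linearGradient id="%s" x1="0" y1="0" x2="1" y2="0">',
        '<stop offset="0" stop-color="%s"/>',
        '<stop offset="0.5" stop-color="%s"/>',
        '<stop offset="1" stop-color="%s"/></linearGradient>'),
        esc(gid), el$min_color, el$mid_color, el$max_color))
      emit(sprintf(
        '<rect class="legend-gradient" x="%s" y="%s" width="%s" height="%s" fill="url(#%s)" stroke="#555555"/>',
        fmt(x), fmt(y + 2), fmt(grad_w), fmt(sw), esc(gid)))
      ty <- y + sw + legend$font_size + 4
      ticks <- c(el$min_value, el$mid_value, el$max_value)
      tx <- c(x, x + grad_w / 2, x + grad_w)
      anchors <- c("start", "middle", "end")
      for (i in 1:3) {
        emit(sprintf(
          '<text class="legend-tick" x="%s" y="%s" font-size="%s" text-anchor="%s">%s</text>',
          fmt(tx[i]), fmt(ty), fmt(legend$font_size * 0.9), anchors[i],
          esc(ov_fmt_tick(ticks[i]))))
      }
      y <- y + 2.6 * line_h
    } else if (el$type == "ring_list") {
      for (i in seq_along(el$columns)) {
        emit(sprintf(
          '<text class="legend-ring" x="%s" y="%s" font-size="%s">%d. %s%s</text>',
          fmt(x + 4), fmt(y + legend$font_size), fmt(legend$font_size * 0.9),
          i, esc(el$columns[i]), if (i == 1) " (innermost)" else ""))
        y <- y + line_h
      }
    }
  }
  emit("</g>")
  paste(out, collapse = "\n")
}
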