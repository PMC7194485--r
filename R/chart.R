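#' Visualization configuration for pie and donut glyphs
#'
#' A pie draws slices inside the node from a single value column: one slice
#' per connected row. A donut draws concentric rings around the node; with
#' the default `"ring_is_column"` there is one ring per value column (the
#' first listed column innermost) and one slice per connected row, while
#' `"ring_is_row"` transposes this (one ring per row, one slice per column).
#'
#' @param style `"pie"` or `"donut"`.
#' @param value_columns Table columns holding the values (exactly one for a
#'   pie; order fixes donut ring order, first innermost).
#' @param mapping An [ov_continuous_mapping()] or [ov_discrete_mapping()].
#' @param label_column Optional table column used as slice labels.
#' @param filtered_only Use only currently visible connected rows.
#' @param ring_mode `"ring_is_column"` (default) or `"ring_is_row"`; donuts
#'   only.
#' @param arc_start First slice boundary in degrees; 0 is the 3 o'clock
#'   position, angles increase clockwise.
#' @param label_size Label font size in points, or `NULL` for the renderer
#'   default.
#' @param na_color Fill for slices with missing values.
#' @return An `ov_viz_config`.
#' @export
ov_viz_config <- function(style, value_columns, mapping, label_column = NULL,
                          filtered_only = FALSE,
                          ring_mode = c("ring_is_column", "ring_is_row"),
                          arc_start = 0, label_size = NULL,
                          na_color = "#CCCCCC") {
  style <- match.arg(style, c("pie", "donut"))
  ring_mode <- match.arg(ring_mode)
  if (style == "pie" && length(value_columns) != 1L) {
    ov_abort("a pie visualization takes exactly one value column", "input_error")
  }
  if (length(value_columns) < 1L) {
    ov_abort("at least one value column is required", "input_error")
  }
  stopifnot(inherits(mapping, "ov_mapping"))
  structure(
    list(style = style, value_columns = as.character(value_columns),
         label_column = label_column, mapping = mapping,
         filtered_only = isTRUE(filtered_only), ring_mode = ring_mode,
         arc_start = as.numeric(arc_start),
         label_size = if (is.null(label_size)) NULL else as.numeric(label_size),
         na_color = ov_check_hex(na_color)),
    class = "ov_viz_config"
  )
}

# equal angular widths; the final slice closes the ring exactly at
# arc_start + 360 so per-ring spans always sum to 360 by telescoping
ov_slice_angles <- function(k, arc_start) {
  i <- seq_len(k)
  tibble(start = arc_start + 360 * (i - 1) / k,
         end = arc_start + 360 * i / k)
}

ov_check_viz_columns <- function(config, table) {
  needed <- c(config$value_columns, config$label_column)
  missing_cols <- setdiff(needed, names(table$data))
  if (length(missing_cols) > 0) {
    ov_abort(sprintf("column(s) not in table '%s': %s", table$name,
                     paste0("'", missing_cols, "'", collapse = ", ")),
             "schema_error")
  }
  invisible(TRUE)
}

ov_connected_rows <- function(node_id, connection, config, table) {
  rows <- connection$rows_per_node[[node_id]]
  if (is.null(rows)) {
    ov_abort(sprintf("node '%s' not in network '%s'", node_id,
                     connection$network$name), "schema_error")
  }
  if (config$filtered_only) rows <- rows[rows %in% table$visible]
  rows
}

ov_row_labels <- function(rows, config, table) {
  if (is.null(config$label_column)) return(rep(NA_character_, length(rows)))
  ov_render_text(table$data[[config$label_column]][rows])
}

ov_new_chart <- function(node_id, style, rings, config) {
  structure(
    list(node = node_id, style = style, arc_start = config$arc_start,
         label_size = config$label_size, rings = rings),
    class = "ov_chart"
  )
}

#' @export
print.ov_chart <- function(x, ...) {
  cat(sprintf("<ov_chart> %s for node '%s': %d ring(s) of %s slice(s)\n",
              x$style, x$node, length(x$rings),
              paste(vapply(x$rings, nrow, integer(1)), collapse = "/")))
  invisible(x)
}

#' Build the pie glyph of one node
#'
#' One ring of one slice per connected row (in table row order; visible rows
#' only when the configuration says `filtered_only`). Slices partition the
#' circle into equal angles starting at `arc_start`. Nodes with no connected
#' rows get no chart (`NULL`).
#'
#' @param node_id Node identifier.
#' @param connection An `ov_connection` from [ov_connect()].
#' @param config An [ov_viz_config()] with `style = "pie"`.
#' @param table Table to read cells from; defaults to the connection's
#'   table — pass the current table when it was re-filtered after
#'   connecting.
#' @return An `ov_chart` or `NULL`.
#' @export
ov_build_pie <- function(node_id, connection, config,
                         table = connection$table) {
  stopifnot(inherits(connection, "ov_connection"),
            inherits(config, "ov_viz_config"))
  if (config$style != "pie") {
    ov_abort("config style must be 'pie'", "input_error")
  }
  ov_check_viz_columns(config, table)
  rows <- ov_connected_rows(node_id, connection, config, table)
  k <- length(rows)
  if (k == 0L) return(NULL)
  cells <- table$data[[config$value_columns[1]]][rows]
  ring <- ov_slice_angles(k, config$arc_start)
  ring$color <- ov_map_colors(cells, config$mapping, config$na_color)
  ring$label <- ov_row_labels(rows, config, table)
  ring$value <- ov_render_text(cells)
  ov_new_chart(node_id, "pie", list(ring), config)
}

#' Build the donut glyph of one node
#'
#' With `ring_mode = "ring_is_column"` (the default), one ring per value
#' column — the first listed column is the innermost ring — and one slice
#' per connected row. With `"ring_is_row"`, one ring per connected row and
#' one slice per value column (the transpose). Slice angles are equal within
#' each ring; a missing cell keeps its angular span and takes the
#' missing-value color so rings stay aligned.
#'
#' @inheritParams ov_build_pie
#' @param config An [ov_viz_config()] with `style = "donut"`.
#' @return An `ov_chart` or `NULL` when the node has no connected rows.
#' @export
ov_build_donut <- function(node_id, connection, config,
                           table = connection$table) {
  stopifnot(inherits(connection, "ov_connection"),
            inherits(config, "ov_viz_config"))
  if (config$style != "donut") {
    ov_abort("config style must be 'donut'", "input_error")
  }
  ov_check_viz_columns(config, table)
  rows <- ov_connected_rows(node_id, connection, config, table)
  if (length(rows) == 0L) return(NULL)
  labels <- ov_row_labels(rows, config, table)
  if (config$ring_mode == "ring_is_column") {
    rings <- purrr::map(config$value_columns, function(colname) {
      cells <- table$data[[colname]][rows]
      ring <- ov_slice_angles(length(rows), config$arc_start)
      ring$color <- ov_map_colors(cells, config$mapping, config$na_color)
      ring$label <- labels
      ring$value <- ov_render_text(cells)
      ring
    })
  } else {
    rings <- purrr::map(seq_along(rows), function(i) {
      cells <- purrr::map(config$value_columns,
                          function(colname) table$data[[colname]][rows[i]])
      ring <- ov_slice_angles(length(config$value_columns), config$arc_start)
      ring$color <- vapply(cells, function(v)
        ov_map_colors(v, config$mapping, config$na_color), character(1))
      ring$label <- rep(labels[i], length(cells))
      ring$value <- vapply(cells, ov_render_text, character(1))
      ring
    })
  }
  ov_new_chart(node_id, "donut", rings, config)
}

#' Build glyphs for every node of a connection
#'
#' @param connection An `ov_connection`.
#' @param config An [ov_viz_config()].
#' @param table Table to read cells from (see [ov_build_pie()]).
#' @return Named list of `ov_chart` objects (nodes without connected rows are
#'   omitted).
#' @export
ov_build_charts <- function(connection, config, table = connection$table) {
  builder <- if (config$style == "pie") ov_build_pie else ov_build_donut
  charts <- purrr::map(connection$network$nodes$id, builder,
                       connection = connection, config = config, table = table)
  names(charts) <- connection$network$nodes$id
  purrr::compact(charts)
}

#' Write chart strings and value columns into the node table
#'
#' For each charted node, one namespaced node-table column stores the chart
#' description string and one column per value list stores the plotted
#' values — one list for a pie, one per ring for a donut. Under a continuous
#' mapping the emitted values are centered with [ov_center_transform()]
#' (only these copies are shifted; the source table is untouched). The
#' configuration itself is recorded at network level. Re-applying a
#' visualization overwrites its columns; it never duplicates them.
#'
#' @param connection An `ov_connection`.
#' @param config The [ov_viz_config()] the charts were built with.
#' @param charts Named list of `ov_chart` objects from [ov_build_charts()].
#' @return The updated `ov_connection` (network columns rewritten, config
#'   stored under `network$viz[[style]]`, charts under
#'   `connection$charts[[style]]`).
#' @export
ov_emit_chart_columns <- function(connection, config, charts) {
  stopifnot(inherits(connection, "ov_connection"),
            inherits(config, "ov_viz_config"))
  nodes <- connection$network$nodes
  prefix <- ov_ns_col(config$style)
  nodes <- nodes[, !startsWith(names(nodes), prefix), drop = FALSE]
  idx <- match(nodes$id, names(charts))
  nodes[[paste0(prefix, " chart")]] <- ifelse(
    is.na(idx), NA_character_,
    vapply(charts, ov_emit_chart_string, character(1))[idx])
  n_value_cols <- if (config$style == "pie") 1L else {
    max(c(0L, vapply(charts, function(ch) length(ch$rings), integer(1))))
  }
  continuous <- inherits(config$mapping, "ov_continuous_mapping")
  for (r in seq_len(n_value_cols)) {
    colname <- if (config$style == "pie") paste0(prefix, " values")
               else sprintf("%s ring%d values", prefix, r)
    nodes[[colname]] <- purrr::map(idx, function(i) {
      if (is.na(i) || length(charts[[i]]$rings) < r) return(NULL)
      vals <- charts[[i]]$rings[[r]]$value
      if (continuous) {
        ov_center_transform(suppressWarnings(as.numeric(vals)),
                            config$mapping)$values
      } else {
        vals
      }
    })
  }
  connection$network$nodes <- nodes
  connection$network$viz[[config$style]] <- config
  if (is.null(connection$charts)) connection$charts <- list()
  connection$charts[[config$style]] <- charts
  connection
}

#' @rdname ov_emit_chart_columns
#' @export
ov_apply_viz <- function(connection, config, table = connection$table) {
  charts <- ov_build_charts(connection, config, table = table)
  ov_emit_chart_columns(connection, config, charts)
}

# ---- chart description strings ------------------------------------------
#
# microformat (documented in the README), one line per chart:
#   style:<pie|donut>|node:<enc>|arcstart:<num>|labelsize:<num or empty>|
#   ring:<slice>,<slice>,...|ring:...
# slice := <#RRGGBB>;<value text, enc>;<label, enc; empty = no label>
# enc = percent-encoding of the reserved characters  | , ; : % and space.
# Slice angles are not stored: they are recomputed from arcstart and the
# slice count, which is exactly how they were derived at build time.

ov_enc <- function(x) {
  vapply(x, function(s) {
    if (is.na(s)) return("")
    s <- gsub("%", "%25", s, fixed = TRUE)
    for (ch in c("|", ",", ";", ":", " ")) {
      s <- gsub(ch, sprintf("%%%02X", utf8ToInt(ch)), s, fixed = TRUE)
    }
    s
  }, character(1), USE.NAMES = FALSE)
}

ov_dec <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return(NA_character_)
    utils::URLdecode(s)
  }, character(1), USE.NAMES = FALSE)
}

ov_num_fmt <- function(x) sprintf("%.17g", x)

#' Emit and parse chart description strings
#'
#' `ov_emit_chart_string()` serializes a chart to the declarative
#' one-line microformat stored in the node table (in the spirit of the
#' Cytoscape enhancedGraphics custom-chart strings: key:value fields with
#' arc start, label size, per-ring value/color/label lists).
#' `ov_parse_chart_string()` is its inverse; parsing an emitted string
#' reproduces the chart structurally.
#'
#' @param chart An `ov_chart`.
#' @param text A chart string.
#' @return The string, resp. the reconstructed `ov_chart`.
#' @export
ov_emit_chart_string <- function(chart) {
  stopifnot(inherits(chart, "ov_chart"))
  rings <- vapply(chart$rings, function(ring) {
    paste(sprintf("%s;%s;%s", ring$color, ov_enc(ring$value),
                  ov_enc(ring$label)),
          collapse = ",")
  }, character(1))
  paste(c(
    paste0("style:", chart$style),
    paste0("node:", ov_enc(chart$node)),
    paste0("arcstart:", ov_num_fmt(chart$arc_start)),
    paste0("labelsize:", if (is.null(chart$label_size)) ""
           else ov_num_fmt(chart$label_size)),
    paste0("ring:", rings)
  ), collapse = "|")
}

#' @rdname ov_emit_chart_string
#' @export
ov_parse_chart_string <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(text)) {
    ov_abort("chart string must be a non-empty string", "parse_error")
  }
  fields <- strsplit(text, "|", fixed = TRUE)[[1]]
  keys <- sub(":.*$", "", fields)
  vals <- sub("^[^:]*:", "", fields)
  need <- c("style", "node", "arcstart", "labelsize")
  if (!identical(keys[1:4], need) || !any(keys == "ring")) {
    ov_abort("malformed chart string: expected style|node|arcstart|labelsize|ring...",
             "parse_error")
  }
  style <- vals[1]
  if (!style %in% c("pie", "donut")) {
    ov_abort(sprintf("unknown chart style '%s'", style), "parse_error")
  }
  arc_start <- suppressWarnings(as.numeric(vals[3]))
  if (is.na(arc_start)) ov_abort("malformed arcstart", "parse_error")
  label_size <- if (!nzchar(vals[4])) NULL else {
    ls <- suppressWarnings(as.numeric(vals[4]))
    if (is.na(ls)) ov_abort("malformed labelsize", "parse_error")
    ls
  }
  rings <- purrr::map(vals[keys == "ring"], function(ringtxt) {
    slices <- strsplit(ringtxt, ",", fixed = TRUE)[[1]]
    parts <- strsplit(slices, ";", fixed = TRUE)
    bad <- vapply(parts, length, integer(1)) > 3L
    if (length(slices) == 0L || any(bad)) {
      ov_abort("malformed ring in chart string", "parse_error")
    }
    field <- function(p, i) if (length(p) >= i) p[[i]] else ""
    ring <- ov_slice_angles(length(slices), arc_start)
    ring$color <- ov_check_hex(vapply(parts, field, character(1), 1))
    ring$value <- ov_dec(vapply(parts, field, character(1), 2))
    ring$label <- ov_dec(vapply(parts, field, character(1), 3))
    ring[, c("start", "end", "color", "label", "value")]
  })
  structure(
    list(node = ov_dec(vals[2]), style = style, arc_start = arc_start,
         label_size = label_size, rings = rings),
    class = "ov_chart"
  )
}
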