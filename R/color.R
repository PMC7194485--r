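#' Bundled color palettes
#'
#' A small set of qualitative, diverging and sequential palettes stored as
#' literal hex lists (ColorBrewer-style identifiers plus a viridis ramp), so
#' no runtime palette dependency is needed.
#'
#' @param name Palette name; see `ov_palettes()` for the available set.
#' @return `ov_palette()` returns a character vector of `#RRGGBB` colors;
#'   `ov_palettes()` a named character vector mapping palette name to type.
#' @export
ov_palette <- function(name) {
  if (!name %in% names(OV_PALETTES)) {
    ov_abort(sprintf("unknown palette '%s' (available: %s)", name,
                     paste(names(OV_PALETTES), collapse = ", ")),
             "input_error")
  }
  OV_PALETTES[[name]]$colors
}

#' @rdname ov_palette
#' @export
ov_palettes <- function() {
  vapply(OV_PALETTES, function(p) p$type, character(1))
}

OV_PALETTES <- list(
  Paired = list(type = "qualitative", colors = c(
    "#A6CEE3", "#1F78B4", "#B2DF8A", "#33A02C", "#FB9A99", "#E31A1C",
    "#FDBF6F", "#FF7F00", "#CAB2D6", "#6A3D9A", "#FFFF99", "#B15928")),
  Set1 = list(type = "qualitative", colors = c(
    "#E41A1C", "#377EB8", "#4DAF4A", "#984EA3", "#FF7F00", "#FFFF33",
    "#A65628", "#F781BF", "#999999")),
  Dark2 = list(type = "qualitative", colors = c(
    "#1B9E77", "#D95F02", "#7570B3", "#E7298A", "#66A61E", "#E6AB02",
    "#A6761D", "#666666")),
  RdBu = list(type = "diverging", colors = c(
    "#0571B0", "#F7F7F7", "#CA0020")),
  BlueWhiteRed = list(type = "diverging", colors = c(
    "#0571B0", "#FFFFFF", "#CA0020")),
  Viridis = list(type = "sequential", colors = c(
    "#440154", "#46327E", "#365C8D", "#277F8E", "#1FA187", "#4AC16D",
    "#A0DA39", "#FDE725"))
)

ov_check_hex <- function(colors, what = "color") {
  bad <- !grepl("^#[0-9A-Fa-f]{6}$", colors)
  if (any(bad)) {
    ov_abort(sprintf("invalid %s(s): %s (expected #RRGGBB)", what,
                     paste0("'", colors[bad], "'", collapse = ", ")),
             "parse_error")
  }
  toupper(colors)
}

#' Continuous three-anchor color mapping
#'
#' Maps numbers to a diverging gradient through three anchors: the minimum,
#' middle and maximum values with their colors. Values below the minimum or
#' above the maximum clamp to the boundary colors. Defaults use a
#' blue-white-red diverging scheme suited to log-ratios centered on zero.
#'
#' @param min_value,mid_value,max_value Anchor values,
#'   `min_value <= mid_value <= max_value` (equal anchors are allowed; the
#'   empty segment maps to its shared anchor color).
#' @param min_color,mid_color,max_color Anchor colors as `#RRGGBB`.
#' @param palette Optional palette name recording provenance of the colors.
#' @return An `ov_continuous_mapping`.
#' @examples
#' m <- ov_continuous_mapping(-8, 0, 8)
#' ov_continuous_color(c(-10, 0, 4), m)
#' @export
ov_continuous_mapping <- function(min_value, mid_value, max_value,
                                  min_color = "#0571B0",
                                  mid_color = "#FFFFFF",
                                  max_color = "#CA0020",
                                  palette = NULL) {
  stopifnot(is.numeric(min_value), is.numeric(mid_value), is.numeric(max_value))
  if (!(min_value <= mid_value && mid_value <= max_value)) {
    ov_abort("anchor values must satisfy min <= mid <= max", "input_error")
  }
  cols <- ov_check_hex(c(min_color, mid_color, max_color))
  structure(
    list(min_value = as.numeric(min_value), mid_value = as.numeric(mid_value),
         max_value = as.numeric(max_value),
         min_color = cols[1], mid_color = cols[2], max_color = cols[3],
         palette = palette),
    class = c("ov_continuous_mapping", "ov_mapping")
  )
}

#' @export
print.ov_continuous_mapping <- function(x, ...) {
  cat(sprintf("<ov_continuous_mapping> %g (%s) .. %g (%s) .. %g (%s)\n",
              x$min_value, x$min_color, x$mid_value, x$mid_color,
              x$max_value, x$max_color))
  invisible(x)
}

#' Default symmetric bounds for a continuous mapping
#'
#' The maximum bound is the maximum of the absolute values of the data
#' minimum and maximum; the minimum bound is its opposite, so the scale is
#' centered on zero.
#'
#' @param values Numeric values (missing values ignored).
#' @return Numeric vector `c(min, mid, max)` = `c(-M, 0, M)`.
#' @examples
#' ov_default_continuous_bounds(c(-3, 5)) # -5 0 5
#' @export
ov_default_continuous_bounds <- function(values) {
  values <- values[!is.na(values) & is.finite(values)]
  if (length(values) == 0) {
    ov_abort("cannot derive bounds: no finite values", "bounds_error")
  }
  M <- max(abs(min(values)), abs(max(values)))
  if (M == 0) {
    ov_abort("all values are zero: specify bounds explicitly", "bounds_error")
  }
  c(min = -M, mid = 0, max = M)
}

#' Map values through a continuous mapping
#'
#' Values at or below the minimum take the minimum color, at or above the
#' maximum the maximum color, exactly at the middle the middle color;
#' otherwise colors are linearly interpolated per sRGB channel within the
#' lower or upper segment. Missing values take `na_color`.
#'
#' @param value Numeric vector.
#' @param mapping An [ov_continuous_mapping()].
#' @param na_color Color for missing values.
#' @return Character vector of `#RRGGBB` colors.
#' @export
ov_continuous_color <- function(value, mapping, na_color = "#CCCCCC") {
  stopifnot(inherits(mapping, "ov_continuous_mapping"))
  na_color <- ov_check_hex(na_color)
  vapply(as.numeric(value), function(v) {
    if (is.na(v)) return(na_color)
    if (v <= mapping$min_value) return(mapping$min_color)
    if (v >= mapping$max_value) return(mapping$max_color)
    if (v == mapping$mid_value) return(mapping$mid_color)
    if (v < mapping$mid_value) {
      ov_lerp_hex(mapping$min_color, mapping$mid_color,
                  (v - mapping$min_value) / (mapping$mid_value - mapping$min_value))
    } else {
      ov_lerp_hex(mapping$mid_color, mapping$max_color,
                  (v - mapping$mid_value) / (mapping$max_value - mapping$mid_value))
    }
  }, character(1))
}

ov_lerp_hex <- function(from, to, t) {
  a <- grDevices::col2rgb(from)[, 1]
  b <- grDevices::col2rgb(to)[, 1]
  ch <- round(a + t * (b - a))
  sprintf("#%02X%02X%02X", ch[1], ch[2], ch[3])
}

#' Center values around the middle anchor
#'
#' Shifts values and bounds by the middle value so that a downstream
#' renderer anchored at zero shows the intended colors: `v' = v - mid`,
#' `min' = min - mid`, `max' = max - mid`. Only the emitted copies are
#' shifted; source tables are never modified.
#'
#' @param values Numeric vector.
#' @param mapping An [ov_continuous_mapping()].
#' @return List with `values`, `min` and `max` (all shifted).
#' @export
ov_center_transform <- function(values, mapping) {
  stopifnot(inherits(mapping, "ov_continuous_mapping"))
  list(values = as.numeric(values) - mapping$mid_value,
       min = mapping$min_value - mapping$mid_value,
       max = mapping$max_value - mapping$mid_value)
}

#' Discrete value-to-color mapping
#'
#' @param values Distinct keys (rendered to text), in display order.
#' @param colors `#RRGGBB` colors, one per key.
#' @param palette Optional palette name recording provenance.
#' @return An `ov_discrete_mapping` with an ordered `assignments` tibble.
#' @export
ov_discrete_mapping <- function(values, colors, palette = NULL) {
  values <- ov_render_text(values)
  if (anyDuplicated(values)) {
    ov_abort(sprintf("duplicate mapping key(s): %s",
                     paste0("'", unique(values[duplicated(values)]), "'",
                            collapse = ", ")), "parse_error")
  }
  if (length(values) != length(colors)) {
    ov_abort("values and colors must have equal length", "input_error")
  }
  structure(
    list(assignments = tibble(value = values,
                              color = ov_check_hex(colors)),
         palette = palette),
    class = c("ov_discrete_mapping", "ov_mapping")
  )
}

#' @export
print.ov_discrete_mapping <- function(x, ...) {
  cat("<ov_discrete_mapping>",
      paste(x$assignments$value, x$assignments$color, sep = ":",
            collapse = ","), "\n")
  invisible(x)
}

#' Parse a discrete mapping string
#'
#' @param text Comma-separated `value:#RRGGBB` pairs, e.g.
#'   `"A:#1F78B4,B:#FF7F00,C:#E31A1C"`; order is preserved.
#' @return An [ov_discrete_mapping()].
#' @export
ov_parse_discrete_mapping <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    ov_abort("mapping text must be a non-empty string", "parse_error")
  }
  parts <- strsplit(text, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^\\s*(.*?)\\s*:\\s*(#[0-9A-Fa-f]{6})\\s*$", parts))
  bad <- vapply(m, length, integer(1)) != 3L
  if (any(bad)) {
    ov_abort(sprintf("malformed mapping entr%s: %s",
                     if (sum(bad) > 1) "ies" else "y",
                     paste0("'", parts[bad], "'", collapse = ", ")),
             "parse_error")
  }
  ov_discrete_mapping(vapply(m, `[[`, character(1), 2),
                      vapply(m, `[[`, character(1), 3))
}

#' Build a discrete mapping from data values and a qualitative palette
#'
#' Distinct values, in first-appearance order, are paired with the palette's
#' colors. When the palette has fewer colors than there are values, colors
#' cycle and a warning is raised.
#'
#' @param values Data values (missing values skipped).
#' @param palette Palette name (default `"Paired"`).
#' @return An [ov_discrete_mapping()].
#' @export
ov_auto_discrete_mapping <- function(values, palette = "Paired") {
  pal <- ov_palette(palette)
  keys <- unique(ov_render_text(values))
  keys <- keys[!is.na(keys)]
  if (length(keys) == 0) {
    return(ov_discrete_mapping(character(), character(), palette = palette))
  }
  if (length(keys) > length(pal)) {
    warn(sprintf(
      "palette '%s' has %d colors for %d values; colors will cycle",
      palette, length(pal), length(keys)))
  }
  ov_discrete_mapping(keys, rep_len(pal, length(keys)), palette = palette)
}

# one entry point for the chart builder: colors for cells under any mapping
ov_map_colors <- function(values, mapping, na_color = "#CCCCCC") {
  if (inherits(mapping, "ov_continuous_mapping")) {
    return(ov_continuous_color(values, mapping, na_color = na_color))
  }
  stopifnot(inherits(mapping, "ov_discrete_mapping"))
  na_color <- ov_check_hex(na_color)
  keys <- ov_render_text(values)
  idx <- match(keys, mapping$assignments$value)
  out <- mapping$assignments$color[idx]
  out[is.na(out)] <- na_color
  out
}
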