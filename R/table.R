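#' Long-format data tables with several rows per node
#'
#' An `ov_table` holds a typed, ordered data table in which several rows may
#' refer to the same node of a network (one row per modification site,
#' peptide, isoform, or condition). Filtering never deletes rows: rows that do
#' not satisfy the active filter are merely hidden, so the table keeps its
#' full row set alongside a set of visible row indices.
#'
#' Column types are restricted to the four glyph-relevant scalar types:
#' `"integer"`, `"float"`, `"boolean"` and `"string"` (stored as R integer,
#' double, logical and character vectors). Cells may be missing (`NA`).
#'
#' @param data A data frame or tibble. Columns of unsupported types are
#'   rendered to strings.
#' @param name Display name of the table.
#' @return An `ov_table` object: a list with fields `name`, `data` (tibble),
#'   `filter` (an `ov_filter` or `NULL`) and `visible` (integer row indices).
#' @examples
#' tab <- ov_table(data.frame(UniProt = c("P1", "P1", "Q2"), x = 1:3))
#' ov_n_rows(tab)
#' @export
ov_table <- function(data, name = "table") {
  stopifnot(is.data.frame(data))
  data <- as_tibble(data)
  data <- dplyr::mutate(data, dplyr::across(
    .cols = dplyr::everything(),
    .fns = ov_as_supported
  ))
  structure(
    list(
      name = as.character(name)[1],
      data = data,
      filter = NULL,
      visible = seq_len(nrow(data))
    ),
    class = "ov_table"
  )
}

# coerce an arbitrary vector to one of the four supported storage types
ov_as_supported <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.integer(x) || is.double(x) || is.logical(x) || is.character(x)) {
    return(x)
  }
  ov_render_text(x)
}

#' @export
print.ov_table <- function(x, ...) {
  cat(sprintf(
    "<ov_table> '%s': %d rows x %d columns (%d visible%s)\n",
    x$name, nrow(x$data), ncol(x$data), length(x$visible),
    if (is.null(x$filter)) "" else ", filter active"
  ))
  cat("  dtypes:", paste(names(x$data), ov_dtypes(x), sep = ":", collapse = " "), "\n")
  print(x$data, ...)
  invisible(x)
}

#' @export
dim.ov_table <- function(x) dim(x$data)

#' @export
as_tibble.ov_table <- function(x, ...) x$data

#' Number of rows, visible rows and column dtypes
#'
#' @param table An [ov_table()].
#' @return `ov_n_rows()` and `ov_n_visible()` return counts; `ov_dtypes()` a
#'   named character vector over `"integer"`, `"float"`, `"boolean"`,
#'   `"string"`; `ov_visible_data()` the tibble of currently visible rows.
#' @export
ov_n_rows <- function(table) nrow(table$data)

#' @rdname ov_n_rows
#' @export
ov_n_visible <- function(table) length(table$visible)

#' @rdname ov_n_rows
#' @export
ov_dtypes <- function(table) {
  vapply(table$data, ov_dtype_of, character(1))
}

#' @rdname ov_n_rows
#' @export
ov_visible_data <- function(table) table$data[table$visible, , drop = FALSE]

ov_dtype_of <- function(x) {
  if (is.integer(x)) "integer"
  else if (is.double(x)) "float"
  else if (is.logical(x)) "boolean"
  else "string"
}

ov_dtype_is_numeric <- function(dtype) dtype %in% c("integer", "float")

# canonical text rendering: integers (and whole doubles) without decimal
# point, booleans as true/false; used for key matching and serialization
ov_render_text <- function(x) {
  if (is.character(x)) return(x)
  if (is.logical(x)) return(ifelse(is.na(x), NA_character_, ifelse(x, "true", "false")))
  if (is.integer(x)) return(as.character(x))
  if (is.double(x)) {
    out <- vapply(x, function(v) {
      if (is.na(v)) return(NA_character_)
      if (is.finite(v) && v == trunc(v) && abs(v) < 1e15) {
        return(sprintf("%.0f", v))
      }
      # 17 significant digits: doubles survive a text round trip exactly
      sprintf("%.17g", v)
    }, character(1))
    return(out)
  }
  vapply(as.list(x), function(v) format(v), character(1))
}

#' Infer the type of a column from its raw text values
#'
#' Inspects at most `sample_limit` non-missing cells (mirroring inference from
#' the first hundred lines of a file) and returns the narrowest type, in the
#' order integer, float, boolean, string, that parses every inspected cell.
#' Cells beyond the sample can therefore fail the inferred type; such cells
#' become missing during coercion rather than aborting the import.
#'
#' @param cells Character vector of raw cell text.
#' @param sample_limit Maximum number of non-missing cells inspected
#'   (default 100).
#' @param na Strings treated as missing (default empty string and `"NA"`).
#' @return One of `"integer"`, `"float"`, `"boolean"`, `"string"`. Empty or
#'   all-missing input returns `"string"`.
#' @examples
#' infer_column_type(c("1", "2", "3"))      # "integer"
#' infer_column_type(c("0.01", "1e-3", "2")) # "float"
#' infer_column_type(c("P20700", "Q15149")) # "string"
#' @export
infer_column_type <- function(cells, sample_limit = 100L, na = c("", "NA")) {
  stopifnot(sample_limit >= 1L)
  cells <- as.character(cells)
  cells[cells %in% na] <- NA_character_
  sample <- utils::head(cells[!is.na(cells)], sample_limit)
  if (length(sample) == 0L) return("string")
  if (all(ov_parses_as(sample, "integer"))) return("integer")
  if (all(ov_parses_as(sample, "float"))) return("float")
  if (all(ov_parses_as(sample, "boolean"))) return("boolean")
  "string"
}

ov_parses_as <- function(txt, dtype) {
  switch(dtype,
    integer = grepl("^[+-]?[0-9]+$", txt) &
      !is.na(suppressWarnings(as.integer(txt))),
    float = !is.na(suppressWarnings(as.numeric(txt))),
    boolean = tolower(txt) %in% c("true", "false"),
    string = rep(TRUE, length(txt))
  )
}

# coerce raw text to a dtype; cells that fail become NA (rows are retained)
ov_coerce_cells <- function(txt, dtype, na = c("", "NA")) {
  txt <- as.character(txt)
  txt[txt %in% na] <- NA_character_
  switch(dtype,
    integer = {
      ok <- ov_parses_as(txt, "integer")
      out <- rep(NA_integer_, length(txt))
      out[which(ok)] <- as.integer(txt[which(ok)])
      out
    },
    float = suppressWarnings(as.numeric(txt)),
    boolean = {
      low <- tolower(txt)
      out <- rep(NA, length(txt))
      out[low %in% "true"] <- TRUE
      out[low %in% "false"] <- FALSE
      out
    },
    string = txt
  )
}

#' Import a delimited text file as an `ov_table`
#'
#' Reads a CSV/TSV-style file (UTF-8, first row a header by default), selects
#' columns, and types each column either from an explicit override or by
#' [infer_column_type()] on its first hundred non-missing cells. Cells that
#' fail coercion to the column's type become missing; their rows are kept.
#'
#' @param path Path to the file.
#' @param delimiter `"auto"` (sniffed among tab, comma, semicolon) or an
#'   explicit single character.
#' @param columns Character vector of column names to import (default: all).
#' @param dtypes Named character vector of dtype overrides, e.g.
#'   `c("Adj p-value" = "float")`.
#' @param na Strings treated as missing on input.
#' @param name Table display name; defaults to the file basename.
#' @param sample_limit Number of cells inspected by type inference.
#' @return An [ov_table()].
#' @export
ov_read_table <- function(path, delimiter = "auto", columns = NULL,
                          dtypes = NULL, na = c("", "NA"), name = NULL,
                          sample_limit = 100L) {
  if (!file.exists(path)) {
    ov_abort(sprintf("file not found: '%s'", path), "io_error")
  }
  delim <- if (identical(delimiter, "auto")) ov_sniff_delimiter(path) else delimiter
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = FALSE, progress = FALSE,
    show_col_types = FALSE, name_repair = "minimal"
  )
  if (!is.null(columns)) {
    missing_cols <- setdiff(columns, names(raw))
    if (length(missing_cols) > 0) {
      ov_abort(sprintf(
        "selected column(s) absent from header: %s",
        paste0("'", missing_cols, "'", collapse = ", ")
      ), "schema_error")
    }
    raw <- raw[, columns, drop = FALSE]
  }
  unknown_overrides <- setdiff(names(dtypes), names(raw))
  if (length(unknown_overrides) > 0) {
    ov_abort(sprintf(
      "dtype override(s) for unknown column(s): %s",
      paste0("'", unknown_overrides, "'", collapse = ", ")
    ), "schema_error")
  }
  typed <- purrr::imap(raw, function(cells, colname) {
    dtype <- if (colname %in% names(dtypes)) {
      match.arg(dtypes[[colname]], c("integer", "float", "boolean", "string"))
    } else {
      infer_column_type(cells, sample_limit = sample_limit, na = na)
    }
    ov_coerce_cells(cells, dtype, na = na)
  })
  data <- tibble::as_tibble(typed, .name_repair = "minimal")
  if (nrow(raw) == 0L) data <- data[0, , drop = FALSE]
  ov_table(data, name = name %||% basename(path))
}

ov_sniff_delimiter <- function(path) {
  header <- readLines(path, n = 1L, warn = FALSE)
  if (length(header) == 0L) return("\t")
  counts <- c(
    "\t" = stringr::str_count(header, stringr::fixed("\t")),
    "," = stringr::str_count(header, stringr::fixed(",")),
    ";" = stringr::str_count(header, stringr::fixed(";"))
  )
  names(counts)[which.max(counts)]
}

#' Serialize an `ov_table` to tab-separated text
#'
#' Missing cells are written as empty strings; booleans as `true`/`false`.
#' Re-importing the output with the same dtype assignments reproduces the
#' table (round-trip identity).
#'
#' @param table An [ov_table()].
#' @param path Output file path, or `NULL` to return the TSV text.
#' @return The TSV text, invisibly when written to `path`.
#' @export
ov_write_table <- function(table, path = NULL) {
  rendered <- purrr::map(table$data, function(col) {
    txt <- ov_render_text(col)
    txt[is.na(txt)] <- ""
    txt
  })
  rendered <- tibble::as_tibble(rendered, .name_repair = "minimal")
  txt <- readr::format_tsv(rendered, na = "")
  if (is.null(path)) return(txt)
  writeLines(sub("\n$", "", txt), path, sep = "\n")
  invisible(txt)
}

# dtype lattice join: integer < float; anything else mixes to string
ov_dtype_join <- function(a, b) {
  if (a == b) return(a)
  if (all(c(a, b) %in% c("integer", "float"))) return("float")
  "string"
}

#' Import node-attribute columns as a long-format table
#'
#' Melts selected columns of a network's node attribute table into a table
#' with exactly three columns: `node` (the node identifier), `source` (the
#' originating column name) and `values` (the cell value). One row is emitted
#' per (node, selected column) pair, nodes outermost, so the row count is
#' `n_nodes * length(columns)`. The `values` column takes the widest common
#' dtype of the selected columns (integer widens to float; otherwise string).
#' The result is automatically connected to the source network using the
#' `node` column as key; the connection is attached as attribute
#' `"connection"`.
#'
#' @param network An [ov_network()].
#' @param columns Node attribute column names to import (at least one).
#' @param name Table name; default derives from the network name.
#' @return An [ov_table()] with three columns and an attached connection.
#' @export
ov_from_node_table <- function(network, columns, name = NULL) {
  stopifnot(inherits(network, "ov_network"))
  if (length(columns) == 0L) {
    ov_abort("no columns selected: nothing to import", "schema_error")
  }
  attrs <- setdiff(names(network$nodes), c("x", "y"))
  missing_cols <- setdiff(columns, attrs)
  if (length(missing_cols) > 0) {
    ov_abort(sprintf(
      "unknown node attribute column(s): %s",
      paste0("'", missing_cols, "'", collapse = ", ")
    ), "schema_error")
  }
  dtypes <- vapply(network$nodes[columns], ov_dtype_of, character(1))
  joint <- Reduce(ov_dtype_join, dtypes)
  cells <- purrr::map(columns, function(colname) {
    col <- network$nodes[[colname]]
    if (joint == "string") ov_render_text(col)
    else if (joint == "float") as.double(col)
    else col
  })
  n <- nrow(network$nodes)
  k <- length(columns)
  values <- vector(switch(joint,
    integer = "integer", float = "double",
    boolean = "logical", string = "character"
  ), n * k)
  for (j in seq_len(k)) values[seq(j, by = k, length.out = n)] <- cells[[j]]
  out <- ov_table(
    tibble(
      node = rep(network$nodes$id, each = k),
      source = rep(columns, times = n),
      values = values
    ),
    name = name %||% paste0(network$name, " node data")
  )
  attr(out, "connection") <- ov_connect(out, network, "id", "node")
  out
}
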