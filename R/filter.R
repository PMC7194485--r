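#' Typed row filters with nested boolean connectives
#'
#' Filters are trees: a leaf is a criterion `(column, operator, operand)`, an
#' inner node combines one or more sub-filters with `AND` or `OR`. Applying a
#' filter hides rows; it never deletes them.
#'
#' Operators by column type:
#' * all types: `EQUALS`, `NOT_EQUALS`, `NULL`, `NOT_NULL`
#' * string also: `CONTAINS`, `NOT_CONTAINS`, `MATCHES`
#' * numeric (integer/float) also: `LOWER`, `LOWER_EQUALS`, `GREATER`,
#'   `GREATER_EQUALS`
#'
#' `NULL` is true iff the cell is missing; every other operator evaluates to
#' false on a missing cell (three-valued logic collapsed to false at the
#' leaf). `CONTAINS` is a case-sensitive substring test; `MATCHES` is a
#' full-string (anchored) regular-expression match. There is no `NOT`
#' connective; negation is expressed through the paired operators.
#'
#' @name ov_filter
NULL

OV_OPERATORS <- c(
  "EQUALS", "NOT_EQUALS", "NULL", "NOT_NULL",
  "CONTAINS", "NOT_CONTAINS", "MATCHES",
  "LOWER", "LOWER_EQUALS", "GREATER", "GREATER_EQUALS"
)
OV_OPS_STRING <- c("CONTAINS", "NOT_CONTAINS", "MATCHES")
OV_OPS_NUMERIC <- c("LOWER", "LOWER_EQUALS", "GREATER", "GREATER_EQUALS")
OV_OPS_NO_OPERAND <- c("NULL", "NOT_NULL")

#' Build a single filter criterion
#'
#' @param column Column name the criterion applies to.
#' @param operator One of the operators listed in [ov_filter].
#' @param operand Comparison value as text (absent for `NULL`/`NOT_NULL`);
#'   coerced to the column's type at evaluation time.
#' @return An `ov_filter` leaf.
#' @examples
#' ov_criterion("Adj p-value", "LOWER_EQUALS", "0.01")
#' @export
ov_criterion <- function(column, operator, operand = NULL) {
  operator <- match.arg(operator, OV_OPERATORS)
  if (operator %in% OV_OPS_NO_OPERAND && !is.null(operand)) {
    ov_abort(sprintf("operator %s takes no operand", operator), "parse_error")
  }
  if (!operator %in% OV_OPS_NO_OPERAND && is.null(operand)) {
    ov_abort(sprintf("operator %s requires an operand", operator), "parse_error")
  }
  structure(
    list(column = column, operator = operator,
         operand = if (is.null(operand)) NULL else as.character(operand)),
    class = c("ov_filter_leaf", "ov_filter")
  )
}

#' Combine filters with a boolean connective
#'
#' @param connective `"AND"` or `"OR"`.
#' @param ... One or more `ov_filter` objects.
#' @return An `ov_filter` node.
#' @export
ov_connective <- function(connective, ...) {
  connective <- match.arg(connective, c("AND", "OR"))
  children <- list(...)
  if (length(children) == 1L && is.list(children[[1]]) &&
      !inherits(children[[1]], "ov_filter")) {
    children <- children[[1]]
  }
  if (length(children) < 1L) {
    ov_abort(sprintf("%s needs at least one sub-filter", connective), "parse_error")
  }
  ok <- vapply(children, inherits, logical(1), what = "ov_filter")
  if (!all(ok)) ov_abort("all children must be ov_filter objects", "parse_error")
  structure(
    list(connective = connective, children = children),
    class = c("ov_filter_node", "ov_filter")
  )
}

#' Parse a filter string into a filter tree
#'
#' Grammar (whitespace around tokens is ignored; a column name runs to the
#' first comma and may contain spaces):
#' ```
#' expr := "(" column "," operator ["," operand] ")"
#'       | "(" ("AND"|"OR") "," expr {"," expr} ")"
#' ```
#'
#' @param text Filter string, e.g. `"(Adj p-value,LOWER_EQUALS,0.01)"`.
#' @return An `ov_filter`.
#' @examples
#' ov_parse_filter("(AND,(Cluster,EQUALS,A),(EOC vs FTE,GREATER,0))")
#' @export
ov_parse_filter <- function(text) {
  if (!is.character(text) || length(text) != 1L || !nzchar(trimws(text))) {
    ov_abort("filter text must be a non-empty string", "parse_error")
  }
  st <- list(s = text, n = nchar(text))
  res <- ov_parse_expr(st, ov_skip_ws(st, 1L))
  i <- ov_skip_ws(st, res$i)
  if (i <= st$n) {
    ov_abort(sprintf("unexpected trailing text at position %d: '%s'",
                     i, substr(st$s, i, st$n)), "parse_error")
  }
  res$expr
}

ov_skip_ws <- function(st, i) {
  while (i <= st$n && grepl("^\\s$", substr(st$s, i, i))) i <- i + 1L
  i
}

ov_expect_char <- function(st, i, ch) {
  if (i > st$n || substr(st$s, i, i) != ch) {
    found <- if (i > st$n) "end of input" else sprintf("'%s'", substr(st$s, i, i))
    ov_abort(sprintf("expected '%s' at position %d, found %s", ch, i, found),
             "parse_error")
  }
  i + 1L
}

# token up to the next top-level ',' or ')' (no nesting inside tokens)
ov_parse_token <- function(st, i) {
  j <- i
  while (j <= st$n && !substr(st$s, j, j) %in% c(",", ")")) {
    if (substr(st$s, j, j) == "(") {
      ov_abort(sprintf("unexpected '(' inside token at position %d", j), "parse_error")
    }
    j <- j + 1L
  }
  list(token = trimws(substr(st$s, i, j - 1L)), i = j)
}

ov_parse_expr <- function(st, i) {
  i <- ov_skip_ws(st, i)
  i <- ov_expect_char(st, i, "(")
  first <- ov_parse_token(st, ov_skip_ws(st, i))
  if (first$token %in% c("AND", "OR")) {
    children <- list()
    i <- first$i
    repeat {
      i <- ov_expect_char(st, ov_skip_ws(st, i), ",")
      sub <- ov_parse_expr(st, i)
      children <- c(children, list(sub$expr))
      i <- ov_skip_ws(st, sub$i)
      if (i > st$n || substr(st$s, i, i) != ",") break
    }
    i <- ov_expect_char(st, i, ")")
    return(list(expr = ov_connective(first$token, children), i = i))
  }
  column <- first$token
  i <- ov_expect_char(st, ov_skip_ws(st, first$i), ",")
  opt <- ov_parse_token(st, ov_skip_ws(st, i))
  if (!opt$token %in% OV_OPERATORS) {
    ov_abort(sprintf("unknown operator '%s' at position %d", opt$token, i),
             "parse_error")
  }
  i <- ov_skip_ws(st, opt$i)
  operand <- NULL
  if (i <= st$n && substr(st$s, i, i) == ",") {
    if (opt$token %in% OV_OPS_NO_OPERAND) {
      ov_abort(sprintf("operator %s takes no operand (position %d)", opt$token, i),
               "parse_error")
    }
    op_tok <- ov_parse_token(st, i + 1L)
    operand <- op_tok$token
    i <- op_tok$i
  }
  i <- ov_expect_char(st, ov_skip_ws(st, i), ")")
  list(expr = ov_criterion(column, opt$token, operand), i = i)
}

#' @export
format.ov_filter <- function(x, ...) {
  if (inherits(x, "ov_filter_leaf")) {
    if (is.null(x$operand)) {
      sprintf("(%s,%s)", x$column, x$operator)
    } else {
      sprintf("(%s,%s,%s)", x$column, x$operator, x$operand)
    }
  } else {
    sprintf("(%s,%s)", x$connective,
            paste(vapply(x$children, format, character(1)), collapse = ","))
  }
}

#' @export
print.ov_filter <- function(x, ...) {
  cat("<ov_filter>", format(x), "\n")
  invisible(x)
}

# check leaf columns exist and operators are admissible for their dtypes
ov_validate_filter <- function(expr, table) {
  if (inherits(expr, "ov_filter_node")) {
    purrr::walk(expr$children, ov_validate_filter, table = table)
    return(invisible(TRUE))
  }
  if (!expr$column %in% names(table$data)) {
    ov_abort(sprintf("filter column '%s' not found in table '%s'",
                     expr$column, table$name), "filter_error")
  }
  dtype <- ov_dtype_of(table$data[[expr$column]])
  bad_string <- expr$operator %in% OV_OPS_STRING && dtype != "string"
  bad_numeric <- expr$operator %in% OV_OPS_NUMERIC && !ov_dtype_is_numeric(dtype)
  if (bad_string || bad_numeric) {
    ov_abort(sprintf("operator %s not admissible for %s column '%s'",
                     expr$operator, dtype, expr$column), "filter_error")
  }
  invisible(TRUE)
}

# vectorized truth mask over all rows of the table
ov_filter_mask <- function(expr, table) {
  if (inherits(expr, "ov_filter_node")) {
    masks <- purrr::map(expr$children, ov_filter_mask, table = table)
    return(Reduce(if (expr$connective == "AND") `&` else `|`, masks))
  }
  cells <- table$data[[expr$column]]
  op <- expr$operator
  if (op == "NULL") return(is.na(cells))
  if (op == "NOT_NULL") return(!is.na(cells))
  dtype <- ov_dtype_of(cells)
  operand <- ov_coerce_operand(expr$operand, dtype, expr$column, op)
  res <- switch(op,
    EQUALS = if (dtype == "string") cells == operand else cells == operand,
    NOT_EQUALS = cells != operand,
    CONTAINS = stringr::str_detect(cells, stringr::fixed(operand)),
    NOT_CONTAINS = !stringr::str_detect(cells, stringr::fixed(operand)),
    MATCHES = grepl(paste0("^(?:", expr$operand, ")$"), cells, perl = TRUE),
    LOWER = cells < operand,
    LOWER_EQUALS = cells <= operand,
    GREATER = cells > operand,
    GREATER_EQUALS = cells >= operand
  )
  # every comparison against a missing cell is false
  res[is.na(res)] <- FALSE
  res & !is.na(cells)
}

ov_coerce_operand <- function(operand, dtype, column, op) {
  if (ov_dtype_is_numeric(dtype)) {
    val <- suppressWarnings(as.numeric(operand))
    if (is.na(val)) {
      ov_abort(sprintf(
        "operand '%s' of %s is not numeric (column '%s' is %s)",
        operand, op, column, dtype), "filter_error")
    }
    return(val)
  }
  if (dtype == "boolean") {
    low <- tolower(operand)
    if (!low %in% c("true", "false")) {
      ov_abort(sprintf(
        "operand '%s' of %s is not a boolean (column '%s')",
        operand, op, column), "filter_error")
    }
    return(identical(low, "true"))
  }
  operand
}

#' Evaluate a filter for one row
#'
#' @param expr An `ov_filter`.
#' @param table An [ov_table()].
#' @param row_index 1-based row position.
#' @return `TRUE` or `FALSE`.
#' @export
ov_evaluate <- function(expr, table, row_index) {
  stopifnot(inherits(expr, "ov_filter"), inherits(table, "ov_table"))
  stopifnot(row_index >= 1L, row_index <= ov_n_rows(table))
  ov_validate_filter(expr, table)
  ov_filter_mask(expr, table)[row_index]
}

#' Apply (or clear) a filter, hiding non-matching rows
#'
#' Sets the table's active filter and visible row set. Rows are only hidden,
#' never removed, and visible indices preserve the original row order. The
#' row counts before and after filtering are reported and stored in the
#' `"filter_report"` attribute of the result.
#'
#' @param table An [ov_table()].
#' @param expr An `ov_filter`, a filter string (parsed with
#'   [ov_parse_filter()]), or `NULL` to clear the filter.
#' @param quiet Suppress the before/after row-count message.
#' @return The updated `ov_table`.
#' @export
ov_apply_filter <- function(table, expr, quiet = FALSE) {
  stopifnot(inherits(table, "ov_table"))
  if (is.character(expr)) expr <- ov_parse_filter(expr)
  n_before <- ov_n_visible(table)
  if (is.null(expr)) {
    table$filter <- NULL
    table$visible <- seq_len(ov_n_rows(table))
  } else {
    stopifnot(inherits(expr, "ov_filter"))
    ov_validate_filter(expr, table)
    table$filter <- expr
    table$visible <- which(ov_filter_mask(expr, table))
  }
  n_after <- ov_n_visible(table)
  if (!quiet) {
    message(sprintf("rows: %d before filtering, %d after", n_before, n_after))
  }
  attr(table, "filter_report") <- c(n_before = n_before, n_after = n_after)
  table
}
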