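test_that("filter strings parse into criterion trees", {
  leaf <- ov_parse_filter("(Adj p-value,LOWER_EQUALS,0.01)")
  expect_s3_class(leaf, "ov_filter_leaf")
  expect_identical(leaf$column, "Adj p-value")
  expect_identical(leaf$operator, "LOWER_EQUALS")
  expect_identical(as.numeric(leaf$operand), 0.01)

  node <- ov_parse_filter("(AND,(Cluster,EQUALS,A),(EOC vs FTE,GREATER,0))")
  expect_s3_class(node, "ov_filter_node")
  expect_identical(node$connective, "AND")
  expect_length(node$children, 2L)
  expect_identical(node$children[[2]]$column, "EOC vs FTE")

  # whitespace around tokens is ignored; formatting round-trips
  spaced <- ov_parse_filter(" ( OR , (num, NULL ) , (str,CONTAINS,a) ) ")
  expect_identical(format(spaced), "(OR,(num,NULL),(str,CONTAINS,a))")
  expect_identical(format(ov_parse_filter(format(node))), format(node))
})

test_that("malformed filter strings fail with positioned parse errors", {
  expect_error(ov_parse_filter("(Cluster,NULL,x)"), regexp = "operand",
               class = "ovglyph_parse_error")
  expect_error(ov_parse_filter("(Cluster,EQUALS,A"), regexp = "position",
               class = "ovglyph_parse_error")
  expect_error(ov_parse_filter("(Cluster,FROBNICATE,A)"),
               regexp = "unknown operator", class = "ovglyph_parse_error")
  expect_error(ov_parse_filter("(AND)"), class = "ovglyph_parse_error")
  expect_error(ov_parse_filter("(a,EQUALS,b))"), regexp = "trailing",
               class = "ovglyph_parse_error")
  expect_error(ov_parse_filter(""), class = "ovglyph_parse_error")
})

test_that("leaf semantics: boundaries, missing cells, regex anchoring", {
  tab <- ov_table(tibble::tibble(
    p = c(0.01, 0.0100001, NA, 0.002),
    s = c("alpha", "ALPHA", NA, "al"),
    b = c(TRUE, FALSE, NA, TRUE)))
  le <- ov_criterion("p", "LOWER_EQUALS", "0.01")
  expect_true(ov_evaluate(le, tab, 1))    # boundary included
  expect_false(ov_evaluate(le, tab, 2))
  expect_false(ov_evaluate(le, tab, 3))   # missing compares false
  expect_true(ov_evaluate(le, tab, 4))
  # NULL/NOT_NULL are the only detectors of missing cells
  expect_true(ov_evaluate(ov_criterion("p", "NULL"), tab, 3))
  expect_false(ov_evaluate(ov_criterion("p", "NOT_NULL"), tab, 3))
  expect_false(ov_evaluate(ov_criterion("s", "NOT_EQUALS", "x"), tab, 3))
  expect_false(ov_evaluate(ov_criterion("s", "NOT_CONTAINS", "x"), tab, 3))
  # CONTAINS is case-sensitive; MATCHES matches the full string
  expect_true(ov_evaluate(ov_criterion("s", "CONTAINS", "al"), tab, 1))
  expect_false(ov_evaluate(ov_criterion("s", "CONTAINS", "al"), tab, 2))
  expect_true(ov_evaluate(ov_criterion("s", "MATCHES", "al.*"), tab, 1))
  expect_false(ov_evaluate(ov_criterion("s", "MATCHES", "al"), tab, 1))
  expect_true(ov_evaluate(ov_criterion("s", "MATCHES", "al"), tab, 4))
  # booleans accept EQUALS with true/false operands
  expect_true(ov_evaluate(ov_criterion("b", "EQUALS", "true"), tab, 1))
  expect_false(ov_evaluate(ov_criterion("b", "EQUALS", "true"), tab, 2))
})

test_that("operator admissibility is typed per column", {
  tab <- ov_table(tibble::tibble(s = "a", x = 1))
  expect_error(ov_apply_filter(tab, ov_criterion("s", "LOWER", "1"), quiet = TRUE),
               regexp = "LOWER.*string", class = "ovglyph_filter_error")
  expect_error(ov_apply_filter(tab, ov_criterion("x", "CONTAINS", "1"), quiet = TRUE),
               regexp = "CONTAINS", class = "ovglyph_filter_error")
  expect_error(ov_apply_filter(tab, ov_criterion("absent", "NULL"), quiet = TRUE),
               class = "ovglyph_filter_error")
})

test_that("filtering hides rows, preserves order, clears and re-applies", {
  tab <- ov_table(tibble::tibble(x = c(3, 1, 4, 1, 5, NA)))
  f <- ov_criterion("x", "GREATER_EQUALS", "3")
  tab <- ov_apply_filter(tab, f, quiet = TRUE)
  expect_identical(tab$visible, c(1L, 3L, 5L))      # original order kept
  expect_identical(ov_n_rows(tab), 6L)              # nothing deleted
  expect_identical(attr(tab, "filter_report"),
                   c(n_before = 6L, n_after = 3L))
  # idempotent
  again <- ov_apply_filter(tab, f, quiet = TRUE)
  expect_identical(again$visible, tab$visible)
  # tautology keeps everything visible except nothing
  taut <- ov_connective("OR", ov_criterion("x", "NULL"),
                        ov_criterion("x", "NOT_NULL"))
  expect_identical(ov_apply_filter(tab, taut, quiet = TRUE)$visible, 1:6)
  # clearing restores the identity visibility
  cleared <- ov_apply_filter(tab, NULL, quiet = TRUE)
  expect_identical(cleared$visible, 1:6)
  expect_null(cleared$filter)
  # the before/after report is printed for display
  expect_message(ov_apply_filter(cleared, f),
                 regexp = "6 before filtering, 3 after")
})

test_that("evaluation matches a brute-force recursive evaluator", {
  withr::with_seed(101, {
    for (rep in 1:40) {
      tab <- random_table(n = 12)
      expr <- random_filter(tab, depth = 3)
      got <- ov_apply_filter(tab, expr, quiet = TRUE)$visible
      want <- oracle_visible_rows(expr, tab$data)
      expect_identical(got, want, info = format(expr))
    }
  })
})

test_that("negation duality: hiding by a filter complements its negation", {
  neg_leaf <- function(leaf) {
    pairs <- c(EQUALS = "NOT_EQUALS", NOT_EQUALS = "EQUALS",
               "NULL" = "NOT_NULL", NOT_NULL = "NULL",
               CONTAINS = "NOT_CONTAINS", NOT_CONTAINS = "CONTAINS",
               LOWER = "GREATER_EQUALS", GREATER_EQUALS = "LOWER",
               GREATER = "LOWER_EQUALS", LOWER_EQUALS = "GREATER")
    ov_criterion(leaf$column, unname(pairs[leaf$operator]), leaf$operand)
  }
  negate <- function(expr) {
    if (inherits(expr, "ov_filter_leaf")) return(neg_leaf(expr))
    ov_connective(if (expr$connective == "AND") "OR" else "AND",
                  lapply(expr$children, negate))
  }
  # on complete rows the law is exact; missing cells break it only because
  # both a comparison and its pair are false on a missing cell
  withr::with_seed(33, {
    for (rep in 1:20) {
      tab <- random_table(n = 15, na_frac = 0)
      expr <- random_filter(tab, depth = 2)
      has_matches <- function(e) {
        if (inherits(e, "ov_filter_leaf")) e$operator == "MATCHES"
        else any(vapply(e$children, has_matches, logical(1)))
      }
      if (has_matches(expr)) next   # MATCHES has no operator negation pair
      vis <- ov_apply_filter(tab, expr, quiet = TRUE)$visible
      hid <- ov_apply_filter(tab, negate(expr), quiet = TRUE)$visible
      expect_identical(sort(c(vis, hid)), seq_len(ov_n_rows(tab)))
      expect_length(intersect(vis, hid), 0)
    }
  })
})
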