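# a small connected setup used across the chart tests
chart_setup <- function() {
  ex <- example_tables()
  conn <- ov_connect(ex$table, ex$network, "query term", "UniProt")
  dm <- ov_parse_discrete_mapping("A:#1F78B4,B:#FF7F00,C:#E31A1C")
  cm <- ov_continuous_mapping(-8, 0, 8)
  list(ex = ex, conn = conn, dm = dm, cm = cm)
}

test_that("pies slice the circle equally from the arc start, in row order", {
  st <- chart_setup()
  cfg <- ov_viz_config("pie", "Cluster", st$dm, label_column = "AA position")
  ch <- ov_build_pie("9606.n1", st$conn, cfg)
  expect_identical(ch$style, "pie")
  expect_length(ch$rings, 1L)
  ring <- ch$rings[[1]]
  expect_identical(ring$start, c(0, 180))
  expect_identical(ring$end, c(180, 360))
  expect_identical(ring$color, c("#1F78B4", "#1F78B4"))  # both rows cluster A
  expect_identical(ring$label, c("23", "393"))           # table row order
  # an arc start shifts every boundary
  cfg45 <- ov_viz_config("pie", "Cluster", st$dm, arc_start = 45)
  ch45 <- ov_build_pie("9606.n1", st$conn, cfg45)
  expect_identical(ch45$rings[[1]]$start, c(45, 225))
  # three rows partition into 120-degree slices
  tab3 <- ov_table(tibble::tibble(k = c("p", "p", "p"), v = c("A", "B", "C")))
  net3 <- ov_network(tibble::tibble(id = "n", key = "p"))
  conn3 <- ov_connect(tab3, net3, "key", "k")
  ch3 <- ov_build_pie("n", conn3, ov_viz_config("pie", "v", st$dm))
  expect_equal(ch3$rings[[1]]$start, c(0, 120, 240))
  expect_equal(ch3$rings[[1]]$end, c(120, 240, 360))
  # a node with no connected rows draws nothing
  expect_null(ov_build_pie("9606.n4", st$conn, cfg))
})

test_that("pies honor the active filter only when asked", {
  st <- chart_setup()
  filtered <- ov_apply_filter(st$ex$table, "(Adj p-value,LOWER_EQUALS,0.001)",
                              quiet = TRUE)
  cfg_all <- ov_viz_config("pie", "Cluster", st$dm, filtered_only = FALSE)
  cfg_vis <- ov_viz_config("pie", "Cluster", st$dm, filtered_only = TRUE)
  expect_identical(nrow(ov_build_pie("9606.n1", st$conn, cfg_all,
                                     table = filtered)$rings[[1]]), 2L)
  expect_identical(nrow(ov_build_pie("9606.n1", st$conn, cfg_vis,
                                     table = filtered)$rings[[1]]), 1L)
  expect_error(ov_build_pie("9606.n1", st$conn,
                            ov_viz_config("pie", "nope", st$dm)),
               class = "ovglyph_schema_error")
  expect_error(ov_viz_config("pie", c("a", "b"), st$dm),
               class = "ovglyph_input_error")
})

test_that("donut rings follow column order with the first column innermost", {
  st <- chart_setup()
  cfg <- ov_viz_config("donut", c("EOC vs FTE", "EOC vs OSE"), st$cm,
                       label_column = "AA position")
  ch <- ov_build_donut("9606.n1", st$conn, cfg)
  expect_length(ch$rings, 2L)            # one ring per value column
  expect_identical(nrow(ch$rings[[1]]), 2L)  # one slice per connected row
  # innermost ring carries the first listed column's cells
  expect_identical(ch$rings[[1]]$value,
                   ovglyph:::ov_render_text(st$ex$table$data[["EOC vs FTE"]][c(1, 3)]))
  expect_identical(ch$rings[[2]]$value,
                   ovglyph:::ov_render_text(st$ex$table$data[["EOC vs OSE"]][c(1, 3)]))
})

test_that("ring-is-row is the transpose of ring-is-column", {
  st <- chart_setup()
  cols <- c("EOC vs FTE", "EOC vs OSE")
  by_col <- ov_build_donut("9606.n1", st$conn,
                           ov_viz_config("donut", cols, st$cm,
                                         label_column = "AA position"))
  by_row <- ov_build_donut("9606.n1", st$conn,
                           ov_viz_config("donut", cols, st$cm,
                                         label_column = "AA position",
                                         ring_mode = "ring_is_row"))
  expect_length(by_row$rings, 2L)   # one ring per row now
  for (r in seq_along(by_col$rings)) {
    for (s in seq_len(nrow(by_col$rings[[r]]))) {
      for (field in c("value", "color", "label")) {
        expect_identical(by_col$rings[[r]][[field]][s],
                         by_row$rings[[s]][[field]][r])
      }
    }
  }
})

test_that("a one-column donut lays out exactly like the pie", {
  st <- chart_setup()
  pie <- ov_build_pie("9606.n1", st$conn,
                      ov_viz_config("pie", "Cluster", st$dm,
                                    label_column = "AA position"))
  donut <- ov_build_donut("9606.n1", st$conn,
                          ov_viz_config("donut", "Cluster", st$dm,
                                        label_column = "AA position"))
  expect_identical(donut$rings, pie$rings)
})

test_that("missing cells keep their angular span in the missing color", {
  tab <- ov_table(tibble::tibble(k = c("p", "p"), v = c(2.5, NA)))
  net <- ov_network(tibble::tibble(id = "n", key = "p"))
  conn <- ov_connect(tab, net, "key", "k")
  cm <- ov_continuous_mapping(-4, 0, 4)
  ch <- ov_build_donut("n", conn, ov_viz_config("donut", "v", cm))
  expect_identical(nrow(ch$rings[[1]]), 2L)
  expect_identical(ch$rings[[1]]$color[2], "#CCCCCC")
  expect_identical(ch$rings[[1]]$value[2], NA_character_)
})

test_that("per-ring angles telescope to exactly 360 degrees", {
  withr::with_seed(5, {
    for (rep in 1:60) {
      k <- sample(1:17, 1)
      arc <- stats::runif(1, 0, 359)
      ring <- ovglyph:::ov_slice_angles(k, arc)
      expect_identical(sum(ring$end - ring$start), 360)
      expect_identical(ring$start[1], arc)
      expect_identical(ring$end[k], arc + 360)
      if (k > 1) expect_identical(ring$start[-1], ring$end[-k])
    }
  })
})

test_that("chart columns are emitted per ring and overwrite cleanly", {
  st <- chart_setup()
  dcfg <- ov_viz_config("donut", c("EOC vs FTE", "EOC vs OSE"), st$cm)
  conn <- ov_apply_viz(st$conn, dcfg)
  ncols <- names(conn$network$nodes)
  expect_true("ov::donut chart" %in% ncols)
  expect_identical(sum(grepl("^ov::donut ring\\d+ values$", ncols)), 2L)
  # pie adds exactly one value column plus the chart string column
  pcfg <- ov_viz_config("pie", "Cluster", st$dm)
  conn <- ov_apply_viz(conn, pcfg)
  ncols <- names(conn$network$nodes)
  expect_true("ov::pie chart" %in% ncols)
  expect_identical(sum(ncols == "ov::pie values"), 1L)
  # continuous donut values are centered copies; the table is untouched
  m2 <- ov_continuous_mapping(-8, 2, 8)
  conn2 <- ov_apply_viz(st$conn, ov_viz_config("donut", "EOC vs FTE", m2))
  v <- conn2$network$nodes[["ov::donut ring1 values"]][[1]]
  expect_equal(v, st$ex$table$data[["EOC vs FTE"]][c(1, 3)] - 2)
  expect_identical(conn2$table$data, st$ex$table$data)
  # re-applying overwrites rather than duplicating namespace columns
  conn3 <- ov_apply_viz(conn, dcfg)
  expect_setequal(names(conn3$network$nodes), names(conn$network$nodes))
  expect_false(anyDuplicated(names(conn3$network$nodes)) > 0)
  # the configuration is recorded at network level
  expect_identical(conn3$network$viz$donut$value_columns,
                   c("EOC vs FTE", "EOC vs OSE"))
})

test_that("chart strings are deterministic and round-trip structurally", {
  st <- chart_setup()
  cfg <- ov_viz_config("donut", c("EOC vs FTE", "EOC vs OSE"), st$cm,
                       label_column = "AA position", label_size = 15)
  ch <- ov_build_donut("9606.n1", st$conn, cfg)
  s1 <- ov_emit_chart_string(ch)
  s2 <- ov_emit_chart_string(ov_build_donut("9606.n1", st$conn, cfg))
  expect_identical(s1, s2)   # byte-identical on identical inputs
  back <- ov_parse_chart_string(s1)
  expect_equal(unclass(back), unclass(ch))
  # random charts with reserved characters in labels and node ids
  withr::with_seed(19, {
    for (rep in 1:50) {
      chart <- random_chart()
      back <- ov_parse_chart_string(ov_emit_chart_string(chart))
      expect_equal(unclass(back), unclass(chart))
    }
  })
})

test_that("malformed chart strings are rejected", {
  expect_error(ov_parse_chart_string(""), class = "ovglyph_parse_error")
  expect_error(ov_parse_chart_string("style:pie|node:n"),
               class = "ovglyph_parse_error")
  expect_error(ov_parse_chart_string(
    "style:hex|node:n|arcstart:0|labelsize:|ring:#000000;;"),
    class = "ovglyph_parse_error")
  expect_error(ov_parse_chart_string(
    "style:pie|node:n|arcstart:zz|labelsize:|ring:#000000;;"),
    class = "ovglyph_parse_error")
})

test_that("chart tidiers expose slices and summaries", {
  st <- chart_setup()
  ch <- ov_build_donut("9606.n1", st$conn,
                       ov_viz_config("donut", c("EOC vs FTE", "EOC vs OSE"),
                                     st$cm))
  td <- tidy(ch)
  expect_identical(nrow(td), 4L)
  expect_identical(unique(td$ring), c(1L, 2L))
  gl <- glance(ch)
  expect_identical(gl$n_rings, 2L)
  expect_identical(gl$n_slices, 4L)
  p <- autoplot(ch)
  expect_s3_class(p, "ggplot")
})
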