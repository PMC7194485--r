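test_that("connecting on matching keys links every row of a node", {
  ex <- example_tables()
  conn <- ov_connect(ex$table, ex$network, "query term", "UniProt")
  # the P20700 node is keyed to exactly its two table rows, in table order
  expect_identical(conn$rows_per_node[["9606.n1"]], c(1L, 3L))
  expect_identical(conn$rows_per_node[["9606.n2"]], 2L)
  expect_identical(conn$rows_per_node[["9606.n4"]], integer(0))
  # the connected-row count lands in the namespaced node column
  expect_identical(conn$network$nodes[["ov::nrows"]], c(2L, 1L, 1L, 0L))
  expect_identical(conn$network$connected_to, "sites")
  # row data is untouched
  expect_identical(conn$table$data, ex$table$data)
})

test_that("a table with no matching keys still connects, vacuously", {
  tab <- ov_table(tibble::tibble(k = c("x", "y")), name = "t")
  net <- ov_network(tibble::tibble(id = "n", key = "z"))
  conn <- ov_connect(tab, net, "key", "k")
  expect_identical(conn$rows_per_node, list(n = integer(0)))
})

test_that("numeric keys match by canonical text rendering", {
  tab <- ov_table(tibble::tibble(k = c(1L, 2L, 1L)))
  net <- ov_network(tibble::tibble(id = c("a", "b"), key = c(1, 3)))
  conn <- ov_connect(tab, net, "key", "k")
  expect_identical(conn$rows_per_node, list(a = c(1L, 3L), b = integer(0)))
})

test_that("connected rows equal a nested-loop join on random keys", {
  withr::with_seed(55, {
    for (rep in 1:20) {
      keys <- sprintf("K%d", sample.int(8, sample(3:8, 1)))
      node_keys <- unique(keys)
      row_keys <- sample(c(sprintf("K%d", 1:10), NA), sample(5:25, 1),
                         replace = TRUE)
      tab <- ov_table(tibble::tibble(k = row_keys))
      net <- ov_network(tibble::tibble(id = paste0("n", seq_along(node_keys)),
                                       key = node_keys))
      conn <- ov_connect(tab, net, "key", "k")
      want <- oracle_join_rows(node_keys, row_keys)
      expect_identical(unname(conn$rows_per_node), want)
      # with unique node keys the total equals the rows whose key occurs
      expect_identical(sum(lengths(conn$rows_per_node)),
                       sum(!is.na(row_keys) & row_keys %in% node_keys))
    }
  })
})

test_that("connected-row counts ignore the active filter", {
  ex <- example_tables()
  conn_before <- ov_connect(ex$table, ex$network, "query term", "UniProt")
  filtered <- ov_apply_filter(ex$table, "(Adj p-value,LOWER_EQUALS,0.004)",
                              quiet = TRUE)
  conn_after <- ov_connect(filtered, ex$network, "query term", "UniProt")
  expect_identical(conn_after$rows_per_node, conn_before$rows_per_node)
  expect_identical(conn_after$network$nodes[["ov::nrows"]],
                   conn_before$network$nodes[["ov::nrows"]])
})

test_that("one table per network: reconnecting needs an explicit replace", {
  ex <- example_tables()
  conn <- ov_connect(ex$table, ex$network, "query term", "UniProt")
  other <- ov_table(tibble::tibble(UniProt = "P20700"), name = "other")
  expect_error(ov_connect(other, conn$network, "query term", "UniProt"),
               class = "ovglyph_conflict_error")
  replaced <- ov_connect(other, conn$network, "query term", "UniProt",
                         replace = TRUE)
  expect_identical(replaced$network$connected_to, "other")
})

test_that("disconnect restores the node table and is idempotent-with-warning", {
  ex <- example_tables()
  conn <- ov_connect(ex$table, ex$network, "query term", "UniProt")
  restored <- ov_disconnect(conn)
  expect_identical(restored$nodes, ex$network$nodes)
  expect_null(restored$connected_to)
  expect_warning(ov_disconnect(restored), regexp = "no connection")
})

test_that("the query column is found by a case-insensitive substring", {
  t1 <- ov_table(tibble::tibble(UniProt = "a", Cluster = "b"))
  expect_identical(ov_detect_query_column(t1), "UniProt")
  t2 <- ov_table(tibble::tibble(uniprot_id = "a", other = "b"))
  expect_identical(ov_detect_query_column(t2), "uniprot_id")
  t3 <- ov_table(tibble::tibble(Gene = "a", Site = "b"))
  expect_null(ov_detect_query_column(t3))
})

test_that("retrieval sends defaults, builds query terms and auto-connects", {
  ex <- example_tables()
  client <- ov_string_client_mock()
  conn <- ov_retrieve_string_network(ex$table, client = client)
  # defaults reach the client untouched
  expect_identical(client$calls$taxon, 9606L)
  expect_identical(client$calls$cutoff, 0.40)
  # one node per unique identifier; 'query term' carries the query
  expect_identical(nrow(conn$network$nodes), 4L)
  expect_setequal(conn$network$nodes[["query term"]],
                  unique(ex$table$data$UniProt))
  expect_identical(conn$net_key, "query term")
  expect_identical(conn$table_key, "UniProt")
  # P20700 again resolves to two rows through the retrieved network
  qt <- conn$network$nodes$id[conn$network$nodes[["query term"]] == "P20700"]
  expect_identical(conn$rows_per_node[[qt]], c(1L, 3L))
})

test_that("retrieval respects filtered_only and rejects empty queries", {
  ex <- example_tables()
  client <- ov_string_client_mock()
  hidden <- ov_apply_filter(ex$table, "(Adj p-value,LOWER,0)", quiet = TRUE)
  expect_error(
    ov_retrieve_string_network(hidden,
                               ov_string_query(filtered_only = TRUE),
                               client = client),
    class = "ovglyph_input_error")
  some <- ov_apply_filter(ex$table, "(UniProt,EQUALS,P20700)", quiet = TRUE)
  conn <- ov_retrieve_string_network(some,
                                     ov_string_query(filtered_only = TRUE),
                                     client = client)
  expect_identical(client$calls$identifiers, "P20700")
  expect_identical(nrow(conn$network$nodes), 1L)
})

test_that("client failures surface as retrieval errors with the message", {
  ex <- example_tables()
  broken <- list(map = function(ids, taxon) stop("service down"),
                 network = function(ids, cutoff) NULL)
  expect_error(ov_retrieve_string_network(ex$table, client = broken),
               regexp = "service down", class = "ovglyph_retrieval_error")
})

test_that("SIF and GraphML files round into networks with attributes", {
  sif <- withr::local_tempfile(fileext = ".sif")
  writeLines(c("a\tpp\tb\tc", "d"), sif)
  attrs <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tquery term\tscore", "a\tP1\t0.5", "b\tP2\t0.7",
               "c\tP3\t0.2", "d\tP4\t0.9"), attrs)
  net <- ov_read_sif(sif, attributes = attrs)
  expect_identical(sort(net$nodes$id), c("a", "b", "c", "d"))
  expect_identical(nrow(net$edges), 2L)
  expect_identical(net$nodes$score[net$nodes$id == "b"], 0.7)

  gml <- withr::local_tempfile(fileext = ".graphml")
  writeLines(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    '<graphml xmlns="http://graphml.graphdrawing.org/xmlns">',
    '<key id="k0" for="node" attr.name="query term" attr.type="string"/>',
    '<key id="k1" for="edge" attr.name="w" attr.type="double"/>',
    '<graph edgedefault="undirected">',
    '<node id="x"><data key="k0">P1</data></node>',
    '<node id="y"><data key="k0">P2</data></node>',
    '<edge source="x" target="y"><data key="k1">0.8</data></edge>',
    '</graph></graphml>'), gml)
  net2 <- ov_read_graphml(gml)
  expect_identical(net2$nodes[["query term"]], c("P1", "P2"))
  expect_identical(net2$edges$w, 0.8)

  expect_error(ov_network(tibble::tibble(id = "a"),
                          tibble::tibble(source = "a", target = "zz")),
               class = "ovglyph_schema_error")
})
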