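#' Molecular networks with node attribute tables
#'
#' An `ov_network` is a node/edge graph: `nodes` is a tibble with a unique
#' character `id` column plus arbitrary typed attribute columns (and optional
#' `x`, `y` positions); `edges` is a tibble with `source` and `target`
#' columns referencing node ids, plus edge attributes.
#'
#' Columns written by this package into the node table live under the
#' namespace prefix `"ov::"` so they are easy to identify and remove.
#'
#' @param nodes Data frame with an `id` column (coerced to character).
#' @param edges Data frame with `source` and `target` columns; may be empty.
#' @param name Network display name.
#' @return An `ov_network`.
#' @examples
#' net <- ov_network(data.frame(id = c("a", "b")),
#'                   data.frame(source = "a", target = "b"))
#' @export
ov_network <- function(nodes, edges = NULL, name = "network") {
  nodes <- as_tibble(nodes)
  if (!"id" %in% names(nodes)) {
    ov_abort("node table must have an 'id' column", "schema_error")
  }
  nodes$id <- as.character(nodes$id)
  if (anyDuplicated(nodes$id)) {
    ov_abort("node ids must be unique", "schema_error")
  }
  if (is.null(edges)) {
    edges <- tibble(source = character(), target = character())
  }
  edges <- as_tibble(edges)
  if (!all(c("source", "target") %in% names(edges))) {
    ov_abort("edge table must have 'source' and 'target' columns", "schema_error")
  }
  edges$source <- as.character(edges$source)
  edges$target <- as.character(edges$target)
  dangling <- setdiff(c(edges$source, edges$target), nodes$id)
  if (length(dangling) > 0) {
    ov_abort(sprintf("edge endpoint(s) not in node table: %s",
                     paste0("'", utils::head(dangling, 5), "'", collapse = ", ")),
             "schema_error")
  }
  structure(
    list(name = as.character(name)[1], nodes = nodes, edges = edges,
         connected_to = NULL, viz = list(), legend = NULL),
    class = "ov_network"
  )
}

#' @export
print.ov_network <- function(x, ...) {
  cat(sprintf("<ov_network> '%s': %d nodes, %d edges%s\n",
              x$name, nrow(x$nodes), nrow(x$edges),
              if (is.null(x$connected_to)) ""
              else sprintf(" (connected to table '%s')", x$connected_to)))
  invisible(x)
}

OV_NS <- "ov::"
ov_ns_col <- function(name) paste0(OV_NS, name)

#' Read a network from a SIF file
#'
#' SIF lines are `source <tab> interaction <tab> target [target ...]`
#' (whitespace-delimited when no tab is present); a line with a single token
#' declares an isolated node. An optional sidecar attribute file is a TSV
#' whose first column holds node ids; its remaining columns become typed node
#' attributes (types inferred as for [ov_read_table()]).
#'
#' @param path Path to the SIF file.
#' @param attributes Optional path to the sidecar node-attribute TSV.
#' @param name Network name; defaults to the file basename.
#' @return An [ov_network()].
#' @export
ov_read_sif <- function(path, attributes = NULL, name = NULL) {
  if (!file.exists(path)) {
    ov_abort(sprintf("file not found: '%s'", path), "io_error")
  }
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  node_ids <- character()
  src <- chr_int <- tgt <- character()
  for (line in lines) {
    parts <- if (grepl("\t", line)) strsplit(line, "\t", fixed = TRUE)[[1]]
             else strsplit(trimws(line), "\\s+")[[1]]
    parts <- parts[nzchar(parts)]
    if (length(parts) == 1L) {
      node_ids <- c(node_ids, parts)
    } else if (length(parts) >= 3L) {
      targets <- parts[3:length(parts)]
      src <- c(src, rep(parts[1], length(targets)))
      chr_int <- c(chr_int, rep(parts[2], length(targets)))
      tgt <- c(tgt, targets)
    } else {
      ov_abort(sprintf("malformed SIF line: '%s'", line), "io_error")
    }
  }
  nodes <- tibble(id = unique(c(node_ids, src, tgt)))
  edges <- tibble(source = src, target = tgt, interaction = chr_int)
  net <- ov_network(nodes, edges, name = name %||% basename(path))
  if (!is.null(attributes)) net <- ov_read_node_attributes(net, attributes)
  net
}

#' @rdname ov_read_sif
#' @param network An [ov_network()] to attach the attributes to.
#' @export
ov_read_node_attributes <- function(network, path) {
  attr_tab <- ov_read_table(path, delimiter = "\t")
  key <- names(attr_tab$data)[1]
  at <- attr_tab$data
  at[[key]] <- ov_render_text(at[[key]])
  names(at)[1] <- "id"
  network$nodes <- dplyr::left_join(network$nodes, at, by = "id")
  network
}

#' Read a network from a GraphML file
#'
#' Supports `<node>`/`<edge>` elements with `<data>` values declared by
#' `<key>` elements (`attr.name`/`attr.type` of `int`, `long`, `float`,
#' `double`, `boolean`, `string`).
#'
#' @param path Path to the GraphML file.
#' @param name Network name; defaults to the file basename.
#' @return An [ov_network()].
#' @export
ov_read_graphml <- function(path, name = NULL) {
  if (!file.exists(path)) {
    ov_abort(sprintf("file not found: '%s'", path), "io_error")
  }
  doc <- xml2::read_xml(path)
  xml2::xml_ns_strip(doc)
  keys <- xml2::xml_find_all(doc, ".//key")
  key_info <- purrr::map(keys, function(k) {
    list(id = xml2::xml_attr(k, "id"),
         name = xml2::xml_attr(k, "attr.name") %||% xml2::xml_attr(k, "id"),
         type = xml2::xml_attr(k, "attr.type") %||% "string",
         domain = xml2::xml_attr(k, "for") %||% "all")
  })
  names(key_info) <- purrr::map_chr(key_info, "id")
  read_data <- function(el) {
    data <- xml2::xml_find_all(el, "./data")
    vals <- list()
    for (d in data) {
      info <- key_info[[xml2::xml_attr(d, "key")]]
      if (is.null(info)) next
      raw <- xml2::xml_text(d)
      vals[[info$name]] <- switch(info$type,
        int = , long = suppressWarnings(as.integer(raw)),
        float = , double = suppressWarnings(as.numeric(raw)),
        boolean = tolower(raw) %in% "true",
        raw)
    }
    vals
  }
  node_els <- xml2::xml_find_all(doc, ".//node")
  nodes <- purrr::map(node_els, function(n) {
    c(list(id = xml2::xml_attr(n, "id")), read_data(n))
  })
  edge_els <- xml2::xml_find_all(doc, ".//edge")
  edges <- purrr::map(edge_els, function(e) {
    c(list(source = xml2::xml_attr(e, "source"),
           target = xml2::xml_attr(e, "target")), read_data(e))
  })
  nodes_tbl <- dplyr::bind_rows(purrr::map(nodes, tibble::as_tibble_row))
  edges_tbl <- if (length(edges) > 0) {
    dplyr::bind_rows(purrr::map(edges, tibble::as_tibble_row))
  } else NULL
  ov_network(nodes_tbl, edges_tbl, name = name %||% basename(path))
}

#' Connect a table to a network via matching key columns
#'
#' Links every table row whose `table_key` value equals a node's `net_key`
#' value (string equality after canonical text rendering, so integer keys
#' match their undecorated text form). The per-node connected-row lists keep
#' the table's row order and reflect *all* rows, ignoring any active filter.
#' A per-node connected-row count is written into the node attribute table as
#' column `"ov::nrows"`.
#'
#' A table may be connected to several networks, but a network can be
#' connected to only one table: reconnecting an already-connected network
#' requires `replace = TRUE`.
#'
#' @param table An [ov_table()].
#' @param network An [ov_network()].
#' @param net_key Node attribute column holding the key (e.g. `"query term"`).
#' @param table_key Table column holding the key (e.g. `"UniProt"`).
#' @param replace Allow replacing an existing connection of this network.
#' @return An `ov_connection`: list with the `table`, the updated `network`,
#'   the two key column names, and `rows_per_node` (named list of integer row
#'   indices per node id).
#' @export
ov_connect <- function(table, network, net_key, table_key, replace = FALSE) {
  stopifnot(inherits(table, "ov_table"), inherits(network, "ov_network"))
  if (!net_key %in% names(network$nodes)) {
    ov_abort(sprintf("key column '%s' not found in node table", net_key),
             "schema_error")
  }
  if (!table_key %in% names(table$data)) {
    ov_abort(sprintf("key column '%s' not found in table '%s'",
                     table_key, table$name), "schema_error")
  }
  if (!is.null(network$connected_to) && !replace) {
    ov_abort(sprintf(
      "network '%s' is already connected to table '%s'; use replace = TRUE",
      network$name, network$connected_to), "conflict_error")
  }
  node_keys <- ov_render_text(network$nodes[[net_key]])
  row_keys <- ov_render_text(table$data[[table_key]])
  rows_per_node <- purrr::map(node_keys, function(k) {
    if (is.na(k)) integer(0) else which(!is.na(row_keys) & row_keys == k)
  })
  names(rows_per_node) <- network$nodes$id
  network$nodes[[ov_ns_col("nrows")]] <- unname(lengths(rows_per_node))
  network$connected_to <- table$name
  structure(
    list(table = table, network = network,
         net_key = net_key, table_key = table_key,
         rows_per_node = rows_per_node),
    class = "ov_connection"
  )
}

#' @export
print.ov_connection <- function(x, ...) {
  cat(sprintf(
    "<ov_connection> table '%s' (%s) <-> network '%s' (%s): %d/%d nodes with rows\n",
    x$table$name, x$table_key, x$network$name, x$net_key,
    sum(lengths(x$rows_per_node) > 0), length(x$rows_per_node)))
  invisible(x)
}

#' Remove a connection from a network
#'
#' Drops the `"ov::"` namespace bookkeeping columns from the node table and
#' clears the connection marker. The table itself is untouched. Disconnecting
#' an unconnected network is a warning, not an error.
#'
#' @param network An [ov_network()] or an `ov_connection`.
#' @return The restored `ov_network`.
#' @export
ov_disconnect <- function(network) {
  if (inherits(network, "ov_connection")) network <- network$network
  stopifnot(inherits(network, "ov_network"))
  if (is.null(network$connected_to)) {
    warn(sprintf("network '%s' has no connection; nothing to do", network$name))
    return(network)
  }
  ns_cols <- grep(paste0("^", OV_NS), names(network$nodes), value = TRUE)
  network$nodes <- network$nodes[, setdiff(names(network$nodes), ns_cols),
                                 drop = FALSE]
  network$connected_to <- NULL
  network$viz <- list()
  network
}

#' Find the identifier column of a table
#'
#' Returns the first column whose name contains `"uniprot"`
#' case-insensitively, or `NULL` when none does (the caller must then name
#' the column explicitly).
#'
#' @param table An [ov_table()].
#' @return A column name or `NULL`.
#' @export
ov_detect_query_column <- function(table) {
  hits <- grep("uniprot", names(table$data), ignore.case = TRUE, value = TRUE)
  if (length(hits) == 0) NULL else hits[[1]]
}

#' Query settings for protein-network retrieval
#'
#' Defaults follow the retrieval conventions for functional protein
#' association networks: human (NCBI taxon 9606) and a confidence cutoff of
#' 0.40; when `query_column` is `NULL` it is located by a case-insensitive
#' search for `"uniprot"` among the column names.
#'
#' @param query_column Table column holding the protein identifiers, or
#'   `NULL` to auto-detect.
#' @param species_taxon NCBI taxonomy identifier (default 9606, human).
#' @param confidence_cutoff Interaction confidence cutoff in `[0, 1]`
#'   (default 0.40).
#' @param filtered_only Query only identifiers from currently visible rows.
#' @return An `ov_string_query`.
#' @export
ov_string_query <- function(query_column = NULL, species_taxon = 9606L,
                            confidence_cutoff = 0.40, filtered_only = FALSE) {
  if (confidence_cutoff < 0 || confidence_cutoff > 1) {
    ov_abort("confidence_cutoff must be within [0, 1]", "input_error")
  }
  structure(
    list(query_column = query_column,
         species_taxon = as.integer(species_taxon),
         confidence_cutoff = as.numeric(confidence_cutoff),
         filtered_only = isTRUE(filtered_only)),
    class = "ov_string_query"
  )
}

#' Retrieve a protein network and connect it automatically
#'
#' Sends the unique identifiers of the query column (visible rows only when
#' `filtered_only`) to a pluggable client, builds a network from the result
#' with each query identifier stored in the node attribute `"query term"`,
#' and connects it to the table with `net_key = "query term"` and
#' `table_key` = the query column.
#'
#' The client is a list with two functions mirroring the public STRING API
#' shape: `map(identifiers, taxon)` returning a data frame with columns
#' `query_term` and `id`, and `network(ids, cutoff)` returning a list with
#' `nodes` (data frame with `id` plus attributes) and `edges` (data frame
#' with `source`, `target`). Use [ov_string_client_mock()] for offline work
#' and tests, [ov_string_client_http()] against a live service.
#'
#' @param table An [ov_table()].
#' @param query An [ov_string_query()].
#' @param client The retrieval client.
#' @param name Name for the retrieved network.
#' @return An `ov_connection` whose `network` element is the retrieved
#'   network.
#' @export
ov_retrieve_string_network <- function(table, query = ov_string_query(),
                                       client = ov_string_client_mock(),
                                       name = "retrieved network") {
  stopifnot(inherits(table, "ov_table"), inherits(query, "ov_string_query"))
  qcol <- query$query_column %||% ov_detect_query_column(table)
  if (is.null(qcol)) {
    ov_abort("no query column given and none matching 'uniprot' found",
             "input_error")
  }
  if (!qcol %in% names(table$data)) {
    ov_abort(sprintf("query column '%s' not found in table", qcol),
             "schema_error")
  }
  rows <- if (query$filtered_only) table$visible else seq_len(ov_n_rows(table))
  ids <- unique(ov_render_text(table$data[[qcol]][rows]))
  ids <- ids[!is.na(ids) & nzchar(ids)]
  if (length(ids) == 0) {
    ov_abort("no identifiers to query (all rows hidden or missing keys)",
             "input_error")
  }
  mapped <- tryCatch(
    as_tibble(client$map(ids, query$species_taxon)),
    error = function(e) ov_abort(
      paste0("identifier mapping failed: ", conditionMessage(e)),
      "retrieval_error")
  )
  if (!all(c("query_term", "id") %in% names(mapped))) {
    ov_abort("client$map must return columns 'query_term' and 'id'",
             "retrieval_error")
  }
  net_raw <- tryCatch(
    client$network(mapped$id, query$confidence_cutoff),
    error = function(e) ov_abort(
      paste0("network retrieval failed: ", conditionMessage(e)),
      "retrieval_error")
  )
  nodes <- as_tibble(net_raw$nodes)
  nodes$id <- as.character(nodes$id)
  qt <- mapped$query_term[match(nodes$id, mapped$id)]
  nodes[["query term"]] <- qt
  network <- ov_network(nodes, net_raw$edges, name = name)
  ov_connect(table, network, net_key = "query term", table_key = qcol)
}

#' Deterministic offline retrieval client
#'
#' Echoes every queried identifier as one node (id prefixed `"str."`, with a
#' `display name` attribute) and draws seeded random edges among them. The
#' arguments of the last `map`/`network` calls are recorded in `$calls`, so
#' callers can verify what was sent (taxon, cutoff, identifiers).
#'
#' @param edge_prob Probability of an edge between any node pair.
#' @param seed Seed for the edge draw.
#' @return A client list with `map`, `network` and the `calls` record
#'   environment.
#' @export
ov_string_client_mock <- function(edge_prob = 0, seed = 1L) {
  calls <- new.env(parent = emptyenv())
  list(
    map = function(identifiers, taxon) {
      calls$identifiers <- identifiers
      calls$taxon <- taxon
      tibble(query_term = identifiers, id = paste0("str.", identifiers))
    },
    network = function(ids, cutoff) {
      calls$ids <- ids
      calls$cutoff <- cutoff
      nodes <- tibble(id = ids, `display name` = sub("^str\\.", "", ids))
      edges <- ov_random_edges(ids, edge_prob, seed)
      list(nodes = nodes, edges = edges)
    },
    calls = calls
  )
}

ov_random_edges <- function(ids, edge_prob, seed) {
  n <- length(ids)
  if (n < 2 || edge_prob <= 0) {
    return(tibble(source = character(), target = character()))
  }
  pairs <- utils::combn(n, 2)
  pick <- withr::with_seed(seed, stats::runif(ncol(pairs)) < edge_prob)
  tibble(source = ids[pairs[1, pick]], target = ids[pairs[2, pick]])
}

#' HTTP retrieval client for a STRING-like service
#'
#' Maps identifiers through `get_string_ids` and fetches interactions through
#' `network` JSON endpoints. Requires network access; offline work and all
#' tests use [ov_string_client_mock()].
#'
#' @param base_url Service root.
#' @return A client list with `map` and `network`.
#' @export
ov_string_client_http <- function(base_url = "https://string-db.org") {
  list(
    map = function(identifiers, taxon) {
      url <- sprintf(
        "%s/api/json/get_string_ids?identifiers=%s&species=%d&limit=1",
        base_url, paste(utils::URLencode(identifiers, reserved = TRUE),
                        collapse = "%0d"), taxon)
      res <- jsonlite::fromJSON(url)
      tibble(query_term = identifiers[res$queryIndex + 1L],
             id = res$stringId)
    },
    network = function(ids, cutoff) {
      url <- sprintf(
        "%s/api/json/network?identifiers=%s&required_score=%d",
        base_url, paste(utils::URLencode(ids, reserved = TRUE),
                        collapse = "%0d"), as.integer(round(cutoff * 1000)))
      res <- jsonlite::fromJSON(url)
      all_ids <- unique(c(res$stringId_A, res$stringId_B, ids))
      list(nodes = tibble(id = all_ids),
           edges = tibble(source = res$stringId_A, target = res$stringId_B,
                          score = res$score))
    }
  )
}
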