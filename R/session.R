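#' Analysis sessions
#'
#' A session holds the working state of a multi-step workflow: named tables
#' with their active filters, networks, table-network connections,
#' visualization configurations per network, and the legend. Referential
#' integrity (a network connected to exactly the table named in its
#' connection, at most one table per network) is maintained by the command
#' layer and re-checked when a session file is loaded.
#'
#' @param client Retrieval client used by the `retrieve` command (default:
#'   the deterministic offline mock).
#' @return An `ov_session` (an environment).
#' @export
ov_session <- function(client = ov_string_client_mock()) {
  s <- new.env(parent = emptyenv())
  s$tables <- list()
  s$networks <- list()
  s$connections <- list()   # named by network name; holds ov_connection
  s$active_table <- NULL
  s$active_network <- NULL
  s$legend <- NULL
  s$legend_params <- NULL
  s$client <- client
  class(s) <- "ov_session"
  s
}

#' @export
print.ov_session <- function(x, ...) {
  cat(sprintf(
    "<ov_session> %d table(s), %d network(s), %d connection(s)%s%s\n",
    length(x$tables), length(x$networks), length(x$connections),
    if (is.null(x$active_table)) "" else sprintf("; active table '%s'", x$active_table),
    if (is.null(x$active_network)) "" else sprintf("; active network '%s'", x$active_network)))
  invisible(x)
}

# register a table under a unique name (duplicates get a numeric suffix)
ov_session_add_table <- function(session, table) {
  name <- table$name
  if (name %in% names(session$tables)) {
    i <- 2L
    while (sprintf("%s (%d)", name, i) %in% names(session$tables)) i <- i + 1L
    name <- sprintf("%s (%d)", name, i)
    table$name <- name
  }
  session$tables[[name]] <- table
  session$active_table <- name
  name
}

ov_session_add_network <- function(session, network) {
  name <- network$name
  if (name %in% names(session$networks)) {
    i <- 2L
    while (sprintf("%s (%d)", name, i) %in% names(session$networks)) i <- i + 1L
    name <- sprintf("%s (%d)", name, i)
    network$name <- name
  }
  session$networks[[name]] <- network
  session$active_network <- name
  name
}

# the session's current copy of the table a connection refers to
ov_session_conn_table <- function(session, conn) {
  session$tables[[conn$table$name]] %||% conn$table
}

OV_SESSION_VERSION <- 1L

ov_mapping_to_list <- function(m) {
  if (inherits(m, "ov_continuous_mapping")) {
    list(type = "continuous",
         min_value = m$min_value, mid_value = m$mid_value,
         max_value = m$max_value,
         min_color = m$min_color, mid_color = m$mid_color,
         max_color = m$max_color, palette = m$palette)
  } else {
    list(type = "discrete",
         values = as.list(m$assignments$value),
         colors = as.list(m$assignments$color),
         palette = m$palette)
  }
}

ov_mapping_from_list <- function(x) {
  if (identical(x$type, "continuous")) {
    ov_continuous_mapping(x$min_value, x$mid_value, x$max_value,
                          x$min_color, x$mid_color, x$max_color,
                          palette = x$palette)
  } else {
    ov_discrete_mapping(unlist(x$values) %||% character(),
                        unlist(x$colors) %||% character(),
                        palette = x$palette)
  }
}

ov_config_to_list <- function(cfg) {
  list(style = cfg$style, value_columns = as.list(cfg$value_columns),
       label_column = cfg$label_column, mapping = ov_mapping_to_list(cfg$mapping),
       filtered_only = cfg$filtered_only, ring_mode = cfg$ring_mode,
       arc_start = cfg$arc_start, label_size = cfg$label_size,
       na_color = cfg$na_color)
}

ov_config_from_list <- function(x) {
  ov_viz_config(style = x$style, value_columns = unlist(x$value_columns),
                mapping = ov_mapping_from_list(x$mapping),
                label_column = x$label_column,
                filtered_only = isTRUE(x$filtered_only),
                ring_mode = x$ring_mode, arc_start = x$arc_start,
                label_size = x$label_size, na_color = x$na_color)
}

# tables and node/edge tables embed as TSV blocks for human diff-ability;
# derived "ov::" columns are dropped and rebuilt from the connection records
ov_session_to_list <- function(session) {
  tables <- purrr::map(session$tables, function(tab) {
    list(name = tab$name,
         dtypes = as.list(ov_dtypes(tab)),
         tsv = ov_write_table(tab),
         filter = if (is.null(tab$filter)) NULL else format(tab$filter))
  })
  networks <- purrr::map(session$networks, function(net) {
    keep <- !startsWith(names(net$nodes), OV_NS)
    nodes <- net$nodes[, keep, drop = FALSE]
    node_tab <- ov_table(nodes, name = "nodes")
    edge_tab <- ov_table(net$edges, name = "edges")
    list(name = net$name,
         node_dtypes = as.list(ov_dtypes(node_tab)),
         nodes_tsv = ov_write_table(node_tab),
         edge_dtypes = as.list(ov_dtypes(edge_tab)),
         edges_tsv = ov_write_table(edge_tab),
         viz = purrr::map(unname(net$viz), ov_config_to_list))
  })
  connections <- purrr::map(unname(session$connections), function(conn) {
    list(network = conn$network$name, table = conn$table$name,
         net_key = conn$net_key, table_key = conn$table_key)
  })
  list(version = OV_SESSION_VERSION,
       tables = unname(tables),
       networks = unname(networks),
       connections = connections,
       active_table = session$active_table,
       active_network = session$active_network,
       legend = session$legend_params)
}

#' Save and load a session as versioned JSON
#'
#' Tables are embedded as TSV blocks with explicit column types; filters as
#' their string form; connections and visualizations as records that are
#' re-applied on load, which recreates the table-network links and all
#' derived node-table columns. `ov_load_session(ov_save_session(s))`
#' reproduces the session up to record ordering.
#'
#' @param session An [ov_session()].
#' @param path File path for the JSON session file.
#' @param client Retrieval client to install in the loaded session.
#' @return `ov_save_session()` the path, invisibly; `ov_load_session()` a
#'   fresh `ov_session`.
#' @export
ov_save_session <- function(session, path) {
  stopifnot(inherits(session, "ov_session"))
  jsonlite::write_json(ov_session_to_list(session), path,
                       auto_unbox = TRUE, null = "null", digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname ov_save_session
#' @export
ov_load_session <- function(path, client = ov_string_client_mock()) {
  if (!file.exists(path)) {
    ov_abort(sprintf("session file not found: '%s'", path), "io_error")
  }
  raw <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) ov_abort(
      sprintf("cannot read session file '%s': %s", path, conditionMessage(e)),
      "io_error"))
  version <- raw$version %||% -1L
  if (!identical(as.integer(version), OV_SESSION_VERSION)) {
    ov_abort(sprintf(
      "session version mismatch: file has %s, this build reads %d",
      version, OV_SESSION_VERSION), "migration_error")
  }
  # build into a fresh session; only assign on full success
  session <- ov_session(client = client)
  for (trec in raw$tables) {
    tab <- ov_table_from_tsv(trec$tsv, dtypes = trec$dtypes, name = trec$name)
    if (!is.null(trec$filter)) {
      tab <- ov_apply_filter(tab, ov_parse_filter(trec$filter), quiet = TRUE)
    }
    session$tables[[tab$name]] <- tab
  }
  for (nrec in raw$networks) {
    node_tab <- ov_table_from_tsv(nrec$nodes_tsv, dtypes = nrec$node_dtypes)
    edge_tab <- ov_table_from_tsv(nrec$edges_tsv, dtypes = nrec$edge_dtypes)
    net <- ov_network(node_tab$data, edge_tab$data, name = nrec$name)
    session$networks[[net$name]] <- net
    for (cfgrec in nrec$viz) {
      cfg <- ov_config_from_list(cfgrec)
      session$networks[[net$name]]$viz[[cfg$style]] <- cfg
    }
  }
  for (crec in raw$connections) {
    tab <- session$tables[[crec$table]]
    net <- session$networks[[crec$network]]
    if (is.null(tab) || is.null(net)) {
      ov_abort(sprintf(
        "session refers to unknown table '%s' or network '%s'",
        crec$table, crec$network), "migration_error")
    }
    if (!is.null(net$connected_to)) {
      ov_abort(sprintf("network '%s' is connected twice in the session file",
                       crec$network), "migration_error")
    }
    viz <- net$viz
    conn <- ov_connect(tab, net, crec$net_key, crec$table_key)
    for (cfg in viz) {
      conn <- ov_apply_viz(conn, cfg, table = tab)
    }
    session$connections[[crec$network]] <- conn
    session$networks[[crec$network]] <- conn$network
  }
  session$active_table <- raw$active_table
  session$active_network <- raw$active_network
  if (!is.null(raw$legend)) {
    raw$legend$font_size <- as.numeric(raw$legend$font_size %||% 12)
    session$legend_params <- raw$legend
    session$legend <- ov_rebuild_legend(session)
  }
  session
}

ov_table_from_tsv <- function(tsv, dtypes = NULL, name = "table") {
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(sub("\n$", "", tsv), tmp, sep = "\n")
  dt <- if (length(dtypes) > 0) unlist(dtypes) else NULL
  ov_read_table(tmp, delimiter = "\t", dtypes = dt, name = name)
}

# legends are rebuilt from the stored parameters and the network's active
# visualizations, so they always agree with the current state
ov_rebuild_legend <- function(session) {
  p <- session$legend_params
  net <- session$networks[[p$network %||% session$active_network]]
  if (is.null(net) || length(net$viz) == 0) {
    ov_abort("no active visualization to build a legend from", "input_error")
  }
  ov_build_legend(unname(net$viz), title = p$title %||% "",
                  font = p$font %||% "Helvetica",
                  font_size = p$font_size %||% 12,
                  position = p$position %||% "EAST_TOP")
}
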