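#' Run an `ov` command
#'
#' The command surface mirrors an automation-style interface: a subcommand
#' followed by `key=value` flags (a `--key value` form is also accepted).
#' Each subcommand is a thin adapter over one library operation.
#'
#' Subcommands:
#' * `load file=... [name=...] [attributes=...] [type=table|network]` —
#'   import a delimited table, or a SIF/GraphML network (type sniffed from
#'   the file extension).
#' * `filter filter="(col,OP[,operand])"` — apply a filter to the active
#'   table (empty string clears it); prints row counts before/after.
#' * `connect mappingColNet=... mappingColTable=... [network=] [table=]
#'   [replace=true]` — connect the active (or named) table and network.
#' * `retrieve [taxonID=9606] [cutoff=0.40] [filteredOnly=true]
#'   [queryColumn=...] [name=...]` — retrieve a network through the
#'   session's client and auto-connect it.
#' * `viz apply {inner|outer} {continuous|discrete} attributes="c1,c2"
#'   [labels=...] [filteredOnly=true] [rangeMin=] [rangeMid=] [rangeMax=]
#'   [colorMin=] [colorMid=] [colorMax=] [colorMapping="v:#RRGGBB,..."]
#'   [paletteName=] [ringMode=ring_is_column|ring_is_row]
#'   [chartSettings="arcstart:0,labelsize:15"]` — build and store a pie
#'   (`inner`) or donut (`outer`) visualization on the active network.
#' * `legend draw [position=EAST_TOP] [title=] [font=] [fontSize=]` —
#'   generate the grouped legend for the active network's visualizations.
#' * `render file=out.svg [width=] [height=] [seed=]` — write the decorated
#'   network as SVG.
#' * `session save file=... | session load file=...`
#'
#' @param argv Character vector of command words, e.g.
#'   `c("filter", 'filter=(Adj p-value,LOWER_EQUALS,0.01)')`.
#' @param session An [ov_session()]; mutated in place.
#' @return Invisibly, a list with `status` (0 on success, non-zero on error)
#'   and `output` (printed lines).
#' @examples
#' s <- ov_session()
#' path <- tempfile(fileext = ".tsv")
#' ov_write_table(ov_fixture_table(n_proteins = 5), path)
#' ov_run_command(c("load", paste0("file=", path)), s)
#' @export
ov_run_command <- function(argv, session) {
  stopifnot(is.character(argv), inherits(session, "ov_session"))
  out <- character()
  status <- 0L
  res <- tryCatch(
    ov_dispatch_command(argv, session),
    ovglyph_error = function(e) {
      message("ov: ", conditionMessage(e))
      status <<- 1L
      NULL
    })
  if (!is.null(res)) out <- res
  if (length(out) > 0) cat(out, sep = "\n")
  invisible(list(status = status, output = out))
}

ov_dispatch_command <- function(argv, session) {
  if (length(argv) == 0) ov_abort("no subcommand given", "usage_error")
  sub <- argv[[1]]
  rest <- argv[-1]
  switch(sub,
    load = ov_cmd_load(rest, session),
    filter = ov_cmd_filter(rest, session),
    connect = ov_cmd_connect(rest, session),
    retrieve = ov_cmd_retrieve(rest, session),
    viz = ov_cmd_viz(rest, session),
    legend = ov_cmd_legend(rest, session),
    render = ov_cmd_render(rest, session),
    session = ov_cmd_session(rest, session),
    ov_abort(sprintf("unknown subcommand '%s'", sub), "usage_error")
  )
}

# split positional words from key=value / --key value flags
ov_parse_flags <- function(argv, allowed, positional_max = 0L) {
  flags <- list()
  positional <- character()
  i <- 1L
  while (i <= length(argv)) {
    tok <- argv[[i]]
    m <- regmatches(tok, regexec("^(?:--?)?([A-Za-z][A-Za-z0-9]*)=(.*)$", tok))[[1]]
    if (length(m) == 3L) {
      key <- m[2]; val <- m[3]
    } else if (grepl("^--", tok)) {
      key <- sub("^--", "", tok)
      if (i == length(argv)) {
        ov_abort(sprintf("flag '--%s' needs a value", key), "usage_error")
      }
      i <- i + 1L
      val <- argv[[i]]
    } else {
      if (length(positional) >= positional_max) {
        ov_abort(sprintf("unexpected argument '%s'", tok), "usage_error")
      }
      positional <- c(positional, tok)
      i <- i + 1L
      next
    }
    if (!key %in% allowed) {
      ov_abort(sprintf("unknown flag '%s' (expected one of: %s)", key,
                       paste(allowed, collapse = ", ")), "usage_error")
    }
    # tolerate values that still carry their shell quotes
    val <- sub('^"(.*)"$', "\\1", val)
    flags[[key]] <- val
    i <- i + 1L
  }
  list(flags = flags, positional = positional)
}

ov_flag_bool <- function(val, default = FALSE) {
  if (is.null(val)) return(default)
  low <- tolower(val)
  if (!low %in% c("true", "false")) {
    ov_abort(sprintf("expected true/false, got '%s'", val), "usage_error")
  }
  identical(low, "true")
}

ov_flag_num <- function(val, what) {
  if (is.null(val)) return(NULL)
  num <- suppressWarnings(as.numeric(val))
  if (is.na(num)) {
    ov_abort(sprintf("flag '%s' must be numeric, got '%s'", what, val),
             "usage_error")
  }
  num
}

ov_active_table <- function(session, name = NULL) {
  name <- name %||% session$active_table
  if (is.null(name) || !name %in% names(session$tables)) {
    ov_abort("no table loaded (use: ov load file=...)", "state_error")
  }
  list(name = name, table = session$tables[[name]])
}

ov_active_network <- function(session, name = NULL) {
  name <- name %||% session$active_network
  if (is.null(name) || !name %in% names(session$networks)) {
    ov_abort("no network available (load or retrieve one first)", "state_error")
  }
  list(name = name, network = session$networks[[name]])
}

ov_cmd_load <- function(argv, session) {
  p <- ov_parse_flags(argv, c("file", "name", "type", "attributes", "delimiter"))
  file <- p$flags$file
  if (is.null(file)) ov_abort("load requires file=...", "usage_error")
  ext <- tolower(tools::file_ext(file))
  type <- p$flags$type %||%
    (if (ext == "sif") "network"
     else if (ext %in% c("graphml", "xml")) "network" else "table")
  if (type == "network") {
    net <- if (ext == "sif") {
      ov_read_sif(file, attributes = p$flags$attributes, name = p$flags$name)
    } else {
      ov_read_graphml(file, name = p$flags$name)
    }
    name <- ov_session_add_network(session, net)
    sprintf("loaded network '%s': %d nodes, %d edges", name,
            nrow(net$nodes), nrow(net$edges))
  } else {
    tab <- ov_read_table(file, delimiter = p$flags$delimiter %||% "auto",
                         name = p$flags$name)
    name <- ov_session_add_table(session, tab)
    sprintf("loaded table '%s': %d rows, %d columns", name,
            ov_n_rows(tab), ncol(tab$data))
  }
}

ov_cmd_filter <- function(argv, session) {
  p <- ov_parse_flags(argv, c("filter", "table"))
  at <- ov_active_table(session, p$flags$table)
  expr <- if (is.null(p$flags$filter) || !nzchar(p$flags$filter)) NULL
          else ov_parse_filter(p$flags$filter)
  tab <- ov_apply_filter(at$table, expr, quiet = TRUE)
  session$tables[[at$name]] <- tab
  rep <- attr(tab, "filter_report")
  sprintf("rows: %d before filtering, %d after", rep[["n_before"]],
          rep[["n_after"]])
}

ov_cmd_connect <- function(argv, session) {
  p <- ov_parse_flags(argv, c("mappingColNet", "mappingColTable",
                              "network", "table", "replace"))
  if (is.null(p$flags$mappingColNet) || is.null(p$flags$mappingColTable)) {
    ov_abort("connect requires mappingColNet=... and mappingColTable=...",
             "usage_error")
  }
  at <- ov_active_table(session, p$flags$table)
  an <- ov_active_network(session, p$flags$network)
  conn <- ov_connect(at$table, an$network,
                     net_key = p$flags$mappingColNet,
                     table_key = p$flags$mappingColTable,
                     replace = ov_flag_bool(p$flags$replace))
  session$connections[[an$name]] <- conn
  session$networks[[an$name]] <- conn$network
  sprintf("connected table '%s' to network '%s' (%d of %d nodes have rows)",
          at$name, an$name, sum(lengths(conn$rows_per_node) > 0),
          length(conn$rows_per_node))
}

ov_cmd_retrieve <- function(argv, session) {
  p <- ov_parse_flags(argv, c("taxonID", "cutoff", "filteredOnly",
                              "queryColumn", "name", "table"))
  at <- ov_active_table(session, p$flags$table)
  query <- ov_string_query(
    query_column = p$flags$queryColumn,
    species_taxon = ov_flag_num(p$flags$taxonID, "taxonID") %||% 9606L,
    confidence_cutoff = ov_flag_num(p$flags$cutoff, "cutoff") %||% 0.40,
    filtered_only = ov_flag_bool(p$flags$filteredOnly))
  conn <- ov_retrieve_string_network(at$table, query, client = session$client,
                                     name = p$flags$name %||% "retrieved network")
  name <- ov_session_add_network(session, conn$network)
  conn$network$name <- name
  session$connections[[name]] <- conn
  session$networks[[name]] <- conn$network
  sprintf("retrieved network '%s': %d nodes, %d edges (auto-connected on 'query term' <-> '%s')",
          name, nrow(conn$network$nodes), nrow(conn$network$edges),
          conn$table_key)
}

ov_cmd_viz <- function(argv, session) {
  if (length(argv) < 3 || argv[[1]] != "apply") {
    ov_abort("usage: ov viz apply {inner|outer} {continuous|discrete} ...",
             "usage_error")
  }
  where <- argv[[2]]
  if (!where %in% c("inner", "outer")) {
    ov_abort("viz apply expects 'inner' (pie) or 'outer' (donut)", "usage_error")
  }
  kind <- argv[[3]]
  if (!kind %in% c("continuous", "discrete")) {
    ov_abort("viz apply expects 'continuous' or 'discrete'", "usage_error")
  }
  style <- if (where == "inner") "pie" else "donut"
  p <- ov_parse_flags(argv[-(1:3)], c(
    "attributes", "labels", "filteredOnly", "network",
    "rangeMin", "rangeMid", "rangeMax", "colorMin", "colorMid", "colorMax",
    "colorMapping", "paletteName", "ringMode", "chartSettings"))
  an <- ov_active_network(session, p$flags$network)
  conn <- session$connections[[an$name]]
  if (is.null(conn)) {
    ov_abort(sprintf("network '%s' is not connected to a table", an$name),
             "state_error")
  }
  table <- ov_session_conn_table(session, conn)
  if (is.null(p$flags$attributes)) {
    ov_abort("viz apply requires attributes=...", "usage_error")
  }
  value_columns <- trimws(strsplit(p$flags$attributes, ",", fixed = TRUE)[[1]])
  missing_cols <- setdiff(value_columns, names(table$data))
  if (length(missing_cols) > 0) {
    ov_abort(sprintf("attribute column(s) not in table: %s",
                     paste0("'", missing_cols, "'", collapse = ", ")),
             "schema_error")
  }
  filtered_only <- ov_flag_bool(p$flags$filteredOnly)
  mapping <- if (kind == "continuous") {
    ov_cmd_continuous_mapping(p$flags, table, value_columns, conn,
                              filtered_only)
  } else {
    ov_cmd_discrete_mapping(p$flags, table, value_columns, conn,
                            filtered_only)
  }
  settings <- ov_parse_chart_settings(p$flags$chartSettings)
  config <- ov_viz_config(
    style = style, value_columns = value_columns, mapping = mapping,
    label_column = p$flags$labels, filtered_only = filtered_only,
    ring_mode = p$flags$ringMode %||% "ring_is_column",
    arc_start = settings$arcstart %||% 0,
    label_size = settings$labelsize)
  conn <- ov_apply_viz(conn, config, table = table)
  session$connections[[an$name]] <- conn
  session$networks[[an$name]] <- conn$network
  n_charts <- length(conn$charts[[style]])
  sprintf("applied %s (%s) visualization on '%s': %d node(s) decorated",
          style, kind, an$name, n_charts)
}

# values of the visualized cells on the rows that will actually be drawn
ov_viz_values <- function(table, value_columns, conn, filtered_only) {
  rows <- sort(unique(unlist(conn$rows_per_node)))
  if (filtered_only) rows <- rows[rows %in% table$visible]
  unlist(purrr::map(value_columns, function(colname) {
    v <- table$data[[colname]][rows]
    suppressWarnings(as.numeric(v))
  }))
}

ov_cmd_continuous_mapping <- function(flags, table, value_columns, conn,
                                      filtered_only) {
  rmin <- ov_flag_num(flags$rangeMin, "rangeMin")
  rmid <- ov_flag_num(flags$rangeMid, "rangeMid") %||% 0
  rmax <- ov_flag_num(flags$rangeMax, "rangeMax")
  if (is.null(rmin) || is.null(rmax)) {
    bounds <- ov_default_continuous_bounds(
      ov_viz_values(table, value_columns, conn, filtered_only))
    rmin <- rmin %||% bounds[["min"]]
    rmax <- rmax %||% bounds[["max"]]
  }
  pal <- flags$paletteName
  anchors <- if (!is.null(pal)) ov_palette(pal)[c(1, 2, 3)]
             else c("#0571B0", "#FFFFFF", "#CA0020")
  ov_continuous_mapping(
    rmin, rmid, rmax,
    min_color = flags$colorMin %||% anchors[1],
    mid_color = flags$colorMid %||% anchors[2],
    max_color = flags$colorMax %||% anchors[3],
    palette = pal)
}

ov_cmd_discrete_mapping <- function(flags, table, value_columns, conn,
                                    filtered_only) {
  if (!is.null(flags$colorMapping)) {
    return(ov_parse_discrete_mapping(flags$colorMapping))
  }
  rows <- sort(unique(unlist(conn$rows_per_node)))
  if (filtered_only) rows <- rows[rows %in% table$visible]
  vals <- unlist(purrr::map(value_columns,
                            function(colname) ov_render_text(table$data[[colname]][rows])))
  ov_auto_discrete_mapping(vals, palette = flags$paletteName %||% "Paired")
}

ov_parse_chart_settings <- function(text) {
  if (is.null(text) || !nzchar(text)) return(list())
  parts <- strsplit(text, ",", fixed = TRUE)[[1]]
  kv <- strsplit(parts, ":", fixed = TRUE)
  bad <- vapply(kv, length, integer(1)) != 2L
  if (any(bad)) {
    ov_abort(sprintf("malformed chartSettings entr%s: %s",
                     if (sum(bad) > 1) "ies" else "y",
                     paste0("'", parts[bad], "'", collapse = ", ")),
             "usage_error")
  }
  keys <- trimws(vapply(kv, `[[`, character(1), 1))
  vals <- trimws(vapply(kv, `[[`, character(1), 2))
  unknown <- setdiff(keys, c("arcstart", "labelsize"))
  if (length(unknown) > 0) {
    ov_abort(sprintf("unknown chartSettings key(s): %s",
                     paste0("'", unknown, "'", collapse = ", ")),
             "usage_error")
  }
  out <- purrr::map(vals, function(v) {
    num <- suppressWarnings(as.numeric(v))
    if (is.na(num)) ov_abort("chartSettings values must be numeric", "usage_error")
    num
  })
  names(out) <- keys
  out
}

ov_cmd_legend <- function(argv, session) {
  if (length(argv) < 1 || argv[[1]] != "draw") {
    ov_abort("usage: ov legend draw [position=] [title=] ...", "usage_error")
  }
  p <- ov_parse_flags(argv[-1], c("position", "title", "font", "fontSize",
                                  "network"))
  an <- ov_active_network(session, p$flags$network)
  if (length(an$network$viz) == 0) {
    ov_abort("no active visualization to build a legend from", "input_error")
  }
  params <- list(network = an$name,
                 title = p$flags$title %||% "",
                 font = p$flags$font %||% "Helvetica",
                 font_size = ov_flag_num(p$flags$fontSize, "fontSize") %||% 12,
                 position = p$flags$position %||% "EAST_TOP")
  session$legend_params <- params
  session$legend <- ov_rebuild_legend(session)
  sprintf("legend: %d element(s) at %s", length(session$legend$elements),
          session$legend$position)
}

ov_cmd_render <- function(argv, session) {
  p <- ov_parse_flags(argv, c("file", "network", "width", "height", "seed"))
  if (is.null(p$flags$file)) ov_abort("render requires file=...", "usage_error")
  an <- ov_active_network(session, p$flags$network)
  conn <- session$connections[[an$name]]
  charts <- if (is.null(conn)) NULL else unname(conn$charts)
  ov_render_svg(an$network, charts = charts, legend = session$legend,
                seed = as.integer(ov_flag_num(p$flags$seed, "seed") %||% 42),
                width = ov_flag_num(p$flags$width, "width") %||% 800,
                height = ov_flag_num(p$flags$height, "height") %||% 600,
                path = p$flags$file)
  sprintf("wrote %s", p$flags$file)
}

ov_cmd_session <- function(argv, session) {
  if (length(argv) < 1 || !argv[[1]] %in% c("save", "load")) {
    ov_abort("usage: ov session {save|load} file=...", "usage_error")
  }
  p <- ov_parse_flags(argv[-1], "file")
  if (is.null(p$flags$file)) {
    ov_abort("session save/load requires file=...", "usage_error")
  }
  if (argv[[1]] == "save") {
    ov_save_session(session, p$flags$file)
    sprintf("session saved to %s", p$flags$file)
  } else {
    loaded <- ov_load_session(p$flags$file, client = session$client)
    for (field in c("tables", "networks", "connections", "active_table",
                    "active_network", "legend", "legend_params")) {
      assign(field, get(field, envir = loaded), envir = session)
    }
    sprintf("session loaded from %s (%d table(s), %d network(s))",
            p$flags$file, length(session$tables), length(session$networks))
  }
}

#' Command-line entry point
#'
#' Thin wrapper used by the `exec/ov` script: maintains a session file
#' across invocations (flag `--session path`, default `ov_session.json` in
#' the working directory) and forwards the remaining words to
#' [ov_run_command()].
#'
#' @param args Command-line words (default: `commandArgs(trailingOnly=TRUE)`).
#' @return The command's exit status, invisibly.
#' @export
ov_cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  session_path <- "ov_session.json"
  hit <- which(args == "--session")
  if (length(hit) > 0) {
    if (hit[1] == length(args)) {
      message("ov: --session needs a path")
      return(invisible(1L))
    }
    session_path <- args[hit[1] + 1L]
    args <- args[-c(hit[1], hit[1] + 1L)]
  }
  session <- if (file.exists(session_path)) {
    tryCatch(ov_load_session(session_path), ovglyph_error = function(e) {
      message("ov: ", conditionMessage(e))
      NULL
    })
  } else {
    ov_session()
  }
  if (is.null(session)) return(invisible(1L))
  res <- ov_run_command(args, session)
  if (res$status == 0L && !identical(args[1], "session")) {
    ov_save_session(session, session_path)
  }
  invisible(res$status)
}
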