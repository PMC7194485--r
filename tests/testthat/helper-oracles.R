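# Independent oracles and random-case generators shared by the unit and
# property tests. The oracles re-derive expected results by the most direct
# route available (per-row recursion, nested loops, channel-wise arithmetic)
# and never call the code paths they check.

# ---- brute-force filter evaluator ---------------------------------------
# materializes the truth value bottom-up for a single row of a plain
# data frame, with its own leaf semantics
oracle_eval <- function(expr, df, i) {
  if (!is.null(expr$connective)) {
    vals <- vapply(expr$children, oracle_eval, logical(1), df = df, i = i)
    if (expr$connective == "AND") return(all(vals))
    return(any(vals))
  }
  cell <- df[[expr$column]][i]
  op <- expr$operator
  if (op == "NULL") return(is.na(cell))
  if (op == "NOT_NULL") return(!is.na(cell))
  if (is.na(cell)) return(FALSE)
  o <- expr$operand
  if (is.numeric(cell)) o <- as.numeric(o)
  if (is.logical(cell)) o <- identical(tolower(o), "true")
  switch(op,
    EQUALS = cell == o,
    NOT_EQUALS = cell != o,
    CONTAINS = grepl(o, cell, fixed = TRUE),
    NOT_CONTAINS = !grepl(o, cell, fixed = TRUE),
    MATCHES = grepl(paste0("^(?:", o, ")$"), cell, perl = TRUE),
    LOWER = cell < o,
    LOWER_EQUALS = cell <= o,
    GREATER = cell > o,
    GREATER_EQUALS = cell >= o)
}

oracle_visible_rows <- function(expr, df) {
  which(vapply(seq_len(nrow(df)), function(i) oracle_eval(expr, df, i),
               logical(1)))
}

# ---- nested-loop join counter -------------------------------------------
oracle_join_rows <- function(node_keys, row_keys) {
  out <- vector("list", length(node_keys))
  for (n in seq_along(node_keys)) {
    hits <- integer()
    for (r in seq_along(row_keys)) {
      if (!is.na(node_keys[n]) && !is.na(row_keys[r]) &&
          node_keys[n] == row_keys[r]) {
        hits <- c(hits, r)
      }
    }
    out[[n]] <- hits
  }
  out
}

# ---- channel-wise color interpolation -----------------------------------
oracle_lerp <- function(from, to, t) {
  a <- grDevices::col2rgb(from)[, 1]
  b <- grDevices::col2rgb(to)[, 1]
  ch <- round(a + t * (b - a))
  sprintf("#%02X%02X%02X", ch[1], ch[2], ch[3])
}

# ---- random-case generators ---------------------------------------------
random_table <- function(n = 20, na_frac = 0.15) {
  num <- stats::rnorm(n)
  num[stats::runif(n) < na_frac] <- NA
  int <- sample.int(5L, n, replace = TRUE)
  int[stats::runif(n) < na_frac] <- NA
  str <- sample(c("alpha", "beta", "gamma", "de lta"), n, replace = TRUE)
  str[stats::runif(n) < na_frac] <- NA
  flag <- sample(c(TRUE, FALSE), n, replace = TRUE)
  flag[stats::runif(n) < na_frac] <- NA
  ov_table(tibble::tibble(num = num, int = as.integer(int), str = str,
                          flag = flag),
           name = "random")
}

random_criterion <- function(tab) {
  col <- sample(names(tab$data), 1)
  dtype <- ovglyph:::ov_dtype_of(tab$data[[col]])
  ops <- c("EQUALS", "NOT_EQUALS", "NULL", "NOT_NULL")
  if (dtype == "string") ops <- c(ops, "CONTAINS", "NOT_CONTAINS", "MATCHES")
  if (dtype %in% c("integer", "float")) {
    ops <- c(ops, "LOWER", "LOWER_EQUALS", "GREATER", "GREATER_EQUALS")
  }
  op <- sample(ops, 1)
  operand <- if (op %in% c("NULL", "NOT_NULL")) NULL else {
    switch(dtype,
      integer = as.character(sample.int(5L, 1)),
      float = as.character(round(stats::rnorm(1), 2)),
      boolean = sample(c("true", "false"), 1),
      string = if (op == "MATCHES") sample(c("al.*", "beta", "g[am]+a"), 1)
               else sample(c("a", "beta", "lt", "zzz"), 1))
  }
  ov_criterion(col, op, operand)
}

random_filter <- function(tab, depth = 2) {
  if (depth <= 0 || stats::runif(1) < 0.4) return(random_criterion(tab))
  kids <- lapply(seq_len(sample(1:3, 1)), function(i)
    random_filter(tab, depth - 1))
  ov_connective(sample(c("AND", "OR"), 1), kids)
}

random_chart <- function() {
  styles <- c("pie", "donut")
  style <- sample(styles, 1)
  n_rings <- if (style == "pie") 1L else sample(1:3, 1)
  arc <- round(stats::runif(1, 0, 359), 3)
  texts <- c("12", "a,b", "x|y", "p:q", "w;z", "50 %", "plain", NA)
  rings <- lapply(seq_len(n_rings), function(r) {
    k <- sample(1:5, 1)
    ring <- ovglyph:::ov_slice_angles(k, arc)
    ring$color <- toupper(sprintf("#%06X", sample.int(16777215, k)))
    ring$label <- sample(texts, k, replace = TRUE)
    ring$value <- sample(texts, k, replace = TRUE)
    ring
  })
  structure(
    list(node = sample(c("n1", "no de", "a|b"), 1), style = style,
         arc_start = arc,
         label_size = if (stats::runif(1) < 0.5) NULL else
           sample(c(11, 15), 1),
         rings = rings),
    class = "ov_chart")
}

# small worked-example pair: a site-level table and a matching node table,
# synthetic reconstructions of the published linking example (the P20700
# node is keyed to exactly two table rows)
example_tables <- function() {
  tab <- ov_table(tibble::tibble(
    UniProt = c("P20700", "Q15149", "P20700", "O43707", "Q09666"),
    `AA position` = c(23L, 4326L, 393L, 119L, 2301L),
    `EOC vs FTE` = c(-2.00, 1.34, -3.42, 0.89, -1.10),
    `EOC vs OSE` = c(-1.50, 0.12, -2.80, 1.65, -0.40),
    `Adj p-value` = c(0.001, 0.020, 0.004, 0.008, 0.300),
    Cluster = c("A", "B", "A", "C", "B")
  ), name = "sites")
  net <- ov_network(
    tibble::tibble(
      id = c("9606.n1", "9606.n2", "9606.n3", "9606.n4"),
      `query term` = c("P20700", "Q15149", "O43707", "P12814"),
      `display name` = c("LMNB1", "PLEC", "ACTN4", "ACTN1")),
    tibble::tibble(source = c("9606.n1", "9606.n2"),
                   target = c("9606.n2", "9606.n3")),
    name = "demo network")
  list(table = tab, network = net)
}

# run the printed automation workflow against generated fixtures; returns
# the session plus paths (used by CLI and acceptance tests)
run_demo_workflow <- function(seed = 11L, env = parent.frame(),
                              dir = withr::local_tempdir(.local_envir = env)) {
  withr::local_dir(dir, .local_envir = env)
  ov_write_fixtures(dir, seed = seed)
  s <- ov_session()
  cmds <- list(
    c("load", "file=sites.tsv"),
    c("filter", "filter=(Adj p-value,LOWER_EQUALS,0.01)"),
    c("retrieve", "taxonID=9606", "filteredOnly=true", "queryColumn=UniProt"),
    c("viz", "apply", "outer", "continuous",
      "attributes=EOC vs FTE,EOC vs OSE", "labels=AA position",
      "filteredOnly=true", "rangeMin=-8", "rangeMax=8",
      "chartSettings=arcstart:0,labelsize:15"),
    c("viz", "apply", "inner", "discrete", "attributes=Cluster",
      "labels=AA position",
      "colorMapping=A:#1F78B4,B:#FF7F00,C:#E31A1C",
      "filteredOnly=true", "chartSettings=arcstart:0,labelsize:15"),
    c("legend", "draw", "position=EAST_TOP", "title="),
    c("render", "file=out.svg", "seed=7"))
  statuses <- integer()
  for (cmd in cmds) {
    res <- NULL
    utils::capture.output(res <- ov_run_command(cmd, s))
    statuses <- c(statuses, res$status)
  }
  list(session = s, statuses = statuses, dir = dir)
}
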