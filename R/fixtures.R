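#' Generate a synthetic site-level table
#'
#' Emulates the shape of a site-specific phosphoproteomics result table: one
#' row per modification site, several rows per protein. Columns: `UniProt`
#' (accession-like key, letter plus digits), `AA position` (integer site
#' position), one log-ratio column per comparison (default `"EOC vs FTE"`
#' and `"EOC vs OSE"`, drawn from a centered normal with sd `effect_sd`),
#' `Adj p-value` (a fraction `frac_significant` of rows at or below 0.01)
#' and `Cluster` (letters `A`, `B`, ...). Site counts per protein are drawn
#' from a shifted Poisson (minimum 1), so every protein has at least one
#' row. Deterministic for a given seed.
#'
#' @param n_proteins Number of distinct proteins.
#' @param sites_per_protein Mean number of sites per protein (>= 1).
#' @param n_comparisons Number of log-ratio columns.
#' @param comparison_names Names of the log-ratio columns.
#' @param effect_sd Standard deviation of the log-ratios.
#' @param frac_significant Fraction of rows with `Adj p-value` <= 0.01.
#' @param n_clusters Number of cluster labels.
#' @param seed Random seed.
#' @return An [ov_table()].
#' @examples
#' tab <- ov_fixture_table(n_proteins = 10, seed = 7)
#' @export
ov_fixture_table <- function(n_proteins = 40, sites_per_protein = 2,
                             n_comparisons = 2,
                             comparison_names = c("EOC vs FTE", "EOC vs OSE"),
                             effect_sd = 2, frac_significant = 0.5,
                             n_clusters = 3, seed = 1L) {
  stopifnot(n_proteins >= 1, sites_per_protein >= 1, n_comparisons >= 1,
            frac_significant >= 0, frac_significant <= 1, n_clusters >= 1)
  if (length(comparison_names) < n_comparisons) {
    comparison_names <- c(comparison_names,
                          paste0("comparison ",
                                 seq_len(n_comparisons)))[seq_len(n_comparisons)]
  }
  comparison_names <- comparison_names[seq_len(n_comparisons)]
  withr::with_seed(as.integer(seed), {
    keys <- sprintf("P%05d", sample.int(99999, n_proteins))
    n_sites <- 1L + stats::rpois(n_proteins, sites_per_protein - 1)
    n <- sum(n_sites)
    data <- tibble(
      UniProt = rep(keys, n_sites),
      `AA position` = as.integer(unlist(purrr::map(
        n_sites, function(k) sort(sample.int(999, k))))))
    for (comparison in comparison_names) {
      data[[comparison]] <- stats::rnorm(n, mean = 0, sd = effect_sd)
    }
    sig <- stats::runif(n) < frac_significant
    data[["Adj p-value"]] <- ifelse(sig, stats::runif(n, 0, 0.01),
                                    stats::runif(n, 0.0101, 1))
    data[["Cluster"]] <- sample(LETTERS[seq_len(n_clusters)], n, replace = TRUE)
    ov_table(data, name = "synthetic sites")
  })
}

#' Generate a random network matched to a table
#'
#' One node per distinct key value of `key_column`, with the key stored in
#' the node attribute `"query term"` (and a `display name`), so the network
#' connects to the table exactly like a retrieved protein network would.
#' Edges are drawn independently with probability `edge_prob`
#' (Erdős–Rényi); deterministic for a given seed.
#'
#' @param table An [ov_table()].
#' @param key_column Table column holding the node keys (default
#'   auto-detected via [ov_detect_query_column()]).
#' @param edge_prob Edge probability in `[0, 1]`.
#' @param seed Random seed.
#' @param name Network name.
#' @return An [ov_network()].
#' @export
ov_fixture_network <- function(table, key_column = NULL, edge_prob = 0.1,
                               seed = 1L, name = "synthetic network") {
  stopifnot(inherits(table, "ov_table"),
            edge_prob >= 0, edge_prob <= 1)
  key_column <- key_column %||% ov_detect_query_column(table)
  if (is.null(key_column) || !key_column %in% names(table$data)) {
    ov_abort("key column not found in table", "schema_error")
  }
  keys <- unique(ov_render_text(table$data[[key_column]]))
  keys <- keys[!is.na(keys)]
  nodes <- tibble(id = paste0("node.", keys),
                  `query term` = keys,
                  `display name` = paste0("gene-", keys))
  edges <- ov_random_edges(nodes$id, edge_prob, as.integer(seed))
  ov_network(nodes, edges, name = name)
}

#' Write a matched fixture set to a directory
#'
#' Writes the table as TSV, the network as SIF, and the node attributes as a
#' sidecar TSV, so file-based import paths can be exercised end to end.
#'
#' @param dir Output directory (created if needed).
#' @param table An [ov_table()] (default: a generated one).
#' @param network An [ov_network()] (default: matched to `table`).
#' @param seed Seed forwarded to the default generators.
#' @return Named character vector of the three file paths.
#' @export
ov_write_fixtures <- function(dir, table = ov_fixture_table(seed = seed),
                              network = ov_fixture_network(table, seed = seed),
                              seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  table_path <- file.path(dir, "sites.tsv")
  sif_path <- file.path(dir, "network.sif")
  attr_path <- file.path(dir, "node_attributes.tsv")
  ov_write_table(table, table_path)
  sif <- c(
    sprintf("%s\tpp\t%s", network$edges$source, network$edges$target),
    setdiff(network$nodes$id, c(network$edges$source, network$edges$target)))
  writeLines(sif, sif_path)
  keep <- !startsWith(names(network$nodes), OV_NS)
  ov_write_table(ov_table(network$nodes[, keep, drop = FALSE]), attr_path)
  c(table = table_path, network = sif_path, attributes = attr_path)
}
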