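# The screening procedure: top-k hub ranking, dual-threshold hub-bottleneck
# selection, and extraction of the induced panel subnetwork.

#' Screening thresholds
#'
#' Defaults mirror the reference analysis: the 20 top nodes by degree are
#' hubs, and hubs with degree >= 60 and betweenness >= 0.03 (both inclusive)
#' are hub-bottlenecks.
#'
#' @param top_k Number of top-degree nodes taken as hubs.
#' @param degree_min Inclusive degree threshold for hub-bottlenecks.
#' @param bc_min Inclusive betweenness threshold, in \[0,1\].
#' @return An object of class `screen_config`.
#' @export
screen_config <- function(top_k = 20L, degree_min = 60L, bc_min = 0.03) {
  if (top_k < 1L) stop_arg("`top_k` must be >= 1")
  if (degree_min < 0L) stop_arg("`degree_min` must be >= 0")
  if (bc_min < 0 || bc_min > 1) stop_arg("`bc_min` must be in [0,1]")
  structure(list(top_k = as.integer(top_k), degree_min = degree_min,
                 bc_min = bc_min),
            class = "screen_config")
}

#' Select the top-k hub nodes of a centrality table
#'
#' Takes the first `top_k` rows of a degree-sorted table. The input row
#' order is preserved (a published table's printed order is authoritative);
#' an unsorted table is first stably ordered by degree descending. If the
#' cut would fall inside a group of rows tied at the boundary degree, that
#' tied group alone is reordered by betweenness descending then name
#' ascending before cutting, so the selection is deterministic.
#'
#' @param table A data frame in [centrality_table()] layout.
#' @param top_k Number of hubs to keep (table smaller than `top_k` is
#'   returned whole).
#' @return The selected rows, order preserved.
#' @export
select_hubs <- function(table, top_k = 20L) {
  if (top_k < 1L) stop_arg("`top_k` must be >= 1")
  if (nrow(table) == 0L) return(table)
  if (is.unsorted(-table$degree)) {
    table <- table[order(-table$degree), , drop = FALSE]  # stable sort
  }
  if (nrow(table) > top_k && table$degree[top_k] == table$degree[top_k + 1L]) {
    cut_deg <- table$degree[top_k]
    tied <- which(table$degree == cut_deg)
    block <- table[tied, , drop = FALSE]
    block <- block[order(-block$betweenness, block$name), , drop = FALSE]
    table[tied, ] <- block
  }
  out <- utils::head(table, top_k)
  rownames(out) <- NULL
  out
}

#' Dual-threshold hub-bottleneck selection
#'
#' Keeps rows with degree >= `degree_min` AND betweenness >= `bc_min`.
#' Both comparisons are inclusive — in the reference panel CTNNB1 passes at
#' betweenness exactly 0.03 — and the input order (degree rank) is
#' preserved.
#'
#' @param rows Hub rows, as from [select_hubs()].
#' @param degree_min,bc_min Inclusive thresholds.
#' @return The retained rows.
#' @export
select_hub_bottlenecks <- function(rows, degree_min = 60L, bc_min = 0.03) {
  keep <- rows$degree >= degree_min & rows$betweenness >= bc_min
  out <- rows[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Induced subnetwork on a node set
#'
#' Nodes are `members`; edges are all network edges with both endpoints in
#' `members`. Members absent from the network are retained as isolated
#' panel nodes with a warning.
#'
#' @param network A `ppi_network`.
#' @param members Character vector of node names.
#' @return A `ppi_network` on `members`.
#' @export
#' @examples
#' # any supergraph containing K7 over 7 members induces 21 edges
induced_subgraph <- function(network, members) {
  stopifnot(inherits(network, "ppi_network"))
  members <- unique(as.character(members))
  absent <- setdiff(members, network$nodes)
  if (length(absent) > 0L) {
    warning(length(absent), " member(s) not in the network kept as ",
            "isolated nodes: ", paste(absent, collapse = ", "),
            call. = FALSE)
  }
  e <- network$edges
  keep <- e$node_a %in% members & e$node_b %in% members
  sub <- e[keep, , drop = FALSE]
  rownames(sub) <- NULL
  attrs <- network$node_attrs
  if (!is.null(attrs)) attrs <- attrs[attrs$name %in% members, , drop = FALSE]
  new_network(sort(members), sub, attrs)
}

#' Run the full screen on a centrality table
#'
#' Applies [select_hubs()] then [select_hub_bottlenecks()], and, when the
#' source network is supplied, extracts the induced subnetwork of the
#' hub-bottleneck panel.
#'
#' @param table A [centrality_table()] data frame.
#' @param network Optional `ppi_network` the table was computed from.
#' @param config A [screen_config()].
#' @return An object of class `ppi_panel`: list with `hubs`,
#'   `hub_bottlenecks` (both row data frames) and `subnetwork` (a
#'   `ppi_network`, or `NULL` when no network was given).
#' @export
build_panel <- function(table, network = NULL, config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  hubs <- select_hubs(table, config$top_k)
  hb <- select_hub_bottlenecks(hubs, config$degree_min, config$bc_min)
  sub <- if (!is.null(network)) induced_subgraph(network, hb$name) else NULL
  structure(list(hubs = hubs, hub_bottlenecks = hb, subnetwork = sub,
                 config = config),
            class = "ppi_panel")
}

#' @export
print.ppi_panel <- function(x, ...) {
  cat(sprintf("ppi_panel: %d hubs -> %d hub-bottlenecks (degree >= %s, BC >= %s)\n",
              nrow(x$hubs), nrow(x$hub_bottlenecks),
              format(x$config$degree_min), format(x$config$bc_min)))
  if (nrow(x$hub_bottlenecks) > 0L) {
    cat("  panel:", paste(x$hub_bottlenecks$name, collapse = ", "), "\n")
  }
  if (!is.null(x$subnetwork)) {
    cat("  subnetwork:", length(x$subnetwork$nodes), "nodes,",
        n_edges(x$subnetwork), "edges\n")
  }
  invisible(x)
}

#' Write panel outputs (panel TSV, subnetwork edges TSV, summary JSON)
#'
#' @param panel A `ppi_panel`.
#' @param dir Output directory (created if needed).
#' @return Named vector of written paths, invisibly.
#' @export
write_panel <- function(panel, dir) {
  stopifnot(inherits(panel, "ppi_panel"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(panel = file.path(dir, "panel.tsv"),
             hubs = file.path(dir, "hubs.tsv"),
             summary = file.path(dir, "screen_summary.json"))
  write_tsv(panel$hub_bottlenecks, paths[["panel"]])
  write_tsv(panel$hubs, paths[["hubs"]])
  summary <- list(n_hubs = nrow(panel$hubs),
                  n_hub_bottlenecks = nrow(panel$hub_bottlenecks),
                  panel = panel$hub_bottlenecks$name,
                  degree_min = panel$config$degree_min,
                  bc_min = panel$config$bc_min)
  if (!is.null(panel$subnetwork)) {
    paths[["subnetwork"]] <- file.path(dir, "subnetwork_edges.tsv")
    write_tsv(panel$subnetwork$edges, paths[["subnetwork"]])
    summary$subnetwork_edges <- n_edges(panel$subnetwork)
  }
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(paths)
}
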