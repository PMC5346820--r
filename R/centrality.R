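# The three centrality parameters the screening procedure uses: degree K,
# betweenness BC and closeness CC. BC and CC are normalized into [0,1].

#' Degree centrality
#'
#' K(v) = number of edges incident to v. Isolated nodes have K = 0.
#'
#' @param network A `ppi_network`.
#' @return A named integer vector over all nodes.
#' @export
degree_centrality <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  deg <- stats::setNames(integer(length(network$nodes)), network$nodes)
  tab <- table(c(network$edges$node_a, network$edges$node_b))
  deg[names(tab)] <- as.integer(tab)
  deg
}

#' Betweenness centrality (Brandes accumulation)
#'
#' For node n, BC(n) sums over all node pairs \{s,t\} (s, t distinct from n)
#' the fraction of shortest s--t paths that pass through n as an interior
#' node. Computed by dependency accumulation over the BFS geodesic structure
#' (one BFS per source), never by explicit path enumeration. Normalization
#' divides by (N-1)(N-2)/2, the number of pairs a node can sit between,
#' which lands BC in \[0,1\].
#'
#' @param network A `ppi_network`.
#' @param normalized Divide by (N-1)(N-2)/2? Default `TRUE`.
#' @param scope `"component"` (default): N is the size of each node's own
#'   connected component, matching how network-analyzer tools report BC on a
#'   main component; `"graph"`: N is the total node count. Nodes whose scope
#'   holds fewer than 3 nodes get BC = 0.
#' @return A named numeric vector over all nodes.
#' @export
#' @examples
#' net <- build_network(data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
#'                                 score = 1), 0.5)
#' betweenness_centrality(net)  # B = 1, endpoints 0
betweenness_centrality <- function(network, normalized = TRUE,
                                   scope = c("component", "graph")) {
  stopifnot(inherits(network, "ppi_network"))
  scope <- match.arg(scope)
  nodes <- network$nodes
  adj <- adjacency_list(network)
  bc <- stats::setNames(numeric(length(nodes)), nodes)
  for (s in nodes) {
    g <- bfs_geodesics(adj, s)
    delta <- stats::setNames(numeric(length(nodes)), nodes)
    # accumulate dependencies in reverse BFS order
    for (w in rev(g$order)) {
      for (p in g$preds[[w]]) {
        delta[[p]] <- delta[[p]] +
          (g$sigma[[p]] / g$sigma[[w]]) * (1 + delta[[w]])
      }
      if (w != s) bc[[w]] <- bc[[w]] + delta[[w]]
    }
  }
  bc <- bc / 2  # each unordered pair {s,t} was accumulated from both ends
  if (normalized) {
    n_scope <- if (scope == "graph") {
      rep(length(nodes), length(nodes))
    } else {
      dec <- decompose_network(network)
      comp_size <- stats::setNames(
        rep(dec$sizes, lengths(dec$components)),
        unlist(dec$components))
      as.integer(comp_size[nodes])
    }
    denom <- (n_scope - 1) * (n_scope - 2) / 2
    bc <- ifelse(n_scope < 3L, 0, bc / denom)
    names(bc) <- nodes
  }
  bc
}

#' Closeness centrality
#'
#' Within a connected component of size m >= 2,
#' CC(v) = (m - 1) / sum of hop distances from v to the other members —
#' the inverse of the mean shortest-path length, which lies in \[0,1\].
#' Isolated nodes get CC = 0 by convention. Computed per component, so
#' adding isolated nodes never perturbs anyone else's closeness.
#'
#' @param network A `ppi_network`.
#' @return A named numeric vector over all nodes.
#' @export
closeness_centrality <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  nodes <- network$nodes
  adj <- adjacency_list(network)
  cc <- stats::setNames(numeric(length(nodes)), nodes)
  for (v in nodes) {
    g <- bfs_geodesics(adj, v)
    reach <- g$order[-1L]  # drop v itself
    if (length(reach) > 0L) {
      cc[[v]] <- length(reach) / sum(g$dist[reach])
    }
  }
  cc
}

#' Assemble the per-node centrality table
#'
#' One row per node with degree K, betweenness BC, closeness CC and the
#' disease score (when node annotations are attached), sorted by degree
#' descending with ties broken by BC descending then name ascending —
#' the layout of the published hub table.
#'
#' @param network A `ppi_network`, optionally carrying node annotations.
#' @param scope Betweenness normalization scope, see
#'   [betweenness_centrality()].
#' @return A data frame with columns `rank`, `name`, `description`,
#'   `degree`, `betweenness`, `closeness`, `disease_score`.
#' @export
centrality_table <- function(network, scope = c("component", "graph")) {
  stopifnot(inherits(network, "ppi_network"))
  scope <- match.arg(scope)
  nodes <- network$nodes
  if (length(nodes) == 0L) {
    return(data.frame(rank = integer(), name = character(),
                      description = character(), degree = integer(),
                      betweenness = numeric(), closeness = numeric(),
                      disease_score = numeric(), stringsAsFactors = FALSE))
  }
  deg <- degree_centrality(network)
  bc <- betweenness_centrality(network, normalized = TRUE, scope = scope)
  cc <- closeness_centrality(network)
  desc <- rep(NA_character_, length(nodes))
  dscore <- rep(NA_real_, length(nodes))
  if (!is.null(network$node_attrs)) {
    idx <- match(nodes, network$node_attrs$name)
    desc <- network$node_attrs$description[idx]
    dscore <- network$node_attrs$disease_score[idx]
  }
  tab <- data.frame(name = nodes, description = desc,
                    degree = as.integer(deg[nodes]),
                    betweenness = as.numeric(bc[nodes]),
                    closeness = as.numeric(cc[nodes]),
                    disease_score = dscore,
                    stringsAsFactors = FALSE)
  tab <- tab[order(-tab$degree, -tab$betweenness, tab$name), , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  tab
}

#' Read a centrality table from TSV
#'
#' Accepts the packaged published-table layout (`rank`, `name`,
#' `description`, `degree`, `betweenness`, `closeness`, `disease_score`);
#' the short column names `BC` and `CC` are also recognized. Row order is
#' preserved exactly as printed.
#'
#' @param path Path to a tab-separated centrality table.
#' @return A data frame in [centrality_table()] layout.
#' @export
read_centrality_table <- function(path) {
  if (!file.exists(path)) stop_arg("centrality table not found: ", path)
  tab <- read_tsv(path)
  lower <- tolower(names(tab))
  alias <- c(bc = "betweenness", cc = "closeness",
             "disease score" = "disease_score", k = "degree")
  hit <- lower %in% names(alias)
  names(tab)[hit] <- alias[lower[hit]]
  names(tab)[!hit] <- lower[!hit]
  needed <- c("name", "degree", "betweenness")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0L) {
    stop_arg("centrality table is missing column(s): ",
             paste(missing_cols, collapse = ", "))
  }
  for (col in c("description", "closeness", "disease_score")) {
    if (!col %in% names(tab)) tab[[col]] <- NA
  }
  if (!"rank" %in% names(tab)) tab$rank <- seq_len(nrow(tab))
  tab[, c("rank", "name", "description", "degree", "betweenness",
          "closeness", "disease_score")]
}

#' Write a centrality table to TSV
#'
#' @param table A [centrality_table()] data frame.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_centrality_table <- function(table, path) write_tsv(table, path)
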