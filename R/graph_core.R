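# Component decomposition and shortest-path machinery shared by the
# centrality and screening stages. Graphs are undirected and unweighted:
# distances are hop counts, and edge scores never enter any computation here.

# Adjacency list with deterministic (sorted) neighbour order.
adjacency_list <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  adj <- vector("list", length(network$nodes))
  names(adj) <- network$nodes
  for (v in network$nodes) adj[[v]] <- character()
  e <- network$edges
  if (nrow(e) > 0L) {
    nb <- split(c(e$node_b, e$node_a), c(e$node_a, e$node_b))
    for (v in names(nb)) adj[[v]] <- sort(nb[[v]])
  }
  adj
}

#' Connected-component decomposition
#'
#' Partitions a network into its connected components and reports the
#' bookkeeping the analysis relies on: how many nodes are isolated, how many
#' form pairs, and the size and edge count of the main (largest) component.
#' The reference gastric-adenocarcinoma network decomposes into 57 isolated
#' nodes, one pair, and a 141-node main component with 1508 edges.
#'
#' @param network A `ppi_network`.
#' @return An object of class `component_decomposition`: a list with
#'   `components` (list of sorted node vectors, largest first, ties broken by
#'   lexicographically smallest member), `sizes`, `n_isolated`, `n_pairs`,
#'   `main_component` and `main_edge_count`.
#' @export
decompose_network <- function(network) {
  stopifnot(inherits(network, "ppi_network"))
  nodes <- network$nodes
  if (length(nodes) == 0L) {
    return(structure(list(components = list(), sizes = integer(),
                          n_isolated = 0L, n_pairs = 0L,
                          main_component = character(),
                          main_edge_count = 0L),
                     class = "component_decomposition"))
  }
  adj <- adjacency_list(network)
  comp_id <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  k <- 0L
  for (start in nodes) {
    if (!is.na(comp_id[[start]])) next
    k <- k + 1L
    queue <- start
    comp_id[[start]] <- k
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      for (w in adj[[v]]) {
        if (is.na(comp_id[[w]])) {
          comp_id[[w]] <- k
          queue <- c(queue, w)
        }
      }
    }
  }
  comps <- split(nodes, comp_id)
  comps <- lapply(comps, sort)
  sizes <- lengths(comps)
  first_member <- vapply(comps, `[`, "", 1L)
  ord <- order(-sizes, first_member)
  comps <- unname(comps[ord])
  sizes <- unname(sizes[ord])
  main <- comps[[1L]]
  in_main <- network$edges$node_a %in% main & network$edges$node_b %in% main
  structure(list(components = comps,
                 sizes = sizes,
                 n_isolated = sum(sizes == 1L),
                 n_pairs = sum(sizes == 2L),
                 main_component = main,
                 main_edge_count = sum(in_main)),
            class = "component_decomposition")
}

#' @export
print.component_decomposition <- function(x, ...) {
  cat("component_decomposition:", length(x$components), "components |",
      x$n_isolated, "isolated,", x$n_pairs, "pair(s), main component of",
      length(x$main_component), "nodes /", x$main_edge_count, "edges\n")
  invisible(x)
}

# Breadth-first search from `source` over an adjacency list. Returns the
# visit order, hop distances, shortest-path counts (sigma) and the geodesic
# predecessor lists — the per-source structure Brandes' accumulation needs.
bfs_geodesics <- function(adj, source) {
  nodes <- names(adj)
  dist <- stats::setNames(rep(NA_integer_, length(nodes)), nodes)
  sigma <- stats::setNames(numeric(length(nodes)), nodes)
  preds <- stats::setNames(vector("list", length(nodes)), nodes)
  dist[[source]] <- 0L
  sigma[[source]] <- 1
  queue <- character(length(nodes))
  queue[1L] <- source
  head <- 1L; tail <- 1L
  order_visited <- character(0L)
  while (head <= tail) {
    v <- queue[[head]]
    head <- head + 1L
    order_visited <- c(order_visited, v)
    for (w in adj[[v]]) {
      if (is.na(dist[[w]])) {
        dist[[w]] <- dist[[v]] + 1L
        tail <- tail + 1L
        queue[[tail]] <- w
      }
      if (dist[[w]] == dist[[v]] + 1L) {
        sigma[[w]] <- sigma[[w]] + sigma[[v]]
        preds[[w]] <- c(preds[[w]], v)
      }
    }
  }
  list(order = order_visited, dist = dist, sigma = sigma, preds = preds)
}

#' Single-source shortest paths with geodesic counts
#'
#' Breadth-first hop distances from `source`, together with the number of
#' distinct shortest paths to each reachable node. Unreachable nodes are
#' absent from the result.
#'
#' @param network A `ppi_network`.
#' @param source A node in the network.
#' @return A list with named vectors `distance` (nonnegative integers) and
#'   `path_count` (positive counts), over reachable nodes only.
#' @export
#' @examples
#' net <- build_network(data.frame(node_a = c("A", "B"), node_b = c("B", "C"),
#'                                 score = 1), 0.5)
#' single_source_shortest_paths(net, "A")$distance  # A:0 B:1 C:2
single_source_shortest_paths <- function(network, source) {
  stopifnot(inherits(network, "ppi_network"))
  if (!source %in% network$nodes) {
    stop_arg("source node '", source, "' is not in the network")
  }
  res <- bfs_geodesics(adjacency_list(network), source)
  reach <- res$order
  list(distance = res$dist[reach], path_count = res$sigma[reach])
}
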