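# Independent oracles and small graph builders. Everything here deliberately
# avoids the package's own BFS/Brandes code paths: distances come from
# Floyd-Warshall, betweenness from explicit shortest-path enumeration,
# components from union-find, and hypergeometric tails from direct
# combinatorial sums (and, at tiny N, exhaustive draws).

net_from_edges <- function(a, b, nodes = NULL, score = 1) {
  rec <- data.frame(node_a = a, node_b = b,
                    score = rep_len(score, length(a)),
                    stringsAsFactors = FALSE)
  build_network(rec, score_cutoff = 0, node_universe = nodes)
}

complete_graph <- function(labels) {
  pr <- utils::combn(labels, 2L)
  net_from_edges(pr[1L, ], pr[2L, ])
}

path_graph <- function(labels) {
  n <- length(labels)
  net_from_edges(labels[-n], labels[-1L])
}

star_graph <- function(center, leaves) {
  net_from_edges(rep(center, length(leaves)), leaves)
}

cycle_graph <- function(labels) {
  n <- length(labels)
  net_from_edges(labels, labels[c(2:n, 1L)])
}

# Erdos-Renyi record list (all scores 1), optionally with isolated extras.
rand_records <- function(n, p, seed, prefix = "N") {
  withr::with_seed(seed, {
    labels <- sprintf("%s%03d", prefix, seq_len(n))
    pr <- utils::combn(labels, 2L)
    keep <- stats::runif(ncol(pr)) < p
    list(records = data.frame(node_a = pr[1L, keep], node_b = pr[2L, keep],
                              score = rep_len(1, sum(keep)),
                              stringsAsFactors = FALSE),
         labels = labels)
  })
}

rand_net <- function(n, p, seed) {
  r <- rand_records(n, p, seed)
  build_network(r$records, 0, node_universe = r$labels)
}

# All-pairs hop distances by Floyd-Warshall.
oracle_distances_fw <- function(net) {
  nodes <- net$nodes
  n <- length(nodes)
  D <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(D) <- 0
  for (i in seq_len(nrow(net$edges))) {
    a <- net$edges$node_a[i]; b <- net$edges$node_b[i]
    D[a, b] <- 1; D[b, a] <- 1
  }
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], `+`))
  D
}

# Connected components by union-find over the edge list.
oracle_components_unionfind <- function(net) {
  nodes <- net$nodes
  parent <- stats::setNames(nodes, nodes)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (i in seq_len(nrow(net$edges))) {
    ra <- find(net$edges$node_a[i]); rb <- find(net$edges$node_b[i])
    if (ra != rb) parent[[max(ra, rb)]] <- min(ra, rb)
  }
  roots <- vapply(nodes, find, "")
  unname(lapply(split(nodes, roots), sort))
}

# Normalized per-component betweenness by exhaustive enumeration of every
# shortest path (Floyd-Warshall distances + recursive geodesic expansion).
oracle_betweenness_enum <- function(net) {
  nodes <- net$nodes
  D <- oracle_distances_fw(net)
  adj <- lapply(stats::setNames(nodes, nodes), function(v) {
    c(net$edges$node_b[net$edges$node_a == v],
      net$edges$node_a[net$edges$node_b == v])
  })
  enumerate <- function(s, t) {
    if (s == t) return(list(s))
    preds <- adj[[t]][D[s, adj[[t]]] == D[s, t] - 1]
    out <- list()
    for (u in preds) {
      for (pth in enumerate(s, u)) out[[length(out) + 1L]] <- c(pth, t)
    }
    out
  }
  raw <- stats::setNames(numeric(length(nodes)), nodes)
  for (i in seq_along(nodes)) {
    for (j in seq_along(nodes)) {
      if (j <= i) next
      s <- nodes[[i]]; t <- nodes[[j]]
      if (!is.finite(D[s, t])) next
      paths <- enumerate(s, t)
      sigma <- length(paths)
      for (pth in paths) {
        interior <- pth[-c(1L, length(pth))]
        for (v in interior) raw[[v]] <- raw[[v]] + 1 / sigma
      }
    }
  }
  m <- rowSums(is.finite(D))  # component size per node
  ifelse(m < 3, 0, raw / ((m - 1) * (m - 2) / 2))
}

# Per-component closeness recomputed from Floyd-Warshall distances.
oracle_closeness_fw <- function(net) {
  D <- oracle_distances_fw(net)
  vapply(net$nodes, function(v) {
    d <- D[v, is.finite(D[v, ])]
    d <- d[names(d) != v]
    if (length(d) == 0L) 0 else length(d) / sum(d)
  }, 0)
}

# Right-tail hypergeometric by direct combinatorial sum.
oracle_hyper_sum <- function(k, K, n, N) {
  js <- k:min(K, n)
  sum(choose(K, js) * choose(N - K, n - js)) / choose(N, n)
}

# Right-tail hypergeometric by exhaustive enumeration of all C(N, n) draws.
oracle_hyper_draws <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # term genes are 1..K
  mean(hits >= k)
}

# Transitive closure of the kappa >= threshold relation (grouping oracle).
oracle_kappa_groups <- function(hit_sets, query, threshold) {
  m <- length(hit_sets)
  ind <- vapply(hit_sets, function(h) sort(query) %in% h,
                logical(length(query)))
  kap <- function(i, j) {
    x <- ind[, i]; y <- ind[, j]
    if (all(x == y)) return(1)
    po <- mean(x == y)
    pe <- mean(x) * mean(y) + mean(!x) * mean(!y)
    (po - pe) / (1 - pe)
  }
  R <- diag(m) > 0
  for (i in seq_len(m)) for (j in seq_len(m)) R[i, j] <- kap(i, j) >= threshold
  repeat {
    R2 <- R | (R %*% R > 0)
    if (identical(R2, R)) break
    R <- R2
  }
  unique(lapply(seq_len(m), function(i) which(R[i, ])))
}

expect_setequal_sorted <- function(x, y) expect_identical(sort(x), sort(y))
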