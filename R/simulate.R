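# Planted-structure synthetic data: interaction record lists whose filtered
# network has an exact component decomposition (isolated nodes, pairs, one
# main component of dense communities), planted high-degree hubs, planted
# bridge nodes that are the only connection between neighbouring communities
# (hence cut vertices with structurally large betweenness), sub-cutoff decoy
# records, and annotation term sets with a planted enriched term. Structure
# is constructed, not rejection-sampled, so requested counts hold exactly.

#' Specification for a synthetic interaction dataset
#'
#' Defaults emulate the reference network's shape: 200 genes of which 57
#' stay isolated and 2 form a pair, leaving a 141-node main component. The
#' main component consists of `n_communities` dense random communities
#' (each held together by a random spanning tree plus independent edges at
#' `intra_edge_prob`), joined in a chain by `n_communities - 1` planted
#' bridge nodes that attach to `bridge_stubs` members on each side and are
#' the sole inter-community connections. `n_planted_hubs` communities also
#' receive an intra-community hub wired up to `hub_target_degree`
#' neighbours. Retained-edge scores are Uniform(score_cutoff, 1); `n_decoys`
#' decoy records score Uniform(0, score_cutoff) and must be removed by the
#' confidence filter; a few above-cutoff self-loop records exercise
#' self-loop removal.
#'
#' The screening thresholds a recovery analysis should use sit between the
#' planted and background regimes and are reported in the generated ground
#' truth: `screen_degree_min` (default 25, versus planted degrees >= 35 and
#' background degrees around 8) and `screen_bc_min` (default 0.30, versus a
#' structural bridge-betweenness lower bound near 0.44 and intra-community
#' betweenness below ~0.11).
#'
#' @param n_nodes Total genes.
#' @param n_isolated Genes with no retained edge.
#' @param n_pair_nodes Genes forming size-2 components (must be even).
#' @param n_communities Number of dense communities (>= 2).
#' @param intra_edge_prob Independent intra-community edge probability.
#' @param n_planted_hubs Communities that receive an intra-community hub.
#' @param hub_target_degree Degree each planted hub is wired up to.
#' @param bridge_stubs Neighbours a bridge takes in each adjacent community.
#' @param score_cutoff Confidence cutoff the dataset is built around.
#' @param n_decoys Number of sub-cutoff decoy records.
#' @param screen_degree_min,screen_bc_min Planted screening thresholds.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_nodes = 200L, n_isolated = 57L,
                           n_pair_nodes = 2L, n_communities = 3L,
                           intra_edge_prob = 0.15, n_planted_hubs = 2L,
                           hub_target_degree = 35L, bridge_stubs = 20L,
                           score_cutoff = 0.5, n_decoys = 300L,
                           screen_degree_min = 25L, screen_bc_min = 0.30,
                           seed = 1L) {
  if (n_pair_nodes %% 2L != 0L) stop_arg("`n_pair_nodes` must be even")
  if (n_isolated + n_pair_nodes > n_nodes) {
    stop_arg("isolated + pair nodes exceed `n_nodes`")
  }
  if (n_communities < 2L) stop_arg("`n_communities` must be >= 2")
  if (intra_edge_prob < 0 || intra_edge_prob > 1) {
    stop_arg("`intra_edge_prob` must be in [0,1]")
  }
  if (score_cutoff < 0 || score_cutoff > 1) {
    stop_arg("`score_cutoff` must be in [0,1]")
  }
  if (n_planted_hubs > n_communities) {
    stop_arg("`n_planted_hubs` cannot exceed `n_communities`")
  }
  n_bridges <- n_communities - 1L
  main_n <- n_nodes - n_isolated - n_pair_nodes
  comm_n <- main_n - n_bridges
  if (comm_n < 2L * n_communities) {
    stop_arg("main component too small for ", n_communities, " communities")
  }
  min_comm <- comm_n %/% n_communities
  if (hub_target_degree >= min_comm) {
    stop_arg("`hub_target_degree` (", hub_target_degree,
             ") must be below the community size (", min_comm, ")")
  }
  if (bridge_stubs > min_comm) {
    stop_arg("`bridge_stubs` (", bridge_stubs,
             ") exceeds the community size (", min_comm, ")")
  }
  structure(list(n_nodes = as.integer(n_nodes),
                 n_isolated = as.integer(n_isolated),
                 n_pair_nodes = as.integer(n_pair_nodes),
                 n_communities = as.integer(n_communities),
                 intra_edge_prob = intra_edge_prob,
                 n_planted_hubs = as.integer(n_planted_hubs),
                 hub_target_degree = as.integer(hub_target_degree),
                 bridge_stubs = as.integer(bridge_stubs),
                 score_cutoff = score_cutoff,
                 n_decoys = as.integer(n_decoys),
                 screen_degree_min = as.integer(screen_degree_min),
                 screen_bc_min = screen_bc_min,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic interaction record list with ground truth
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `records` (a shuffled interaction record data frame
#'   ready for [build_network()]), `universe` (all gene symbols) and
#'   `truth`: `hub_nodes` (intra-community hubs and bridges),
#'   `bridge_nodes`, `hub_bottlenecks` (= bridges: the nodes that are both
#'   high-degree and high-betweenness by construction), `communities`,
#'   `isolated_nodes`, `pair_nodes` and the planted `screen` thresholds.
#' @export
generate_network <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_local_seed(spec$seed, {
    width <- max(3L, nchar(as.character(spec$n_nodes)))
    all_nodes <- sprintf(paste0("G%0", width, "d"), seq_len(spec$n_nodes))
    roles <- sample(all_nodes)
    n_bridges <- spec$n_communities - 1L
    isolated <- roles[seq_len(spec$n_isolated)]
    roles <- roles[-seq_len(spec$n_isolated)]
    pair_nodes <- roles[seq_len(spec$n_pair_nodes)]
    roles <- roles[-seq_len(spec$n_pair_nodes)]
    bridges <- roles[seq_len(n_bridges)]
    comm_members <- roles[-seq_len(n_bridges)]
    communities <- split(comm_members,
                         rep_len(seq_len(spec$n_communities),
                                 length(comm_members)))

    edge_a <- character(0L); edge_b <- character(0L)
    seen <- new.env(parent = emptyenv())
    add_edge <- function(u, v) {
      key <- paste(min(u, v), max(u, v), sep = "\r")
      if (is.null(seen[[key]])) {
        assign(key, TRUE, envir = seen)
        edge_a[[length(edge_a) + 1L]] <<- u
        edge_b[[length(edge_b) + 1L]] <<- v
        TRUE
      } else FALSE
    }

    for (comm in communities) {
      # spanning tree keeps the community connected
      for (i in seq_along(comm)[-1L]) {
        add_edge(comm[[i]], sample(comm[seq_len(i - 1L)], 1L))
      }
      pairs <- utils::combn(comm, 2L)
      draw <- stats::runif(ncol(pairs)) < spec$intra_edge_prob
      for (j in which(draw)) add_edge(pairs[1L, j], pairs[2L, j])
    }

    hubs <- character(0L)
    for (ci in seq_len(spec$n_planted_hubs)) {
      comm <- communities[[ci]]
      hub <- sample(comm, 1L)
      hubs <- c(hubs, hub)
      deg <- sum(edge_a == hub) + sum(edge_b == hub)
      candidates <- sample(setdiff(comm, hub))
      for (v in candidates) {
        if (deg >= spec$hub_target_degree) break
        if (add_edge(hub, v)) deg <- deg + 1L
      }
    }

    for (bi in seq_len(n_bridges)) {
      b <- bridges[[bi]]
      for (side in list(communities[[bi]], communities[[bi + 1L]])) {
        for (v in sample(side, spec$bridge_stubs)) add_edge(b, v)
      }
    }

    for (i in seq_len(spec$n_pair_nodes %/% 2L)) {
      add_edge(pair_nodes[[2L * i - 1L]], pair_nodes[[2L * i]])
    }

    lo <- spec$score_cutoff
    real <- data.frame(node_a = edge_a, node_b = edge_b,
                       score = lo + (1 - lo) * stats::runif(length(edge_a)),
                       stringsAsFactors = FALSE)
    decoy <- data.frame(
      node_a = sample(all_nodes, spec$n_decoys, replace = TRUE),
      node_b = sample(all_nodes, spec$n_decoys, replace = TRUE),
      score = lo * stats::runif(spec$n_decoys) * 0.999,
      stringsAsFactors = FALSE)
    decoy <- decoy[decoy$node_a != decoy$node_b, , drop = FALSE]
    loops <- data.frame(node_a = sample(all_nodes, 3L),
                        node_b = NA_character_,
                        score = lo + (1 - lo) * stats::runif(3L),
                        stringsAsFactors = FALSE)
    loops$node_b <- loops$node_a
    records <- rbind(real, decoy, loops)
    records <- records[sample(nrow(records)), , drop = FALSE]
    rownames(records) <- NULL

    list(records = records,
         universe = sort(all_nodes),
         truth = list(hub_nodes = sort(c(hubs, bridges)),
                      bridge_nodes = sort(bridges),
                      hub_bottlenecks = sort(bridges),
                      communities = lapply(communities, sort),
                      isolated_nodes = sort(isolated),
                      pair_nodes = sort(pair_nodes),
                      screen = list(top_k = 20L,
                                    degree_min = spec$screen_degree_min,
                                    bc_min = spec$screen_bc_min)))
  })
}

#' Generate annotation terms with a planted enriched signal
#'
#' Background terms draw genes uniformly from the universe; planted terms
#' contain a fixed number of the planted query genes by construction, plus
#' uniform filler genes. Defaults (6 of a 7-gene query inside a 30-gene
#' term against a ~200-gene background) give the planted term a
#' hypergeometric p-value around 5e-5, comfortably below the 0.001 bound,
#' while background terms pass all filters only at the false-positive rate
#' of the test itself.
#'
#' @param genes Gene universe (character vector).
#' @param planted_query The query gene set the signal is planted for.
#' @param n_terms Number of background terms.
#' @param n_planted Number of planted enriched terms.
#' @param planted_hits Query genes placed in each planted term.
#' @param planted_term_size Total size of each planted term.
#' @param term_size_range Background term sizes are drawn uniformly from
#'   this inclusive range.
#' @param seed Integer seed.
#' @return A list with `terms` (a list of [annotation_term()]; planted
#'   terms first, ids `PT1`, `PT2`, ...) and `planted` (data frame of
#'   planted term ids and their constructed hit counts).
#' @export
generate_annotations <- function(genes, planted_query, n_terms = 200L,
                                 n_planted = 1L, planted_hits = 6L,
                                 planted_term_size = 30L,
                                 term_size_range = c(10L, 60L),
                                 seed = 1L) {
  genes <- unique(as.character(genes))
  planted_query <- unique(as.character(planted_query))
  if (!all(planted_query %in% genes)) {
    stop_arg("`planted_query` must be a subset of `genes`")
  }
  if (planted_hits > length(planted_query)) {
    stop_arg("`planted_hits` exceeds the planted query size")
  }
  if (planted_term_size > length(genes)) {
    stop_arg("`planted_term_size` exceeds the gene universe")
  }
  if (max(term_size_range) > length(genes)) {
    stop_arg("`term_size_range` exceeds the gene universe")
  }
  with_local_seed(seed, {
    planted <- lapply(seq_len(n_planted), function(i) {
      hits <- sample(planted_query, planted_hits)
      fillers <- sample(setdiff(genes, planted_query),
                        planted_term_size - planted_hits)
      annotation_term(paste0("PT", i), c(hits, fillers),
                      name = paste0("planted_term_", i))
    })
    background <- lapply(seq_len(n_terms), function(i) {
      size <- sample(seq(term_size_range[1L], term_size_range[2L]), 1L)
      annotation_term(sprintf("T%04d", i), sample(genes, size),
                      name = sprintf("background_term_%04d", i))
    })
    list(terms = c(planted, background),
         planted = data.frame(
           term_id = vapply(planted, `[[`, "", "term_id"),
           n_planted_hits = rep_len(planted_hits, length(planted)),
           stringsAsFactors = FALSE))
  })
}
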