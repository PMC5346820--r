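# Top-k hub ranking, dual-threshold hub-bottleneck selection, induced
# panel subnetwork.

fixture <- read_centrality_table(table1_fixture())

test_that("top-k hub selection on the published table keeps printed order", {
  hubs <- select_hubs(fixture, 20L)
  expect_equal(nrow(hubs), 20L)
  expect_identical(hubs$name[1L], "TP53")
  expect_equal(hubs$degree[1L], 89L)
  expect_identical(hubs$name[20L], "KIT")
  expect_equal(hubs$degree[20L], 46L)
  expect_identical(select_hubs(fixture, 1L)$name, "TP53")
  # equal-degree rows stay in printed order (ALB before ERBB2 at K=69)
  expect_identical(hubs$name[3:4], c("ALB", "ERBB2"))
  # table smaller than top_k comes back whole
  expect_equal(nrow(select_hubs(fixture, 50L)), 20L)
  expect_error(select_hubs(fixture, 0L), ">= 1")
})

test_that("top-k selection on an unsorted table equals a sort-and-slice oracle", {
  tab <- data.frame(rank = 1:5, name = c("E", "B", "A", "D", "C"),
                    description = NA, degree = c(3L, 9L, 5L, 7L, 1L),
                    betweenness = c(0.1, 0.5, 0.2, 0.3, 0.05),
                    closeness = 0.5, disease_score = NA)
  top3 <- select_hubs(tab, 3L)
  oracle <- tab[order(-tab$degree), ][1:3, ]
  expect_identical(top3$name, oracle$name)
})

test_that("a boundary tie is broken by betweenness then name", {
  tab <- data.frame(rank = 1:4, name = c("W", "X", "Y", "Z"),
                    description = NA, degree = c(9L, 5L, 5L, 5L),
                    betweenness = c(0.5, 0.10, 0.30, 0.30),
                    closeness = 0.5, disease_score = NA)
  # cut falls inside the degree-5 group: keep higher BC, then smaller name
  expect_identical(select_hubs(tab, 2L)$name, c("W", "Y"))
  expect_identical(select_hubs(tab, 3L)$name, c("W", "Y", "Z"))
})

test_that("the dual-threshold screen reproduces the published panel", {
  panel <- select_hub_bottlenecks(fixture, 60L, 0.03)
  expect_identical(panel$name,
                   c("TP53", "EGFR", "ALB", "ERBB2", "AKT1", "SRC", "CTNNB1"))
  # CTNNB1 passes at BC exactly 0.03: comparisons are inclusive
  expect_true("CTNNB1" %in% panel$name)
  expect_equal(nrow(select_hub_bottlenecks(fixture, 0L, 0)), 20L)
  expect_equal(nrow(select_hub_bottlenecks(fixture, 90L, 0.5)), 0L)
})

test_that("screening is monotone in both thresholds", {
  base <- select_hub_bottlenecks(fixture, 60L, 0.03)$name
  for (dm in c(61L, 65L, 70L)) {
    expect_true(all(select_hub_bottlenecks(fixture, dm, 0.03)$name %in% base))
  }
  for (bm in c(0.04, 0.05, 0.08)) {
    expect_true(all(select_hub_bottlenecks(fixture, 60L, bm)$name %in% base))
  }
})

test_that("screening the full table at zero thresholds is the identity", {
  all_rows <- select_hubs(fixture, nrow(fixture))
  back <- select_hub_bottlenecks(all_rows, 0L, 0)
  expect_identical(back$name, fixture$name)
  expect_identical(back$degree, fixture$degree)
})

test_that("induced subgraph of 7 members of a complete graph is K7", {
  k10 <- complete_graph(LETTERS[1:10])
  sub <- induced_subgraph(k10, c("A", "C", "D", "F", "G", "I", "J"))
  expect_length(sub$nodes, 7L)
  expect_equal(nrow(sub$edges), 21L)
  expect_true(all(degree_centrality(sub) == 6L))
})

test_that("induced subgraph keeps only edges inside the member set", {
  net <- net_from_edges(c("A", "B", "C"), c("B", "C", "D"))
  expect_equal(nrow(induced_subgraph(net, c("A", "D"))$edges), 0L)
  for (seed in 1:3) {
    net <- rand_net(30, 0.2, seed)
    members <- withr::with_seed(seed, sample(net$nodes, 12))
    sub <- induced_subgraph(net, members)
    keys <- function(e) paste(e$node_a, e$node_b)
    # O(|members|^2) membership oracle
    pr <- utils::combn(sort(members), 2L)
    all_keys <- keys(net$edges)
    expected <- paste(pr[1L, ], pr[2L, ])[paste(pr[1L, ], pr[2L, ]) %in%
                                            all_keys]
    expect_setequal_sorted(keys(sub$edges), expected)
  }
  expect_warning(induced_subgraph(net, c(net$nodes[1L], "GHOST")),
                 "GHOST")
})

test_that("build_panel composes hubs, screen and subnetwork", {
  k7 <- complete_graph(c("TP53", "EGFR", "ALB", "ERBB2", "AKT1", "SRC",
                         "CTNNB1"))
  pan <- build_panel(fixture, network = k7,
                     config = screen_config(20L, 60L, 0.03))
  expect_equal(nrow(pan$hubs), 20L)
  expect_equal(nrow(pan$hub_bottlenecks), 7L)
  expect_equal(nrow(pan$subnetwork$edges), 21L)
  # every subnetwork edge joins two panel members
  expect_true(all(c(pan$subnetwork$edges$node_a,
                    pan$subnetwork$edges$node_b) %in%
                    pan$hub_bottlenecks$name))
})

test_that("planted bridges dominate betweenness and are recovered", {
  hits <- 0L
  for (seed in 1:5) {
    g <- generate_network(synthetic_spec(seed = seed))
    net <- build_network(g$records, 0.5, node_universe = g$universe)
    tab <- centrality_table(net)
    bc <- stats::setNames(tab$betweenness, tab$name)
    planted <- g$truth$bridge_nodes
    background <- setdiff(tab$name, planted)
    q95 <- stats::quantile(bc[background], 0.95)
    expect_true(all(bc[planted] > q95))
    pan <- build_panel(tab, config = screen_config(
      g$truth$screen$top_k, g$truth$screen$degree_min,
      g$truth$screen$bc_min))
    if (setequal(pan$hub_bottlenecks$name, g$truth$hub_bottlenecks)) {
      hits <- hits + 1L
    }
    # zero false negatives in every run
    expect_true(all(g$truth$hub_bottlenecks %in% pan$hub_bottlenecks$name))
  }
  expect_gte(hits, 4L)
})

test_that("panel outputs round-trip through the written files", {
  k7 <- complete_graph(c("TP53", "EGFR", "ALB", "ERBB2", "AKT1", "SRC",
                         "CTNNB1"))
  pan <- build_panel(fixture, network = k7)
  dir <- withr::local_tempdir()
  paths <- write_panel(pan, dir)
  expect_equal(nrow(utils::read.delim(paths[["panel"]])), 7L)
  expect_equal(nrow(utils::read.delim(paths[["subnetwork"]])), 21L)
  js <- jsonlite::read_json(paths[["summary"]])
  expect_equal(js$n_hub_bottlenecks, 7L)
  expect_equal(js$subnetwork_edges, 21L)
})
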