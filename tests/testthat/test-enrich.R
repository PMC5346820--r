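# Hypergeometric enrichment with ClueGO-style filters, kappa grouping and
# the group naming rule.

test_that("hypergeometric tail matches closed forms and validates bounds", {
  expect_equal(hypergeom_pvalue(2, 2, 2, 4), 1 / 6)
  expect_equal(hypergeom_pvalue(0, 10, 5, 20), 1)   # P(X >= 0) is certain
  expect_equal(hypergeom_pvalue(5, 5, 5, 5), 1)     # k = n, K = N
  expect_error(hypergeom_pvalue(3, 2, 5, 10), "bounds")
  expect_error(hypergeom_pvalue(1, 11, 5, 10), "bounds")
})

test_that("hypergeometric tail equals the combinatorial-sum oracle", {
  withr::with_seed(42, {
    for (i in 1:200) {
      N <- sample(2:30, 1)
      K <- sample(0:N, 1)
      n <- sample(0:N, 1)
      k <- sample(0:min(K, n), 1)
      expect_equal(hypergeom_pvalue(k, K, n, N),
                   oracle_hyper_sum(k, K, n, N), tolerance = 1e-12)
    }
  })
})

test_that("hypergeometric tail equals exhaustive draw enumeration at tiny N", {
  for (N in c(5, 7, 9)) {
    for (K in c(2, N %/% 2, N - 1)) {
      for (n in c(1, N %/% 2)) {
        for (k in 0:min(K, n)) {
          expect_equal(hypergeom_pvalue(k, K, n, N),
                       oracle_hyper_draws(k, K, n, N), tolerance = 1e-12)
        }
      }
    }
  }
})

test_that("the p-value never increases with more hits", {
  for (params in list(c(20, 10, 100), c(50, 7, 200), c(5, 5, 12))) {
    K <- params[1L]; n <- params[2L]; N <- params[3L]
    ps <- vapply(0:min(K, n), function(k) hypergeom_pvalue(k, K, n, N), 0)
    expect_true(all(diff(ps) <= 1e-15))
  }
})

make_term <- function(id, genes) annotation_term(id, genes)

test_that("a strong term passes the pathway filters with its attribution", {
  background <- sprintf("B%04d", 1:1000)
  query <- background[1:7]
  term <- make_term("T1", c(query[1:6], background[101:144]))  # 6 of 50
  res <- enrich_terms(query, list(term), background = background,
                      config = enrich_config("pathway"))
  expect_equal(nrow(res), 1L)
  expect_equal(res$attribution_pct, 12)
  expect_equal(res$n_hits, 6L)
  expect_lt(res$p_value, 0.001)
})

test_that("a 3-hit term is dropped under the pathway minimum regardless of p", {
  background <- sprintf("B%04d", 1:5000)
  query <- background[1:7]
  term <- make_term("T1", query[1:3])  # p astronomically small, 3 hits
  expect_lt(hypergeom_pvalue(3, 3, 7, 5000), 1e-8)
  res <- enrich_terms(query, list(term), background = background,
                      config = enrich_config("pathway"))
  expect_equal(nrow(res), 0L)
  # the same term passes the molecular-function preset (min 2 genes, 3%)
  res_mf <- enrich_terms(query, list(term), background = background,
                         config = enrich_config("molecular_function"))
  expect_equal(nrow(res_mf), 1L)
})

test_that("empty query warns and returns an empty result", {
  expect_warning(res <- enrich_terms(character(0),
                                     list(make_term("T1", c("A", "B")))),
                 "empty query")
  expect_equal(nrow(res), 0L)
})

test_that("query genes outside the background are dropped with a warning", {
  background <- sprintf("B%03d", 1:100)
  term <- make_term("T1", background[1:10])
  expect_warning(
    res <- enrich_terms(c(background[1:4], "NOT_THERE"), list(term),
                        background = background,
                        config = enrich_config("pathway", alpha = 0.05)),
    "NOT_THERE")
  expect_equal(res$n_hits, 4L)
})

test_that("tightening any filter never enlarges the retained set", {
  g <- generate_annotations(sprintf("G%03d", 1:200),
                            planted_query = sprintf("G%03d", 1:7),
                            n_terms = 120, seed = 9)
  query <- sprintf("G%03d", 1:7)
  base_cfg <- enrich_config("pathway", min_genes = 1L,
                            min_attribution_pct = 0, alpha = 0.5)
  base <- enrich_terms(query, g$terms, config = base_cfg)$term_id
  tighter <- list(
    enrich_config("pathway", min_genes = 3L, min_attribution_pct = 0,
                  alpha = 0.5),
    enrich_config("pathway", min_genes = 1L, min_attribution_pct = 10,
                  alpha = 0.5),
    enrich_config("pathway", min_genes = 1L, min_attribution_pct = 0,
                  alpha = 0.01))
  for (cfg in tighter) {
    expect_true(all(enrich_terms(query, g$terms,
                                 config = cfg)$term_id %in% base))
  }
})

test_that("BH adjustment is available behind the config flag", {
  background <- sprintf("B%03d", 1:60)
  query <- background[1:6]
  terms <- lapply(1:20, function(i) {
    make_term(sprintf("T%02d", i), background[seq(i, i + 14)])
  })
  raw <- enrich_terms(query, terms, background = background,
                      config = enrich_config("pathway", min_genes = 1L,
                                             min_attribution_pct = 0,
                                             alpha = 0.2))
  bh <- enrich_terms(query, terms, background = background,
                     config = enrich_config("pathway", min_genes = 1L,
                                            min_attribution_pct = 0,
                                            alpha = 0.2, p_adjust = "BH"))
  expect_true(all(bh$term_id %in% raw$term_id))
})

enriched_fixture <- function(hit_sets, query, sizes = NULL) {
  # build an enrich_terms()-shaped frame directly from hit sets
  n <- length(hit_sets)
  sizes <- sizes %||% (lengths(hit_sets) + 10L)
  out <- data.frame(term_id = sprintf("T%02d", seq_len(n)),
                    name = sprintf("term_%02d", seq_len(n)),
                    category = "pathway",
                    n_hits = lengths(hit_sets),
                    term_size = sizes,
                    attribution_pct = 100 * lengths(hit_sets) / sizes,
                    p_value = seq(1e-6, 1e-4, length.out = n),
                    stringsAsFactors = FALSE)
  out$hit_genes <- I(lapply(hit_sets, sort))
  out
}

test_that("identical hit sets group together, disjoint ones do not", {
  query <- LETTERS[1:6]
  same <- enriched_fixture(list(c("A", "B", "C"), c("A", "B", "C")), query)
  expect_length(group_terms(same, query), 1L)
  disjoint <- enriched_fixture(list(c("A", "B", "C"), c("D", "E", "F")),
                               query)
  expect_length(group_terms(disjoint, query), 2L)
})

test_that("grouping equals the transitive-closure oracle and partitions", {
  query <- LETTERS[1:8]
  withr::with_seed(31, {
    for (rep in 1:5) {
      hit_sets <- lapply(1:10, function(i) {
        sample(query, sample(2:6, 1))
      })
      enr <- enriched_fixture(hit_sets, query)
      groups <- group_terms(enr, query, kappa_threshold = 0.4)
      # partition: every term in exactly one group
      ids <- unlist(lapply(groups, `[[`, "term_ids"))
      expect_setequal_sorted(ids, enr$term_id)
      expect_equal(length(ids), length(unique(ids)))
      # same partition as brute-force closure over the kappa relation
      ord <- order(enr$p_value, -enr$attribution_pct, enr$term_id)
      oracle <- oracle_kappa_groups(enr$hit_genes[ord], query, 0.4)
      oracle_key <- sort(vapply(oracle, function(ix) {
        paste(sort(enr$term_id[ord][ix]), collapse = "|")
      }, ""))
      got_key <- sort(vapply(groups, function(g) {
        paste(sort(g$term_ids), collapse = "|")
      }, ""))
      expect_identical(got_key, oracle_key)
    }
  })
})

test_that("groups are named by max hits, then attribution, then name", {
  query <- LETTERS[1:10]
  g1 <- enriched_fixture(list(LETTERS[1:5], LETTERS[1:3]), query)
  expect_identical(name_group(g1), "term_01")  # 5 hits beats 3
  g2 <- enriched_fixture(list(LETTERS[1:4], LETTERS[1:4]), query,
                         sizes = c(40L, 28L))  # 10% vs ~14% attribution
  expect_identical(name_group(g2), "term_02")
  g3 <- enriched_fixture(list(LETTERS[1:2]), query)
  expect_identical(name_group(g3), "term_01")
})

test_that("the enrichment report flattens groups with labels", {
  query <- LETTERS[1:6]
  enr <- enriched_fixture(list(c("A", "B", "C"), c("A", "B", "C"),
                               c("D", "E", "F")), query)
  groups <- group_terms(enr, query)
  rep <- enrichment_report(groups)
  expect_equal(nrow(rep), 3L)
  expect_true(all(c("group_label", "hit_genes") %in% names(rep)))
  expect_type(rep$hit_genes, "character")
  gs <- attr(rep, "group_summary")
  expect_equal(sum(gs$n_terms), 3L)
})
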