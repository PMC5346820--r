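# ClueGO-style term enrichment on a query gene set: minimum-gene and
# attribution-percentage filters, right-tailed hypergeometric p-values,
# kappa-based term grouping, and the group naming rule.

#' Construct an annotation term
#'
#' @param term_id Term identifier.
#' @param genes Character vector of member gene symbols (deduplicated).
#' @param name Display name; defaults to the id.
#' @param category `"pathway"` or `"molecular_function"`.
#' @return An object of class `annotation_term`.
#' @export
annotation_term <- function(term_id, genes, name = term_id,
                            category = c("pathway", "molecular_function")) {
  category <- match.arg(category)
  genes <- unique(trimws(as.character(genes)))
  genes <- genes[nzchar(genes)]
  if (length(genes) == 0L) stop_arg("term '", term_id, "' has no genes")
  structure(list(term_id = term_id, name = name, category = category,
                 genes = genes),
            class = "annotation_term")
}

#' Enrichment filter settings
#'
#' Category presets follow the reference analysis: pathways must hold at
#' least 4 query genes at >= 4% attribution, molecular functions at least
#' 2 genes at >= 3%; in both cases the raw p-value must fall below 0.001.
#' Attribution percentage is 100 * (query genes in the term) / (term size).
#'
#' @param category Preset selector; explicit arguments override it.
#' @param min_genes Minimum query hits in a term.
#' @param min_attribution_pct Minimum attribution percentage.
#' @param alpha Strict p-value bound (terms with p < alpha are kept).
#' @param grouping_kappa Kappa threshold for term grouping, in \[0,1\].
#' @param p_adjust `"none"` (raw p, the reference behaviour) or `"BH"`
#'   (Benjamini-Hochberg across tested terms before the alpha filter).
#' @return An object of class `enrich_config`.
#' @export
enrich_config <- function(category = c("pathway", "molecular_function"),
                          min_genes = NULL, min_attribution_pct = NULL,
                          alpha = 0.001, grouping_kappa = 0.4,
                          p_adjust = c("none", "BH")) {
  category <- match.arg(category)
  p_adjust <- match.arg(p_adjust)
  min_genes <- min_genes %||% switch(category, pathway = 4L,
                                     molecular_function = 2L)
  min_attribution_pct <- min_attribution_pct %||%
    switch(category, pathway = 4, molecular_function = 3)
  if (min_genes < 0 || min_attribution_pct < 0) {
    stop_arg("filter thresholds must be nonnegative")
  }
  if (alpha <= 0 || alpha >= 1) stop_arg("`alpha` must be in (0,1)")
  if (grouping_kappa < 0 || grouping_kappa > 1) {
    stop_arg("`grouping_kappa` must be in [0,1]")
  }
  structure(list(category = category, min_genes = as.integer(min_genes),
                 min_attribution_pct = min_attribution_pct, alpha = alpha,
                 grouping_kappa = grouping_kappa, p_adjust = p_adjust),
            class = "enrich_config")
}

#' Right-tailed hypergeometric p-value
#'
#' P(X >= k) for X ~ hypergeometric(N, K, n): the chance of drawing at
#' least `k` of the `K` term genes in a query of size `n` from a background
#' of `N` genes. Evaluated through the stable log-space tail of the
#' hypergeometric distribution.
#'
#' @param k Observed hits, `0 <= k <= min(K, n)`.
#' @param K Term size within the background.
#' @param n Query size.
#' @param N Background size; `K, n <= N`.
#' @return The p-value in (0, 1].
#' @export
#' @examples
#' hypergeom_pvalue(2, 2, 2, 4)  # 1 / choose(4, 2) = 1/6
hypergeom_pvalue <- function(k, K, n, N) {
  ok <- k >= 0 & k <= pmin(K, n) & K <= N & n <= N & K >= 0 & n >= 0
  if (any(!ok)) {
    stop_arg("hypergeometric bounds violated: need 0 <= k <= min(K, n) ",
             "and K, n <= N")
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' ClueGO-style term enrichment
#'
#' Every term is intersected with the background, tested against the query
#' with a right-tailed hypergeometric test, and retained when it holds at
#' least `min_genes` query genes, its attribution percentage meets
#' `min_attribution_pct`, and its p-value falls below `alpha`. Results are
#' sorted by p ascending, then attribution descending, then term id.
#'
#' @param query Character vector of query gene symbols (the screened
#'   panel).
#' @param terms A list of [annotation_term()] objects.
#' @param background Background gene universe. Default: the union of all
#'   term genes (the reference analysis never states its universe; this is
#'   the conventional fallback).
#' @param config An [enrich_config()].
#' @return A data frame with one row per retained term: `term_id`, `name`,
#'   `category`, `n_hits`, `term_size`, `attribution_pct`, `p_value` and a
#'   list column `hit_genes`.
#' @export
enrich_terms <- function(query, terms, background = NULL,
                         config = enrich_config()) {
  stopifnot(inherits(config, "enrich_config"))
  empty <- data.frame(term_id = character(), name = character(),
                      category = character(), n_hits = integer(),
                      term_size = integer(), attribution_pct = numeric(),
                      p_value = numeric(), stringsAsFactors = FALSE)
  empty$hit_genes <- list()
  query <- unique(trimws(as.character(query)))
  if (length(query) == 0L) {
    warning("empty query gene set; no enrichment performed", call. = FALSE)
    return(empty)
  }
  if (is.null(background)) {
    background <- unique(unlist(lapply(terms, `[[`, "genes")))
  }
  background <- unique(trimws(as.character(background)))
  dropped <- setdiff(query, background)
  if (length(dropped) > 0L) {
    warning(length(dropped), " query gene(s) absent from the background ",
            "were dropped: ", paste(dropped, collapse = ", "),
            call. = FALSE)
    query <- intersect(query, background)
    if (length(query) == 0L) return(empty)
  }
  N <- length(background)
  n <- length(query)
  rows <- lapply(terms, function(tm) {
    genes <- intersect(tm$genes, background)
    if (length(genes) == 0L) return(NULL)
    hits <- intersect(query, genes)
    if (length(hits) == 0L) return(NULL)
    data.frame(term_id = tm$term_id, name = tm$name, category = tm$category,
               n_hits = length(hits), term_size = length(genes),
               attribution_pct = 100 * length(hits) / length(genes),
               p_value = hypergeom_pvalue(length(hits), length(genes), n, N),
               hit_genes = I(list(sort(hits))),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0L) return(empty)
  res <- do.call(rbind, rows)
  p_filter <- if (config$p_adjust == "BH") {
    stats::p.adjust(res$p_value, method = "BH")
  } else {
    res$p_value
  }
  keep <- res$n_hits >= config$min_genes &
    res$attribution_pct >= config$min_attribution_pct &
    p_filter < config$alpha
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$p_value, -res$attribution_pct, res$term_id), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

# Cohen's kappa between two binary membership vectors over the same genes.
# Identical vectors get kappa 1 (the chance-agreement denominator would
# otherwise vanish for two saturated raters).
cohen_kappa <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (all(x == y)) return(1)
  po <- mean(x == y)
  pe <- mean(x) * mean(y) + mean(!x) * mean(!y)
  (po - pe) / (1 - pe)
}

#' Group enriched terms by query-membership similarity
#'
#' Terms are compared by Cohen's kappa between their hit-membership
#' indicator vectors over the query genes; pairs at or above the threshold
#' are merged by single linkage (connected components of the kappa graph),
#' mirroring the grouping of similar enrichments into clusters. Input is
#' ordered by p-value first, so grouping is deterministic.
#'
#' @param enriched An [enrich_terms()] result.
#' @param query The query gene set the enrichment was run with.
#' @param kappa_threshold Merge threshold in \[0,1\] (default 0.4).
#' @return A list of groups; each group is a list with `label` (the
#'   representative term's name, see [name_group()]), `term_ids` and
#'   `members` (the member rows of `enriched`).
#' @export
group_terms <- function(enriched, query, kappa_threshold = 0.4) {
  query <- sort(unique(query))
  m <- nrow(enriched)
  if (m == 0L) return(list())
  enriched <- enriched[order(enriched$p_value, -enriched$attribution_pct,
                             enriched$term_id), , drop = FALSE]
  ind <- vapply(enriched$hit_genes, function(h) query %in% h,
                logical(length(query)))
  ind <- matrix(ind, nrow = length(query))
  # single-linkage union-find over pairs with kappa >= threshold
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (m > 1L) {
    for (i in seq_len(m - 1L)) {
      for (j in seq((i + 1L), m)) {
        if (cohen_kappa(ind[, i], ind[, j]) >= kappa_threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
        }
      }
    }
  }
  roots <- vapply(seq_len(m), find, 1L)
  groups <- lapply(sort(unique(roots)), function(r) {
    members <- enriched[roots == r, , drop = FALSE]
    rownames(members) <- NULL
    list(label = name_group(members), term_ids = members$term_id,
         members = members)
  })
  groups
}

#' Name a term group after its representative member
#'
#' The representative is the member with the most query hits; ties go to
#' the higher attribution percentage, then to the lexicographically
#' smallest name.
#'
#' @param members The member rows of one group (an [enrich_terms()]
#'   subset).
#' @return The representative term's name.
#' @export
name_group <- function(members) {
  if (nrow(members) == 0L) stop_arg("cannot name an empty group")
  ord <- order(-members$n_hits, -members$attribution_pct, members$name)
  members$name[ord[1L]]
}

#' Flatten grouped enrichment results for output
#'
#' @param groups A [group_terms()] result.
#' @return A data frame of all enriched terms with a `group_label` column
#'   (`hit_genes` collapsed to a `;`-separated string), plus one row per
#'   group in `attr(, "group_summary")` with member counts and mean
#'   attribution.
#' @export
enrichment_report <- function(groups) {
  if (length(groups) == 0L) {
    out <- data.frame(term_id = character(), name = character(),
                      category = character(), n_hits = integer(),
                      term_size = integer(), attribution_pct = numeric(),
                      p_value = numeric(), hit_genes = character(),
                      group_label = character(), stringsAsFactors = FALSE)
    attr(out, "group_summary") <- data.frame(group_label = character(),
                                             n_terms = integer(),
                                             max_hits = integer(),
                                             mean_attribution_pct = numeric())
    return(out)
  }
  rows <- do.call(rbind, lapply(groups, function(g) {
    df <- g$members
    df$hit_genes <- vapply(df$hit_genes, paste, "", collapse = ";")
    df$group_label <- g$label
    df
  }))
  rownames(rows) <- NULL
  attr(rows, "group_summary") <- do.call(rbind, lapply(groups, function(g) {
    data.frame(group_label = g$label, n_terms = nrow(g$members),
               max_hits = max(g$members$n_hits),
               mean_attribution_pct = mean(g$members$attribution_pct),
               stringsAsFactors = FALSE)
  }))
  rows
}
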