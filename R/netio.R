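#' Column mapping for interaction tables
#'
#' Describes how to read a STRING-style export: which columns hold the two
#' interactor symbols and the confidence score, and whether scores are on the
#' unit scale or STRING's integer 0--1000 scale.
#'
#' @param node_a,node_b Names of the two interactor columns.
#' @param score Name of the confidence-score column.
#' @param score_scale Either `1` (scores already in \[0,1\]) or `1000`
#'   (STRING integer scores, divided by 1000 on read).
#' @return An object of class `interaction_dialect`.
#' @export
#' @examples
#' interaction_dialect(score_scale = 1000)
interaction_dialect <- function(node_a = "protein1", node_b = "protein2",
                                score = "combined_score", score_scale = 1) {
  if (!score_scale %in% c(1, 1000)) {
    stop_arg("`score_scale` must be 1 or 1000, got ", score_scale)
  }
  structure(list(node_a = node_a, node_b = node_b, score = score,
                 score_scale = score_scale),
            class = "interaction_dialect")
}

#' Read scored interaction records from a TSV export
#'
#' Reads a tab-separated interaction table (one scored undirected edge
#' candidate per row) into a data frame of records. No filtering happens
#' here: self-pairs and duplicates are passed through untouched and resolved
#' by [build_network()].
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect An [interaction_dialect()] naming the columns.
#' @return A data frame with columns `node_a`, `node_b`, `score`
#'   (scores on the unit scale, symbols whitespace-trimmed).
#' @export
read_interactions <- function(path, dialect = interaction_dialect()) {
  if (!file.exists(path)) stop_arg("interaction file not found: ", path)
  raw <- read_tsv(path, colClasses = "character")
  if (nrow(raw) == 0L) {
    warning("interaction file has no data rows: ", path, call. = FALSE)
    return(data.frame(node_a = character(), node_b = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  }
  for (col in c(dialect$node_a, dialect$node_b, dialect$score)) {
    if (!col %in% names(raw)) {
      stop_arg("interaction file is missing column '", col, "': ", path)
    }
  }
  node_a <- trimws(raw[[dialect$node_a]])
  node_b <- trimws(raw[[dialect$node_b]])
  score <- suppressWarnings(as.numeric(raw[[dialect$score]]))
  bad <- which(is.na(score))
  if (length(bad) > 0L) {
    # +1 for the header row, so the message cites the file line.
    stop_arg("unparseable score '", raw[[dialect$score]][bad[1L]],
             "' on line ", bad[1L] + 1L, " of ", path)
  }
  if (dialect$score_scale == 1000) score <- score / 1000
  out_of_range <- which(score < 0 | score > 1)
  if (length(out_of_range) > 0L) {
    stop_arg("score out of [0,1] on line ", out_of_range[1L] + 1L,
             " of ", path)
  }
  empty <- which(node_a == "" | node_b == "")
  if (length(empty) > 0L) {
    stop_arg("empty gene symbol on line ", empty[1L] + 1L, " of ", path)
  }
  data.frame(node_a = node_a, node_b = node_b, score = score,
             stringsAsFactors = FALSE)
}

#' Write interaction records or a network back to the TSV dialect
#'
#' @param x A record data frame (as from [read_interactions()]) or a
#'   `ppi_network`; a network's retained edges are written with their scores.
#' @param path Output path.
#' @param dialect An [interaction_dialect()]; column names are taken from it
#'   and scores rescaled if `score_scale = 1000`.
#' @return The path, invisibly.
#' @export
write_interactions <- function(x, path, dialect = interaction_dialect()) {
  records <- if (inherits(x, "ppi_network")) x$edges else x
  out <- data.frame(a = records$node_a, b = records$node_b,
                    s = records$score, stringsAsFactors = FALSE)
  # full-precision scores so a network round-trips exactly through TSV
  out$s <- if (dialect$score_scale == 1000) {
    round(out$s * 1000)
  } else {
    sprintf("%.17g", out$s)
  }
  names(out) <- c(dialect$node_a, dialect$node_b, dialect$score)
  write_tsv(out, path)
}

#' Build a deduplicated undirected network at a confidence cutoff
#'
#' Applies the interaction-evidence cutoff (0.5 in the reference analysis),
#' drops self-loops, and collapses duplicate unordered pairs keeping the
#' maximum score. Edge scores are retained as metadata only; all downstream
#' centrality computations treat the graph as unweighted.
#'
#' @param records Data frame with columns `node_a`, `node_b`, `score`.
#' @param score_cutoff Minimum score (inclusive) for an edge to be retained,
#'   in \[0,1\].
#' @param node_universe Optional character vector of gene symbols that must
#'   all appear as nodes, so that genes with no retained edge are kept as
#'   isolated nodes (the reference network keeps 57 of them). When `NULL`,
#'   nodes are the endpoints of retained edges.
#' @return An object of class `ppi_network`: a list with sorted `nodes`, an
#'   `edges` data frame (`node_a < node_b`, one row per unordered pair, with
#'   `score`), and `node_attrs` (optional annotation data frame).
#' @export
#' @examples
#' rec <- data.frame(node_a = c("A", "B", "A", "B"),
#'                   node_b = c("B", "A", "A", "C"),
#'                   score = c(0.9, 0.7, 0.8, 0.4))
#' net <- build_network(rec, 0.5, node_universe = c("A", "B", "C", "D"))
#' net$edges  # single A-B edge at score 0.9; C and D isolated
build_network <- function(records, score_cutoff = 0.5, node_universe = NULL) {
  if (!is.numeric(score_cutoff) || length(score_cutoff) != 1L ||
      is.na(score_cutoff) || score_cutoff < 0 || score_cutoff > 1) {
    stop_arg("`score_cutoff` must be a single number in [0,1]")
  }
  a <- trimws(as.character(records$node_a))
  b <- trimws(as.character(records$node_b))
  s <- as.numeric(records$score)
  keep <- s >= score_cutoff & a != b
  a <- a[keep]; b <- b[keep]; s <- s[keep]
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  edges <- if (length(lo) > 0L) {
    key <- paste(lo, hi, sep = "\r")
    best <- tapply(s, key, max)
    parts <- strsplit(names(best), "\r", fixed = TRUE)
    data.frame(node_a = vapply(parts, `[`, "", 1L),
               node_b = vapply(parts, `[`, "", 2L),
               score = as.numeric(best),
               stringsAsFactors = FALSE)
  } else {
    data.frame(node_a = character(), node_b = character(),
               score = numeric(), stringsAsFactors = FALSE)
  }
  edges <- edges[order(edges$node_a, edges$node_b), , drop = FALSE]
  rownames(edges) <- NULL
  endpoints <- unique(c(edges$node_a, edges$node_b))
  nodes <- if (is.null(node_universe)) {
    endpoints
  } else {
    universe <- trimws(as.character(node_universe))
    extra <- setdiff(endpoints, universe)
    if (length(extra) > 0L) {
      warning(length(extra), " edge endpoint(s) outside the node universe ",
              "were added as nodes: ", paste(utils::head(extra, 5L),
                                             collapse = ", "),
              call. = FALSE)
    }
    union(universe, endpoints)
  }
  new_network(sort(nodes), edges)
}

new_network <- function(nodes, edges, node_attrs = NULL) {
  structure(list(nodes = nodes, edges = edges, node_attrs = node_attrs),
            class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat("ppi_network:", length(x$nodes), "nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

n_edges <- function(network) nrow(network$edges)

#' Attach per-node annotations (description, disease score) to a network
#'
#' @param network A `ppi_network`.
#' @param annotations Data frame with columns `name`, `description`,
#'   `disease_score` (as read by [read_node_annotations()]).
#' @return The network with `node_attrs` set.
#' @export
set_node_annotations <- function(network, annotations) {
  stopifnot(inherits(network, "ppi_network"))
  needed <- c("name", "description", "disease_score")
  missing_cols <- setdiff(needed, names(annotations))
  if (length(missing_cols) > 0L) {
    stop_arg("annotation table is missing column(s): ",
             paste(missing_cols, collapse = ", "))
  }
  if (any(annotations$disease_score < 0, na.rm = TRUE)) {
    stop_arg("disease scores must be nonnegative")
  }
  network$node_attrs <- annotations[, needed]
  network
}

#' Read a per-node annotation table
#'
#' @param path TSV with columns `name`, `description`, `disease_score`.
#' @return A data frame.
#' @export
read_node_annotations <- function(path) {
  if (!file.exists(path)) stop_arg("annotation file not found: ", path)
  ann <- read_tsv(path)
  ann$name <- trimws(ann$name)
  ann
}

#' Read annotation terms from a GMT file
#'
#' One term per line: term id, category/description, then one or more gene
#' symbols, tab-separated. Duplicate genes within a line are removed. A
#' second field of `pathway`, `molecular_function` or `MF` is interpreted as
#' the term category.
#'
#' @param path Path to a GMT file.
#' @return A list of [annotation_term()] objects.
#' @export
read_annotation_terms <- function(path) {
  if (!file.exists(path)) stop_arg("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  terms <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- trimws(strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]])
    if (length(fields) < 3L) {
      stop_arg("GMT line ", i, " has fewer than 3 fields (term id, ",
               "description, >=1 gene): ", path)
    }
    category <- switch(fields[2L],
                       "MF" = "molecular_function",
                       "molecular_function" = "molecular_function",
                       "pathway")
    terms[[i]] <- annotation_term(term_id = fields[1L],
                                  genes = unique(fields[-(1:2)]),
                                  category = category)
  }
  terms
}

#' Write annotation terms to a GMT file
#'
#' @param terms A list of [annotation_term()] objects.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_annotation_terms <- function(terms, path) {
  lines <- vapply(terms, function(tm) {
    paste(c(tm$term_id, tm$category, tm$genes), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
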