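# End-to-end pipeline driver: read -> build -> decompose -> centrality ->
# screen -> enrich, with every threshold logged and all tabular outputs
# written as TSV plus a JSON run summary. Also the screen-table shortcut
# that applies the dual-threshold filter directly to a printed centrality
# table (the packaged published hub table ships for exactly that).

#' Pipeline configuration
#'
#' @param interactions Path to the interaction TSV.
#' @param out_dir Output directory (created if needed).
#' @param node_annotations Optional path to a per-node annotation TSV
#'   (`name`, `description`, `disease_score`).
#' @param annotation_gmt Optional path to a GMT term file; enrichment runs
#'   only when it is given.
#' @param node_universe Optional character vector (or path to a one-symbol-
#'   per-line file) fixing the node set, so genes without retained edges
#'   stay in the network as isolated nodes.
#' @param score_cutoff Interaction-evidence cutoff (default 0.5).
#' @param dialect An [interaction_dialect()].
#' @param screen A [screen_config()].
#' @param enrich An [enrich_config()].
#' @param background Optional background gene vector for enrichment.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(interactions, out_dir,
                            node_annotations = NULL, annotation_gmt = NULL,
                            node_universe = NULL, score_cutoff = 0.5,
                            dialect = interaction_dialect(),
                            screen = screen_config(),
                            enrich = enrich_config(),
                            background = NULL) {
  if (is.character(node_universe) && length(node_universe) == 1L &&
      file.exists(node_universe)) {
    node_universe <- trimws(readLines(node_universe))
    node_universe <- node_universe[nzchar(node_universe)]
  }
  structure(list(interactions = interactions, out_dir = out_dir,
                 node_annotations = node_annotations,
                 annotation_gmt = annotation_gmt,
                 node_universe = node_universe,
                 score_cutoff = score_cutoff, dialect = dialect,
                 screen = screen, enrich = enrich,
                 background = background),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys mirror the [pipeline_config()] arguments; `dialect`,
#' `screen` and `enrich` may be nested maps of their constructors'
#' arguments.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop_arg("config file not found: ", path)
  y <- yaml::read_yaml(path)
  for (key in c("interactions", "out_dir")) {
    if (is.null(y[[key]])) stop_arg("config is missing '", key, "'")
  }
  pipeline_config(
    interactions = y$interactions,
    out_dir = y$out_dir,
    node_annotations = y$node_annotations,
    annotation_gmt = y$annotation_gmt,
    node_universe = y$node_universe,
    score_cutoff = y$score_cutoff %||% 0.5,
    dialect = do.call(interaction_dialect, y$dialect %||% list()),
    screen = do.call(screen_config, y$screen %||% list()),
    enrich = do.call(enrich_config, y$enrich %||% list()),
    background = y$background)
}

run_stage <- function(stage, log, expr) {
  log(paste0("[", stage, "] start"))
  tryCatch(expr, error = function(e) {
    stop_arg("pipeline stage '", stage, "' failed: ", conditionMessage(e))
  })
}

#' Run the full screening pipeline
#'
#' Executes read -> build -> decompose -> centrality -> screen (and
#' enrichment when a GMT file is configured), writes all outputs under
#' `config$out_dir`, and returns a run summary whose counts are recomputed
#' from the written files.
#'
#' @param config A [pipeline_config()].
#' @param quiet Suppress the stage log (messages to stderr)?
#' @return A list summarizing the run (also written as `summary.json`).
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  log <- if (quiet) function(...) invisible() else function(msg) message(msg)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$out_dir, f)

  records <- run_stage("read", log,
                       read_interactions(config$interactions, config$dialect))
  log(sprintf("[read] %d interaction records", nrow(records)))

  net <- run_stage("build", log,
                   build_network(records, config$score_cutoff,
                                 config$node_universe))
  log(sprintf("[build] cutoff %.3f -> %d nodes, %d edges",
              config$score_cutoff, length(net$nodes), n_edges(net)))
  if (!is.null(config$node_annotations)) {
    net <- run_stage("annotate", log,
                     set_node_annotations(
                       net, read_node_annotations(config$node_annotations)))
  }
  write_tsv(net$edges, out("network_edges.tsv"))

  dec <- run_stage("decompose", log, decompose_network(net))
  log(sprintf("[decompose] %d isolated, %d pair(s), main component %d/%d",
              dec$n_isolated, dec$n_pairs, length(dec$main_component),
              dec$main_edge_count))

  tab <- run_stage("centrality", log, centrality_table(net))
  write_centrality_table(tab, out("centrality.tsv"))

  panel <- run_stage("screen", log,
                     build_panel(tab, network = net, config = config$screen))
  log(sprintf("[screen] top_k=%d, degree>=%s, BC>=%s -> %d hub-bottlenecks",
              config$screen$top_k, config$screen$degree_min,
              config$screen$bc_min, nrow(panel$hub_bottlenecks)))
  write_panel(panel, config$out_dir)

  enrichment <- NULL
  if (!is.null(config$annotation_gmt)) {
    enrichment <- run_stage("enrich", log, {
      terms <- read_annotation_terms(config$annotation_gmt)
      enr <- enrich_terms(panel$hub_bottlenecks$name, terms,
                          background = config$background,
                          config = config$enrich)
      groups <- group_terms(enr, panel$hub_bottlenecks$name,
                            config$enrich$grouping_kappa)
      report <- enrichment_report(groups)
      write_tsv(report, out("enriched_terms.tsv"))
      write_tsv(attr(report, "group_summary"), out("term_groups.tsv"))
      report
    })
    log(sprintf("[enrich] %d term(s) retained in %d group(s)",
                nrow(enrichment),
                length(unique(enrichment$group_label))))
  }

  summary <- list(
    n_records = nrow(read_tsv(config$interactions)),
    score_cutoff = config$score_cutoff,
    n_nodes = length(net$nodes),
    n_edges = nrow(read_tsv(out("network_edges.tsv"))),
    n_isolated = dec$n_isolated,
    n_pairs = dec$n_pairs,
    main_component_size = length(dec$main_component),
    main_component_edges = dec$main_edge_count,
    n_hubs = nrow(read_tsv(out("hubs.tsv"))),
    n_hub_bottlenecks = nrow(read_tsv(out("panel.tsv"))),
    panel = panel$hub_bottlenecks$name,
    subnetwork_edges = if (!is.null(panel$subnetwork)) {
      nrow(read_tsv(out("subnetwork_edges.tsv")))
    } else NULL,
    n_enriched_terms = if (!is.null(enrichment)) nrow(enrichment) else NULL,
    n_term_groups = if (!is.null(enrichment)) {
      length(unique(enrichment$group_label))
    } else NULL)
  jsonlite::write_json(summary, out("summary.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  log("[done] summary.json written")
  invisible(summary)
}

#' Screen a printed centrality table directly
#'
#' Bypasses network construction and applies the dual-threshold
#' hub-bottleneck filter to a centrality table TSV — the route used on the
#' packaged published 20-hub table, whose screen must return the seven-gene
#' panel.
#'
#' @param path Path to a centrality-table TSV (see
#'   [read_centrality_table()]).
#' @param degree_min,bc_min Inclusive thresholds (defaults 60 and 0.03).
#' @param top_k Optional hub cut applied before the threshold filter.
#' @return The retained rows, printed order preserved.
#' @export
#' @examples
#' fixture <- system.file("extdata", "table1_hubs.tsv", package = "ppipanel")
#' screen_table(fixture)$name  # the seven-gene panel
screen_table <- function(path, degree_min = 60L, bc_min = 0.03,
                         top_k = NULL) {
  tab <- read_centrality_table(path)
  if (!is.null(top_k)) tab <- select_hubs(tab, top_k)
  select_hub_bottlenecks(tab, degree_min, bc_min)
}

#' Path to the packaged published hub table
#'
#' The 20-row hub table of the reference gastric-adenocarcinoma analysis
#' (name, description, degree, betweenness, closeness, disease score),
#' transcribed verbatim, in printed order.
#'
#' @return A file path.
#' @export
table1_fixture <- function() {
  system.file("extdata", "table1_hubs.tsv", package = "ppipanel",
              mustWork = TRUE)
}
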