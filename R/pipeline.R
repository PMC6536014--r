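# End-to-end pipeline runs backing the command-line interface. Every run
# logs each cascade stage with in/out counts and writes a machine-readable
# run manifest sufficient to reproduce the outputs exactly.

#' Run the full screening pipeline
#'
#' Reads a gene list and a scored edge table, induces the query network,
#' decomposes it into components, runs the screening cascade, and writes all
#' artifacts to `out_dir`: a network summary, the full-precision centrality
#' table, the structured screening result, a ranked central-node report in
#' the standard R/name/description/D/BC/CC/Stress layout, and a run
#' manifest. Outputs are deterministic: the same inputs and configuration
#' yield byte-identical files.
#'
#' @param genes Path to the query gene list.
#' @param edges Path to the scored edge table.
#' @param out_dir Output directory (created if missing).
#' @param score_threshold Minimum combined score for an edge (default 400).
#' @param config A [screening_config()].
#' @param annotations Optional two-column TSV path (gene, description) for
#'   the report's description column.
#' @return Invisibly, a list with the `ppi_screen` result, the network, the
#'   unrecognized genes, and the output paths.
#' @export
run_screen_pipeline <- function(genes, edges, out_dir, score_threshold = 400,
                                config = screening_config(),
                                annotations = NULL) {
  gene_list <- read_gene_list(genes)
  message(sprintf("query genes: %d", length(gene_list)))
  universe <- read_edge_table(edges, score_threshold = score_threshold)
  message(sprintf("edge universe: %d nodes, %d edges (score >= %s)",
                  n_nodes(universe), n_edges(universe), format(score_threshold)))
  built <- build_network(gene_list, universe)
  net <- built$network
  message(sprintf("recognized: %d of %d query genes (%d unrecognized)",
                  n_nodes(net), length(gene_list), length(built$unrecognized)))
  parts <- network_components(net)
  main_size <- if (length(parts$sizes)) parts$sizes[[parts$main_index]] else 0L
  main_net <- main_component(net)
  message(sprintf("components: %d, main component %d nodes / %d edges, %d isolated",
                  length(parts$components), main_size, n_edges(main_net),
                  sum(parts$sizes == 1L)))
  screen <- screen_network(net, config)
  message(sprintf("hubs: %d, bottlenecks: %d, hub-bottlenecks: %d, central: %d",
                  length(screen$hubs), length(screen$bottlenecks),
                  length(screen$hub_bottlenecks), length(screen$central_nodes)))

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ann <- if (is.null(annotations)) NULL else
    utils::read.delim(annotations, header = FALSE, stringsAsFactors = FALSE)
  paths <- c(
    summary = file.path(out_dir, "network_summary.txt"),
    metrics = file.path(out_dir, "centrality_table.tsv"),
    screening = file.path(out_dir, "screening.txt"),
    report = file.path(out_dir, "central_report.tsv"),
    manifest = file.path(out_dir, "run_manifest.txt")
  )
  writeLines(c(
    sprintf("query_genes\t%d", length(gene_list)),
    sprintf("recognized\t%d", n_nodes(net)),
    sprintf("unrecognized\t%d", length(built$unrecognized)),
    sprintf("unrecognized_genes\t%s", paste(built$unrecognized, collapse = ",")),
    sprintf("components\t%d", length(parts$components)),
    sprintf("isolated\t%d", sum(parts$sizes == 1L)),
    sprintf("main_component_nodes\t%d", main_size),
    sprintf("main_component_edges\t%d", n_edges(main_net))
  ), paths[["summary"]])
  write_centrality_table(screen$metrics, paths[["metrics"]])
  write_screening_result(screen, paths[["screening"]])
  central_metrics <- screen$metrics[screen$metrics$gene %in% screen$central_nodes, ,
                                    drop = FALSE]
  if (nrow(central_metrics) > 0L) {
    write_metrics_report(central_metrics, paths[["report"]], ranked_by = "degree",
                         annotations = ann)
  } else {
    writeLines("R\tname\tdescription\tD\tBC\tCC\tStress", paths[["report"]])
  }
  write_run_manifest(paths[["manifest"]], c(
    command = "screen",
    genes = genes,
    edges = edges,
    score_threshold = format(score_threshold),
    hub_fraction = format(config$hub_fraction),
    bottleneck_k = format(config$bottleneck_k),
    crossval_k = if (is.null(config$crossval_k)) "auto" else format(config$crossval_k),
    scope = config$scope,
    expand_ties = format(config$expand_ties)
  ))
  invisible(list(screen = screen, network = net,
                 unrecognized = built$unrecognized, paths = paths))
}

#' Run a metrics-only pipeline
#'
#' Reads an edge table and writes the full-precision centrality table,
#' without screening.
#'
#' @param edges Path to the scored edge table.
#' @param out Path of the output TSV.
#' @param score_threshold Minimum combined score (default 400).
#' @param scope `"whole_network"` (default) or `"main_component"`.
#' @return Invisibly, the `centrality_table`.
#' @export
run_metrics_pipeline <- function(edges, out, score_threshold = 400,
                                 scope = c("whole_network", "main_component")) {
  scope <- match.arg(scope)
  net <- read_edge_table(edges, score_threshold = score_threshold)
  if (scope == "main_component") net <- main_component(net)
  table <- node_metrics(net)
  message(sprintf("metrics: %d nodes (%s)", nrow(table), scope))
  dir.create(dirname(out), showWarnings = FALSE, recursive = TRUE)
  write_centrality_table(table, out)
  invisible(table)
}

#' Generate and write a synthetic fixture directory
#'
#' @param dir Output directory.
#' @param n_connected,attachment,n_isolated,n_planted,planted_coverage,seed
#'   Passed to [synthetic_network_spec()].
#' @return Invisibly, the named vector of fixture paths.
#' @export
simulate_fixture <- function(dir, n_connected, attachment = 2L,
                             n_isolated = 0L, n_planted = 0L,
                             planted_coverage = 0.5, seed = 1L) {
  spec <- synthetic_network_spec(n_connected, attachment, n_isolated,
                                 n_planted, planted_coverage, seed)
  out <- generate_network(spec)
  message(sprintf("simulated network: %d nodes, %d edges, %d planted",
                  n_nodes(out$network), n_edges(out$network),
                  length(out$truth$planted_nodes)))
  invisible(write_fixture(out$network, out$truth, dir))
}

#' Write a full-precision centrality table TSV
#'
#' @param table A `centrality_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_centrality_table <- function(table, path) {
  lines <- c(
    "gene\tdegree\tbetweenness\tcloseness\tstress\tcomponent_size",
    sprintf("%s\t%d\t%s\t%s\t%d\t%d",
            table$gene, table$degree,
            sprintf("%.12g", table$betweenness),
            sprintf("%.12g", table$closeness),
            table$stress, table$component_size)
  )
  writeLines(lines, path)
  invisible(path)
}

write_run_manifest <- function(path, fields) {
  fields <- c(fields, package_version = as.character(utils::packageVersion("ppiscreen")),
              r_version = paste(R.version$major, R.version$minor, sep = "."))
  writeLines(sprintf("%s\t%s", names(fields), fields), path)
  invisible(path)
}
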