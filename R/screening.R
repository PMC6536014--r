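# The selection cascade: hubs by top degree fraction, bottlenecks by top-k
# betweenness, hub-bottlenecks as their intersection, and central nodes as
# the hub-bottlenecks cross-validated against the top closeness and top
# stress lists.

#' Screening cascade configuration
#'
#' All thresholds of the hub / bottleneck / central-node selection cascade.
#'
#' @param hub_fraction Fraction in `(0, 1]` of nodes (by degree) selected as
#'   hubs; `max(1, floor(hub_fraction * n))` nodes are taken. Default 0.10.
#' @param bottleneck_k Number of top-betweenness nodes selected as
#'   bottlenecks. Default 10.
#' @param crossval_k Size of the top closeness and top stress lists used to
#'   cross-validate hub-bottlenecks into central nodes. `NULL` (default)
#'   means "the size of the hub set".
#' @param scope Compute metrics on the `"main_component"` (default) or the
#'   `"whole_network"`.
#' @param expand_ties If `TRUE`, nodes tied with the last selected node are
#'   included in every top list; if `FALSE` (default) ties at the cutoff are
#'   broken by symbol ascending.
#' @return An object of class `screening_config`.
#' @export
screening_config <- function(hub_fraction = 0.10, bottleneck_k = 10,
                             crossval_k = NULL,
                             scope = c("main_component", "whole_network"),
                             expand_ties = FALSE) {
  scope <- match.arg(scope)
  if (!is.numeric(hub_fraction) || length(hub_fraction) != 1L ||
      is.na(hub_fraction) || hub_fraction <= 0 || hub_fraction > 1) {
    ppis_config_error("'hub_fraction' must be a single value in (0, 1]")
  }
  if (!is.numeric(bottleneck_k) || length(bottleneck_k) != 1L ||
      is.na(bottleneck_k) || bottleneck_k < 1) {
    ppis_config_error("'bottleneck_k' must be a positive integer")
  }
  if (!is.null(crossval_k) &&
      (!is.numeric(crossval_k) || length(crossval_k) != 1L ||
       is.na(crossval_k) || crossval_k < 1)) {
    ppis_config_error("'crossval_k' must be NULL or a positive integer")
  }
  structure(
    list(
      hub_fraction = hub_fraction,
      bottleneck_k = as.integer(bottleneck_k),
      crossval_k = if (is.null(crossval_k)) NULL else as.integer(crossval_k),
      scope = scope,
      expand_ties = isTRUE(expand_ties)
    ),
    class = "screening_config"
  )
}

#' @export
print.screening_config <- function(x, ...) {
  cat("screening_config:\n")
  cat(sprintf("  hub_fraction: %s\n", format(x$hub_fraction)))
  cat(sprintf("  bottleneck_k: %d\n", x$bottleneck_k))
  cat(sprintf("  crossval_k:   %s\n",
              if (is.null(x$crossval_k)) "hub-set size" else x$crossval_k))
  cat(sprintf("  scope:        %s\n", x$scope))
  cat(sprintf("  expand_ties:  %s\n", x$expand_ties))
  invisible(x)
}

#' Select the top fraction of nodes by a metric
#'
#' Selects `max(1, floor(fraction * n))` genes with the highest value of the
#' given metric. Ties at the cutoff are broken by symbol ascending unless
#' `expand_ties`, in which case every gene tied with the cutoff value is
#' included.
#'
#' @param table A `centrality_table` (non-empty).
#' @param metric One of `"degree"`, `"betweenness"`, `"closeness"`,
#'   `"stress"`.
#' @param fraction Fraction of nodes in `(0, 1]`.
#' @param expand_ties Include all cutoff-tied genes (default `FALSE`).
#' @return Character vector of gene symbols ordered by rank (metric
#'   descending, symbol ascending).
#' @export
select_top_fraction <- function(table, metric, fraction, expand_ties = FALSE) {
  if (NROW(table) == 0L) ppis_config_error("centrality table is empty")
  k <- max(1L, floor(fraction * nrow(table)))
  select_top_k(table, metric, k, expand_ties)
}

#' Select the top k nodes by a metric
#'
#' @param table A `centrality_table`.
#' @param metric One of `"degree"`, `"betweenness"`, `"closeness"`,
#'   `"stress"`.
#' @param k Number of genes to select (capped at the node count).
#' @param expand_ties Include all cutoff-tied genes (default `FALSE`).
#' @return Character vector of gene symbols ordered by rank.
#' @export
select_top_k <- function(table, metric, k, expand_ties = FALSE) {
  if (NROW(table) == 0L) ppis_config_error("centrality table is empty")
  if (length(k) != 1L || is.na(k) || k < 1) {
    ppis_config_error("'k' must be a positive integer")
  }
  col <- metric_column(metric)
  values <- table[[col]]
  ord <- order(-values, table$gene)
  k <- min(as.integer(k), nrow(table))
  if (isTRUE(expand_ties)) {
    cutoff <- values[ord][k]
    k <- sum(values >= cutoff)
  }
  table$gene[ord][seq_len(k)]
}

#' Intersect hub and bottleneck sets
#'
#' @param hubs Character vector of hub genes, ordered by hub rank.
#' @param bottlenecks Character vector of bottleneck genes.
#' @return The hub-bottlenecks: genes present in both sets, ordered by hub
#'   rank.
#' @examples
#' hubs <- c("SRC", "EGFR", "CTNNB1", "CDH1", "IL8",
#'           "PCNA", "TIMP1", "HSPD1", "PTPRC", "SERPINA1")
#' bottlenecks <- c("SRC", "EGFR", "PCNA", "IL8", "CTNNB1",
#'                  "TIMP1", "HSPB1", "CDH1", "SPTAN1", "HSPD1")
#' intersect_hub_bottlenecks(hubs, bottlenecks)
#' @export
intersect_hub_bottlenecks <- function(hubs, bottlenecks) {
  hubs[hubs %in% bottlenecks]
}

#' Cross-validate hub-bottlenecks into central nodes
#'
#' Keeps the hub-bottlenecks that appear in BOTH the top-`crossval_k` list by
#' closeness centrality and the top-`crossval_k` list by stress.
#'
#' @param hub_bottlenecks Character vector of hub-bottleneck genes.
#' @param table The `centrality_table` the top lists are drawn from.
#' @param crossval_k Size of each top list.
#' @param expand_ties Tie policy for the top lists (default `FALSE`).
#' @return Character vector: the central nodes, in hub-bottleneck order.
#' @export
cross_validate_central <- function(hub_bottlenecks, table, crossval_k,
                                   expand_ties = FALSE) {
  if (length(hub_bottlenecks) == 0L) return(character())
  top_cc <- select_top_k(table, "closeness", crossval_k, expand_ties)
  top_stress <- select_top_k(table, "stress", crossval_k, expand_ties)
  hub_bottlenecks[hub_bottlenecks %in% top_cc &
                    hub_bottlenecks %in% top_stress]
}

#' Run the full screening cascade on a network
#'
#' Computes the centrality table on the configured scope (the main connected
#' component by default), then selects hubs (top `hub_fraction` by degree),
#' bottlenecks (top `bottleneck_k` by betweenness), hub-bottlenecks (their
#' intersection) and central nodes (hub-bottlenecks present in the top
#' closeness and top stress lists).
#'
#' @param net A non-empty `ppi_network`.
#' @param config A [screening_config()].
#' @return An object of class `ppi_screen`: a list with the four gene sets
#'   (`hubs`, `bottlenecks`, `hub_bottlenecks`, `central_nodes`), ranked
#'   listings with metric values (`rankings`), the `metrics` table, the
#'   `config` used (with `crossval_k` resolved), and scope bookkeeping.
#' @examples
#' net <- ppi_network(cbind("HUB", paste0("G", 1:9)))
#' screen_network(net)
#' @export
screen_network <- function(net, config = screening_config()) {
  if (!inherits(config, "screening_config")) {
    ppis_config_error("'config' must be a screening_config object")
  }
  if (length(net$nodes) == 0L) {
    ppis_degenerate_error("cannot screen an empty network")
  }
  parts <- network_components(net)
  if (config$scope == "main_component") {
    main_nodes <- parts$components[[parts$main_index]]
    if (length(main_nodes) < 2L) {
      ppis_degenerate_error(
        "degenerate network: the main component has fewer than 2 nodes"
      )
    }
    scope_net <- induced_network(net, main_nodes)
  } else {
    scope_net <- net
  }
  table <- node_metrics(scope_net)
  hubs <- select_top_fraction(table, "degree", config$hub_fraction,
                              config$expand_ties)
  bottlenecks <- select_top_k(table, "betweenness", config$bottleneck_k,
                              config$expand_ties)
  hub_bottlenecks <- intersect_hub_bottlenecks(hubs, bottlenecks)
  crossval_k <- if (is.null(config$crossval_k)) length(hubs) else config$crossval_k
  central <- cross_validate_central(hub_bottlenecks, table, crossval_k,
                                    config$expand_ties)
  config$crossval_k <- as.integer(crossval_k)
  rankings <- list(
    hubs = ranked_listing(table, hubs, "degree"),
    bottlenecks = ranked_listing(table, bottlenecks, "betweenness"),
    hub_bottlenecks = ranked_listing(table, hub_bottlenecks, "degree"),
    central_nodes = ranked_listing(table, central, "degree")
  )
  structure(
    list(
      hubs = hubs,
      bottlenecks = bottlenecks,
      hub_bottlenecks = hub_bottlenecks,
      central_nodes = central,
      rankings = rankings,
      metrics = table,
      config = config,
      scope_size = nrow(table),
      n_components = length(parts$components),
      n_isolated = sum(parts$sizes == 1L)
    ),
    class = "ppi_screen"
  )
}

ranked_listing <- function(table, genes, metric) {
  idx <- match(genes, table$gene)
  out <- data.frame(
    rank = seq_along(genes),
    gene = genes,
    value = table[[metric]][idx],
    stringsAsFactors = FALSE
  )
  names(out)[3L] <- metric
  out
}

#' @export
print.ppi_screen <- function(x, ...) {
  cat("ppi_screen: topology screening cascade\n")
  cat(sprintf("  scope: %s (%d nodes analyzed)\n", x$config$scope, x$scope_size))
  cat(sprintf("  hubs (top %s by degree): %d [%s]\n",
              format(x$config$hub_fraction), length(x$hubs),
              paste(x$hubs, collapse = ", ")))
  cat(sprintf("  bottlenecks (top %d by betweenness): %d [%s]\n",
              x$config$bottleneck_k, length(x$bottlenecks),
              paste(x$bottlenecks, collapse = ", ")))
  cat(sprintf("  hub-bottlenecks: %d [%s]\n", length(x$hub_bottlenecks),
              paste(x$hub_bottlenecks, collapse = ", ")))
  cat(sprintf("  central nodes (closeness & stress top %d): %d [%s]\n",
              x$config$crossval_k, length(x$central_nodes),
              paste(x$central_nodes, collapse = ", ")))
  invisible(x)
}

#' @export
summary.ppi_screen <- function(object, ...) {
  counts <- c(
    analyzed = object$scope_size,
    hubs = length(object$hubs),
    bottlenecks = length(object$bottlenecks),
    hub_bottlenecks = length(object$hub_bottlenecks),
    central_nodes = length(object$central_nodes)
  )
  structure(list(counts = counts, screen = object), class = "summary.ppi_screen")
}

#' @export
print.summary.ppi_screen <- function(x, ...) {
  cat("Screening cascade counts:\n")
  print(x$counts)
  print(x$screen)
  invisible(x)
}

#' Serialize a screening result to a structured text file
#'
#' Writes one section per gene set, each a ranked TSV listing with the
#' ranking metric value, preceded by the resolved configuration. The output
#' is deterministic: identical inputs and configuration produce
#' byte-identical files.
#'
#' @param screen A `ppi_screen` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_screening_result <- function(screen, path) {
  cfg <- screen$config
  lines <- c(
    "# screening result",
    sprintf("hub_fraction\t%s", format(cfg$hub_fraction)),
    sprintf("bottleneck_k\t%d", cfg$bottleneck_k),
    sprintf("crossval_k\t%d", cfg$crossval_k),
    sprintf("scope\t%s", cfg$scope),
    sprintf("expand_ties\t%s", cfg$expand_ties),
    sprintf("nodes_analyzed\t%d", screen$scope_size)
  )
  for (set in names(screen$rankings)) {
    listing <- screen$rankings[[set]]
    metric <- names(listing)[3L]
    lines <- c(
      lines, "",
      sprintf("[%s] n=%d ranked_by=%s", set, nrow(listing), metric),
      sprintf("%d\t%s\t%s", listing$rank, listing$gene,
              format_metric_value(listing[[3L]]))
    )
  }
  writeLines(lines, path)
  invisible(path)
}

format_metric_value <- function(x) {
  if (length(x) == 0L) return(character())
  if (is.integer(x) || all(x == round(x))) {
    sprintf("%d", as.integer(x))
  } else {
    sprintf("%.6f", x)
  }
}
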