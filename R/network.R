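# Undirected simple-graph container and ingestion of the two input formats:
# plain-text gene lists and STRING-style scored edge tables.

#' Construct an undirected interaction network
#'
#' Creates a `ppi_network`: an undirected simple graph over gene symbols with
#' optional per-edge confidence scores. Self-loops are dropped and reciprocal
#' duplicate edges are collapsed, keeping the maximum score, so the stored
#' edge set always satisfies the simple-graph invariants.
#'
#' @param edges Two-column character matrix or data frame of endpoint symbols
#'   (one row per edge), or `NULL` for an edge-free network.
#' @param nodes Character vector of node symbols. Endpoints of `edges` are
#'   always included; extra symbols become isolated nodes.
#' @param scores Optional numeric vector of per-edge confidence scores in
#'   `[0, 1000]`, aligned with the rows of `edges`.
#' @return An object of class `ppi_network` with components `nodes` (sorted
#'   character vector), `edges` (two-column character matrix in canonical
#'   order) and `scores` (numeric vector aligned with `edges`, or `NULL`).
#' @examples
#' net <- ppi_network(rbind(c("SRC", "EGFR"), c("EGFR", "CDH1")), nodes = "PCNA")
#' net
#' @export
ppi_network <- function(edges = NULL, nodes = NULL, scores = NULL) {
  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(), ncol = 2L)
    sc <- if (is.null(scores)) NULL else numeric()
    return(new_ppi_network(sort(unique(as.character(nodes))), em, sc))
  }
  edges <- as.matrix(edges)
  if (ncol(edges) != 2L) {
    ppis_config_error("'edges' must have exactly two columns")
  }
  mode(edges) <- "character"
  if (!is.null(scores)) {
    scores <- as.numeric(scores)
    if (length(scores) != nrow(edges)) {
      ppis_config_error("'scores' must align with the rows of 'edges'")
    }
    if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1000)) {
      ppis_config_error("edge scores must lie in [0, 1000]")
    }
  }
  keep <- edges[, 1L] != edges[, 2L]
  edges <- edges[keep, , drop = FALSE]
  if (!is.null(scores)) scores <- scores[keep]
  a <- pmin(edges[, 1L], edges[, 2L])
  b <- pmax(edges[, 1L], edges[, 2L])
  key <- paste(a, b, sep = "\r")
  if (is.null(scores)) {
    dup <- duplicated(key)
    a <- a[!dup]; b <- b[!dup]
    sc <- NULL
  } else {
    sc_max <- tapply(scores, key, max)
    first <- !duplicated(key)
    a <- a[first]; b <- b[first]
    sc <- as.numeric(sc_max[key[first]])
  }
  ord <- order(a, b)
  em <- cbind(a[ord], b[ord])
  if (!is.null(sc)) sc <- sc[ord]
  all_nodes <- sort(unique(c(as.character(nodes), em[, 1L], em[, 2L])))
  new_ppi_network(all_nodes, em, sc)
}

new_ppi_network <- function(nodes, edges, scores) {
  structure(
    list(nodes = nodes, edges = edges, scores = scores),
    class = "ppi_network"
  )
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf(
    "ppi_network: %d nodes, %d edges%s\n",
    length(x$nodes), nrow(x$edges),
    if (is.null(x$scores)) "" else " (scored)"
  ))
  invisible(x)
}

#' Number of nodes and edges of a network
#'
#' @param net A `ppi_network`.
#' @return `n_nodes()` and `n_edges()` return single integers.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' Read a query gene list
#'
#' Reads a plain-text gene list, one symbol per line. Blank lines and lines
#' starting with `#` are ignored. Symbols are upper-cased (no alias
#' resolution is attempted) and de-duplicated preserving the order of first
#' appearance; the number of dropped duplicates is reported via [message()].
#'
#' @param path Path to the gene-list file.
#' @return Character vector of unique gene symbols, class `gene_list`.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) {
    ppis_io_error(sprintf("gene list file not found: '%s'", path))
  }
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  symbols <- toupper(lines)
  n_dup <- sum(duplicated(symbols))
  if (n_dup > 0L) {
    message(sprintf("read_gene_list: dropped %d duplicate symbol(s)", n_dup))
  }
  symbols <- symbols[!duplicated(symbols)]
  if (length(symbols) == 0L) {
    ppis_stop("empty gene list", "ppiscreen_parse_error")
  }
  structure(symbols, class = "gene_list")
}

#' Read a STRING-style scored edge table
#'
#' Parses a whitespace/tab-separated table with columns `nodeA`, `nodeB`,
#' `combined_score` (integer 0-1000). A header line is auto-detected by a
#' non-numeric third column. Symbols are upper-cased; self-loops are dropped;
#' reciprocal duplicate rows are collapsed keeping the maximum score; only
#' edges with score >= `score_threshold` are retained, and all endpoints of
#' surviving edges become nodes.
#'
#' @param path Path to the edge table.
#' @param score_threshold Integer in `[0, 1000]`; edges below it are dropped.
#'   Default 400, STRING's conventional medium-confidence cutoff.
#' @return A [ppi_network] with per-edge scores.
#' @export
read_edge_table <- function(path, score_threshold = 400) {
  if (!file.exists(path)) {
    ppis_io_error(sprintf("edge table file not found: '%s'", path))
  }
  if (length(score_threshold) != 1L || is.na(score_threshold) ||
      score_threshold < 0 || score_threshold > 1000) {
    ppis_config_error("'score_threshold' must be a single value in [0, 1000]")
  }
  lines <- readLines(path, warn = FALSE)
  a <- character(0); b <- character(0); s <- numeric(0)
  first_data <- TRUE
  for (i in seq_along(lines)) {
    line <- trimws(lines[[i]])
    if (!nzchar(line)) next
    fields <- strsplit(line, "[ \t]+")[[1L]]
    if (length(fields) != 3L) {
      ppis_parse_error(sprintf(
        "line %d: expected 3 columns (nodeA nodeB combined_score), got %d",
        i, length(fields)
      ))
    }
    if (first_data && !grepl("^[0-9]+$", fields[[3L]])) {
      # header line: non-numeric third column
      first_data <- FALSE
      next
    }
    first_data <- FALSE
    if (!grepl("^[0-9]+$", fields[[3L]])) {
      ppis_parse_error(sprintf(
        "line %d: combined_score '%s' is not a non-negative integer",
        i, fields[[3L]]
      ))
    }
    score <- as.numeric(fields[[3L]])
    if (score > 1000) {
      ppis_parse_error(sprintf(
        "line %d: combined_score %d outside [0, 1000]", i, as.integer(score)
      ))
    }
    a <- c(a, toupper(fields[[1L]]))
    b <- c(b, toupper(fields[[2L]]))
    s <- c(s, score)
  }
  if (length(a) == 0L) {
    warning("read_edge_table: no data rows found; returning empty network")
    return(ppi_network())
  }
  # collapse reciprocal duplicates (including repeated self-loops) to the
  # maximum score, then threshold rows; endpoints of every surviving row
  # become nodes, so a self-loop row keeps its gene in the universe as an
  # isolated node even though the loop edge itself is dropped
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  s_max <- tapply(s, key, max)
  first <- !duplicated(key)
  lo <- lo[first]; hi <- hi[first]
  s <- as.numeric(s_max[key[first]])
  keep <- s >= score_threshold
  if (!any(keep)) {
    warning(sprintf(
      "read_edge_table: no rows with score >= %s; returning empty network",
      format(score_threshold)
    ))
  }
  lo <- lo[keep]; hi <- hi[keep]; s <- s[keep]
  proper <- lo != hi
  ppi_network(cbind(lo[proper], hi[proper]),
              nodes = unique(c(lo, hi)), scores = s[proper])
}

#' Write a network as a scored edge table
#'
#' Writes the three-column TSV (`node1`, `node2`, `combined_score`) that
#' [read_edge_table()] reads back. Networks without scores are written with
#' the constant score 999 so any threshold up to 999 preserves the graph.
#' Isolated nodes are written as self-loop rows (score 999): the reader
#' drops the loop but keeps the gene in the node universe, so a write/read
#' round trip at threshold 0 reproduces the node and edge sets exactly.
#'
#' @param net A `ppi_network`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_edge_table <- function(net, path) {
  scores <- net$scores
  if (is.null(scores)) scores <- rep(999, nrow(net$edges))
  isolated <- net$nodes[degree_centrality(net) == 0L]
  lines <- c(
    "node1\tnode2\tcombined_score",
    sprintf("%s\t%s\t%d", net$edges[, 1L], net$edges[, 2L], as.integer(round(scores))),
    sprintf("%s\t%s\t999", isolated, isolated)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Induce the query-gene network from an edge universe
#'
#' Restricts an interaction universe (typically the thresholded STRING-style
#' edge table) to the query genes: the result is the sub-network induced on
#' the query genes that appear in the universe's node set. Query genes absent
#' from the universe are returned as `unrecognized`; recognized genes with no
#' surviving incident edge remain as isolated nodes.
#'
#' @param genes Character vector (or [read_gene_list()] result) of query
#'   gene symbols.
#' @param universe A `ppi_network` providing the node universe and edges.
#' @return List with components `network` (the induced `ppi_network`) and
#'   `unrecognized` (character vector of query genes absent from the
#'   universe, in query order).
#' @export
build_network <- function(genes, universe) {
  genes <- toupper(as.character(genes))
  genes <- genes[!duplicated(genes)]
  recognized <- genes[genes %in% universe$nodes]
  unrecognized <- genes[!genes %in% universe$nodes]
  if (length(unrecognized) > 0L) {
    warning(sprintf(
      "build_network: %d query gene(s) absent from the edge universe: %s",
      length(unrecognized), paste(unrecognized, collapse = ", ")
    ))
  }
  net <- induced_network(universe, recognized)
  list(network = net, unrecognized = unrecognized)
}

#' Sub-network induced on a node subset
#'
#' @param net A `ppi_network`.
#' @param nodes Character vector of nodes to keep (symbols not present in
#'   `net` are ignored).
#' @return A `ppi_network` on `intersect(nodes, net$nodes)` with every edge
#'   of `net` whose two endpoints are kept.
#' @export
induced_network <- function(net, nodes) {
  keep_nodes <- intersect(net$nodes, nodes)
  keep <- net$edges[, 1L] %in% keep_nodes & net$edges[, 2L] %in% keep_nodes
  ppi_network(
    net$edges[keep, , drop = FALSE],
    nodes = keep_nodes,
    scores = if (is.null(net$scores)) NULL else net$scores[keep]
  )
}

#' Connected components of a network
#'
#' Standard undirected connected components via breadth-first traversal.
#' Isolated nodes form singleton components. Components are ordered by
#' decreasing size, ties broken by their lexicographically smallest member,
#' so the main (largest) component is always the first.
#'
#' @param net A `ppi_network`.
#' @return An object of class `ppi_components`: a list with `components`
#'   (list of sorted character vectors partitioning the node set),
#'   `main_index` (index of the largest component, always 1), and `sizes`.
#' @export
network_components <- function(net) {
  n <- length(net$nodes)
  if (n == 0L) {
    return(structure(
      list(components = list(), main_index = NA_integer_, sizes = integer()),
      class = "ppi_components"
    ))
  }
  adj <- adjacency_index(net)
  comp <- integer(n)
  n_comp <- 0L
  for (start in seq_len(n)) {
    if (comp[start] != 0L) next
    n_comp <- n_comp + 1L
    queue <- start
    comp[start] <- n_comp
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nbrs <- adj[[v]]
      new <- nbrs[comp[nbrs] == 0L]
      comp[new] <- n_comp
      queue <- c(queue, new)
    }
  }
  comps <- split(net$nodes, comp)
  comps <- lapply(comps, sort)
  sizes <- lengths(comps)
  first_member <- vapply(comps, `[[`, character(1L), 1L)
  ord <- order(-sizes, first_member)
  comps <- unname(comps[ord])
  structure(
    list(components = comps, main_index = 1L, sizes = lengths(comps)),
    class = "ppi_components"
  )
}

#' @export
print.ppi_components <- function(x, ...) {
  n_singleton <- sum(x$sizes == 1L)
  cat(sprintf(
    "ppi_components: %d component(s), main component of %d node(s), %d isolated\n",
    length(x$components),
    if (length(x$sizes)) x$sizes[[x$main_index]] else 0L,
    n_singleton
  ))
  invisible(x)
}

#' Extract the main connected component
#'
#' @param net A `ppi_network`.
#' @return The sub-network induced on the largest connected component (ties
#'   broken by lexicographically smallest member).
#' @export
main_component <- function(net) {
  parts <- network_components(net)
  if (length(parts$components) == 0L) return(net)
  induced_network(net, parts$components[[parts$main_index]])
}

# Integer adjacency lists over the (sorted) node vector; the sorted order
# also fixes the floating-point accumulation order in the centrality engine.
adjacency_index <- function(net) {
  n <- length(net$nodes)
  i <- match(net$edges[, 1L], net$nodes)
  j <- match(net$edges[, 2L], net$nodes)
  adj <- rep(list(integer()), n)
  if (length(i) > 0L) {
    half <- split(c(j, i), c(i, j))
    idx <- as.integer(names(half))
    adj[idx] <- lapply(half, function(x) sort(as.integer(x)))
  }
  adj
}

#' Write a Table-style centrality report
#'
#' Writes a ranked TSV with columns `R` (1-based rank), `name`,
#' `description`, `D` (degree), `BC` (betweenness, 2 decimals), `CC`
#' (closeness, 2 decimals) and `Stress`, mirroring the presentation used in
#' hub-bottleneck screening reports. Rows are ordered by the ranking metric
#' descending, ties broken by symbol ascending. Descriptions are empty unless
#' an annotation table is supplied.
#'
#' @param metrics A `centrality_table` (see [node_metrics()]), non-empty.
#' @param path Output file path.
#' @param ranked_by Ranking metric: one of `"degree"`, `"betweenness"`,
#'   `"closeness"`, `"stress"`.
#' @param annotations Optional named character vector, or two-column data
#'   frame (`gene`, `description`), supplying the `description` column.
#' @param digits Decimal places for `BC` and `CC` (default 2).
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(metrics, path, ranked_by = "degree",
                                 annotations = NULL, digits = 2) {
  if (NROW(metrics) == 0L) {
    ppis_config_error("cannot write a report for an empty metrics table")
  }
  col <- metric_column(ranked_by)
  ord <- order(-metrics[[col]], metrics$gene)
  metrics <- metrics[ord, , drop = FALSE]
  desc <- rep("", nrow(metrics))
  if (!is.null(annotations)) {
    if (is.data.frame(annotations)) {
      ann <- stats::setNames(as.character(annotations[[2L]]),
                             toupper(as.character(annotations[[1L]])))
    } else {
      ann <- stats::setNames(as.character(annotations), toupper(names(annotations)))
    }
    hit <- match(metrics$gene, names(ann))
    desc[!is.na(hit)] <- ann[hit[!is.na(hit)]]
  }
  fmt <- paste0("%.", digits, "f")
  lines <- c(
    "R\tname\tdescription\tD\tBC\tCC\tStress",
    sprintf(
      "%d\t%s\t%s\t%d\t%s\t%s\t%d",
      seq_len(nrow(metrics)), metrics$gene, desc, metrics$degree,
      sprintf(fmt, metrics$betweenness), sprintf(fmt, metrics$closeness),
      metrics$stress
    )
  )
  writeLines(lines, path)
  invisible(path)
}

metric_column <- function(metric) {
  valid <- c("degree", "betweenness", "closeness", "stress")
  if (length(metric) != 1L || !metric %in% valid) {
    ppis_config_error(sprintf(
      "unknown metric '%s'; must be one of %s",
      paste(metric, collapse = ", "), paste(valid, collapse = ", ")
    ))
  }
  metric
}
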