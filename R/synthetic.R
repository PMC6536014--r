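# Seeded generator of ground-truth test networks emulating the structural
# features the screening assumes: a scale-free (preferential-attachment)
# main component, a configurable number of isolated query genes, and planted
# high-degree/high-betweenness nodes with known identity.

#' Specification of a synthetic test network
#'
#' @param n_connected Number of nodes in the connected (preferential
#'   attachment) part.
#' @param attachment Edges added per new node during preferential attachment
#'   (must be positive and smaller than `n_connected`).
#' @param n_isolated Number of extra edge-free nodes appended.
#' @param n_planted Number of planted central nodes (each additionally wired
#'   to a fixed fraction of the connected nodes); at most `n_connected`.
#' @param planted_coverage Fraction in `(0, 1]` of the other connected nodes
#'   each planted node is wired to.
#' @param seed Integer seed; generation is a pure function of the spec.
#' @return An object of class `synthetic_network_spec`.
#' @export
synthetic_network_spec <- function(n_connected, attachment = 2L,
                                   n_isolated = 0L, n_planted = 0L,
                                   planted_coverage = 0.5, seed = 1L) {
  if (n_connected < 1 || attachment < 1 || attachment >= n_connected) {
    ppis_config_error("need 1 <= attachment < n_connected")
  }
  if (n_isolated < 0 || n_planted < 0 || n_planted > n_connected) {
    ppis_config_error("need n_isolated >= 0 and 0 <= n_planted <= n_connected")
  }
  if (planted_coverage <= 0 || planted_coverage > 1) {
    ppis_config_error("'planted_coverage' must lie in (0, 1]")
  }
  if (n_connected + n_isolated > 9999) {
    ppis_config_error("at most 9999 nodes supported by the GENE#### label scheme")
  }
  structure(
    list(
      n_connected = as.integer(n_connected),
      attachment = as.integer(attachment),
      n_isolated = as.integer(n_isolated),
      n_planted = as.integer(n_planted),
      planted_coverage = planted_coverage,
      seed = as.integer(seed)
    ),
    class = "synthetic_network_spec"
  )
}

#' Generate a seeded ground-truth network
#'
#' Grows a Barabási–Albert preferential-attachment graph on `n_connected`
#' nodes (labelled `GENE0001`, `GENE0002`, ...), wires each of `n_planted`
#' randomly chosen nodes to `planted_coverage` of the other connected nodes,
#' and appends `n_isolated` edge-free nodes. Fully reproducible from the
#' spec's seed; the caller's random-number state is left untouched.
#'
#' @param spec A [synthetic_network_spec()].
#' @return List with `network` (a `ppi_network`) and `truth` (class
#'   `ground_truth`: the planted node labels plus the spec).
#' @examples
#' out <- generate_network(synthetic_network_spec(105, 2, n_isolated = 9, seed = 7))
#' out$network
#' @export
generate_network <- function(spec) {
  if (!inherits(spec, "synthetic_network_spec")) {
    ppis_config_error("'spec' must be a synthetic_network_spec")
  }
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(spec$seed)
  labels <- sprintf("GENE%04d", seq_len(spec$n_connected + spec$n_isolated))
  connected <- labels[seq_len(spec$n_connected)]
  g <- igraph::sample_pa(spec$n_connected, m = spec$attachment, directed = FALSE)
  el <- igraph::as_edgelist(g, names = FALSE)
  from <- connected[el[, 1L]]
  to <- connected[el[, 2L]]
  planted <- character(0)
  if (spec$n_planted > 0L) {
    planted_idx <- sort(sample.int(spec$n_connected, spec$n_planted))
    planted <- connected[planted_idx]
    n_targets <- ceiling(spec$planted_coverage * (spec$n_connected - 1L))
    for (p in planted_idx) {
      others <- setdiff(seq_len(spec$n_connected), p)
      targets <- sort(sample(others, n_targets))
      from <- c(from, rep(connected[p], n_targets))
      to <- c(to, connected[targets])
    }
  }
  net <- ppi_network(cbind(from, to), nodes = labels)
  truth <- structure(list(planted_nodes = planted, spec = spec),
                     class = "ground_truth")
  list(network = net, truth = truth)
}

#' Erdős–Rényi null network
#'
#' Uniform random graph with a fixed edge count, used as a non-scale-free
#' null for degree-tail contrast checks.
#'
#' @param n Number of nodes.
#' @param m Number of edges.
#' @param seed Integer seed.
#' @return A `ppi_network` with nodes `GENE0001` ... The caller's
#'   random-number state is left untouched.
#' @export
erdos_renyi_network <- function(n, m, seed = 1L) {
  old_seed <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(seed)
  labels <- sprintf("GENE%04d", seq_len(n))
  g <- igraph::sample_gnm(n, m)
  el <- igraph::as_edgelist(g, names = FALSE)
  ppi_network(cbind(labels[el[, 1L]], labels[el[, 2L]]), nodes = labels)
}

#' Heavy-tail summary of a degree distribution
#'
#' Descriptive check that a network's degree distribution is heavy-tailed in
#' the way scale-free interactomes are: reports the maximum degree, the
#' degree variance, and the fraction of nodes with degree at most 2. No
#' hypothesis test is performed.
#'
#' @param net A `ppi_network` with at least 10 non-isolated nodes.
#' @return List with `max_degree`, `degree_variance`, `frac_degree_le2`
#'   (computed over the non-isolated nodes).
#' @export
degree_tail_check <- function(net) {
  deg <- degree_centrality(net)
  deg <- deg[deg > 0L]
  if (length(deg) < 10L) {
    ppis_config_error("degree_tail_check needs at least 10 non-isolated nodes")
  }
  list(
    max_degree = max(deg),
    degree_variance = stats::var(as.numeric(deg)),
    frac_degree_le2 = mean(deg <= 2L)
  )
}

#' Write a synthetic network as an on-disk fixture
#'
#' Emits the edge TSV (constant score 999 when the network carries none),
#' the gene list (every node, one per line) and a flat key-value truth
#' manifest, in the same formats the ingestion functions read, so that
#' reading the fixture back reproduces the network exactly.
#'
#' @param net A `ppi_network`.
#' @param truth A `ground_truth` (or `NULL` for an empty planted set).
#' @param dir Output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
write_fixture <- function(net, truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edges_path <- file.path(dir, "edges.tsv")
  genes_path <- file.path(dir, "genes.txt")
  truth_path <- file.path(dir, "truth.txt")
  write_edge_table(net, edges_path)
  writeLines(net$nodes, genes_path)
  planted <- if (is.null(truth)) character(0) else truth$planted_nodes
  lines <- sprintf("planted\t%s", paste(planted, collapse = ","))
  if (!is.null(truth)) {
    sp <- truth$spec
    lines <- c(
      lines,
      sprintf("n_connected\t%d", sp$n_connected),
      sprintf("attachment\t%d", sp$attachment),
      sprintf("n_isolated\t%d", sp$n_isolated),
      sprintf("n_planted\t%d", sp$n_planted),
      sprintf("planted_coverage\t%s", format(sp$planted_coverage)),
      sprintf("seed\t%d", sp$seed)
    )
  }
  writeLines(lines, truth_path)
  invisible(c(edges = edges_path, genes = genes_path, truth = truth_path))
}
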