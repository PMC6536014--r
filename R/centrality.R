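# The four node statistics of topology-based screening: degree, betweenness,
# closeness and stress, on unweighted undirected graphs. Betweenness and
# stress come from a single Brandes-style accumulation over breadth-first
# shortest-path DAGs; closeness reuses the same BFS distances. Edge scores
# never enter any distance: the graph is treated as unweighted throughout.

#' Degree of every node
#'
#' @param net A `ppi_network`.
#' @return Named integer vector over all nodes; isolated nodes get 0.
#' @export
degree_centrality <- function(net) {
  deg <- integer(length(net$nodes))
  names(deg) <- net$nodes
  if (nrow(net$edges) > 0L) {
    tab <- table(c(net$edges[, 1L], net$edges[, 2L]))
    deg[names(tab)] <- as.integer(tab)
  }
  deg
}

#' Betweenness centrality
#'
#' Brandes accumulation of pair dependencies over unweighted shortest paths.
#' By default each node's value is normalized by `(n_c - 1) * (n_c - 2) / 2`,
#' where `n_c` is the size of that node's connected component (the
#' NetworkAnalyzer convention for disconnected graphs), so values lie in
#' `[0, 1]`; nodes in components of size <= 2 get 0. With
#' `normalized = FALSE` the raw sum over unordered pairs is returned.
#'
#' @param net A `ppi_network`.
#' @param normalized Normalize per component (default `TRUE`).
#' @return Named numeric vector over all nodes.
#' @export
betweenness_centrality <- function(net, normalized = TRUE) {
  eng <- centrality_engine(net)
  finish_betweenness(eng, normalized)
}

#' Closeness centrality
#'
#' For a node `v` in a component of size `n_c > 1`, the reciprocal of its
#' mean intra-component distance: `(n_c - 1) / sum(d(v, u))` over the other
#' nodes `u` of its component. Isolated nodes get 0 by convention (harmonic
#' closeness is not used).
#'
#' @param net A `ppi_network`.
#' @return Named numeric vector in `[0, 1]` over all nodes.
#' @export
closeness_centrality <- function(net) {
  centrality_engine(net)$closeness
}

#' Stress centrality
#'
#' For each node `v`, the number of shortest paths between pairs of other
#' nodes that pass through `v` as an interior node, every distinct shortest
#' path counted once per unordered pair. With `ordered = TRUE` each pair is
#' counted in both directions (doubling the values), which matches tools
#' that count ordered pairs.
#'
#' @param net A `ppi_network`.
#' @param ordered Count ordered pairs instead of unordered (default `FALSE`).
#' @return Named numeric vector of non-negative integers over all nodes.
#' @export
stress_centrality <- function(net, ordered = FALSE) {
  s <- centrality_engine(net)$stress_ordered
  if (!ordered) s <- s / 2
  round(s)
}

#' Compute the full centrality table
#'
#' Runs the four statistics (degree, betweenness, closeness, stress) on one
#' consistent snapshot of the network and returns one record per node,
#' together with the size of each node's connected component.
#'
#' @param net A `ppi_network`.
#' @param normalized Normalize betweenness per component (default `TRUE`).
#' @return A data frame of class `centrality_table` with columns `gene`,
#'   `degree`, `betweenness`, `closeness`, `stress`, `component_size`, one
#'   row per node in sorted symbol order.
#' @examples
#' net <- ppi_network(rbind(c("A", "B"), c("B", "C")))
#' node_metrics(net)
#' @export
node_metrics <- function(net, normalized = TRUE) {
  eng <- centrality_engine(net)
  tab <- data.frame(
    gene = net$nodes,
    degree = as.integer(degree_centrality(net)),
    betweenness = unname(finish_betweenness(eng, normalized)),
    closeness = unname(eng$closeness),
    stress = as.integer(round(eng$stress_ordered / 2)),
    component_size = eng$component_size,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  class(tab) <- c("centrality_table", "data.frame")
  tab
}

#' @export
print.centrality_table <- function(x, ...) {
  cat(sprintf("centrality_table: %d node(s)\n", nrow(x)))
  print.data.frame(x, ...)
  invisible(x)
}

finish_betweenness <- function(eng, normalized) {
  bc <- eng$betweenness_raw
  if (normalized) {
    nc <- eng$component_size
    norm <- (nc - 1) * (nc - 2) / 2
    bc[] <- ifelse(norm > 0, bc / norm, 0)
  }
  bc
}

# One pass of breadth-first search per source over the shortest-path DAG.
# delta accumulates Brandes pair dependencies (betweenness); psi[v] counts
# the DAG paths from v to every strictly deeper target, so sigma[v] * psi[v]
# is the number of shortest source->target paths with v interior. Summed
# over all sources this counts every unordered pair twice.
centrality_engine <- function(net) {
  n <- length(net$nodes)
  bc <- numeric(n)
  stress <- numeric(n)
  cc <- numeric(n)
  comp_size <- integer(n)
  names(bc) <- names(stress) <- names(cc) <- net$nodes
  if (n == 0L) {
    return(list(betweenness_raw = bc, stress_ordered = stress,
                closeness = cc, component_size = comp_size))
  }
  adj <- adjacency_index(net)
  dist_sum <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    sigma <- numeric(n)
    preds <- rep(list(integer()), n)
    order_visited <- integer(n)
    n_visited <- 0L
    dist[s] <- 0L
    sigma[s] <- 1
    queue <- integer(n)
    queue[1L] <- s
    q_head <- 1L; q_tail <- 1L
    while (q_head <= q_tail) {
      v <- queue[q_head]
      q_head <- q_head + 1L
      n_visited <- n_visited + 1L
      order_visited[n_visited] <- v
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          q_tail <- q_tail + 1L
          queue[q_tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    comp_size[s] <- n_visited
    dist_sum[s] <- sum(dist[dist > 0L])
    delta <- numeric(n)
    psi <- numeric(n)
    for (k in seq(n_visited, 1L)) {
      w <- order_visited[k]
      for (v in preds[[w]]) {
        delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
        psi[v] <- psi[v] + 1 + psi[w]
      }
      if (w != s) {
        bc[w] <- bc[w] + delta[w]
        stress[w] <- stress[w] + sigma[w] * psi[w]
      }
    }
  }
  cc <- ifelse(comp_size > 1L, (comp_size - 1L) / dist_sum, 0)
  names(cc) <- net$nodes
  list(
    betweenness_raw = bc / 2,
    stress_ordered = stress,
    closeness = cc,
    component_size = comp_size
  )
}

#' Brute-force centrality oracle
#'
#' Computes the same table as [node_metrics()] by exhaustively enumerating
#' every shortest path between every pair of nodes — an independent,
#' transparently correct reference for small graphs. Refuses networks with
#' more than 12 nodes.
#'
#' @param net A `ppi_network` with at most 12 nodes.
#' @param normalized Normalize betweenness per component (default `TRUE`).
#' @return A `centrality_table` identical in layout to [node_metrics()].
#' @export
brute_force_metrics <- function(net, normalized = TRUE) {
  n <- length(net$nodes)
  if (n > 12L) {
    ppis_config_error("brute_force_metrics is restricted to networks with <= 12 nodes")
  }
  deg <- as.integer(degree_centrality(net))
  bc <- numeric(n)
  stress <- numeric(n)
  dist_sum <- numeric(n)
  adj <- adjacency_index(net)
  dist <- matrix(Inf, n, n)
  if (n > 0L) {
    for (s in seq_len(n)) dist[s, ] <- bfs_distances(adj, s, n)
    comp_size <- vapply(seq_len(n), function(v) sum(is.finite(dist[v, ])), integer(1L))
    for (s in seq_len(n)) {
      for (t in seq_len(n)) {
        if (t <= s || !is.finite(dist[s, t])) next
        paths <- enumerate_shortest_paths(adj, dist, s, t)
        interior <- table(unlist(lapply(paths, function(p) p[-c(1L, length(p))])))
        if (length(interior) > 0L) {
          idx <- as.integer(names(interior))
          stress[idx] <- stress[idx] + as.numeric(interior)
          bc[idx] <- bc[idx] + as.numeric(interior) / length(paths)
        }
      }
    }
    dist_sum <- vapply(seq_len(n), function(v) {
      d <- dist[v, ]
      sum(d[is.finite(d) & d > 0])
    }, numeric(1L))
  } else {
    comp_size <- integer(0)
  }
  if (normalized) {
    norm <- (comp_size - 1) * (comp_size - 2) / 2
    bc <- ifelse(norm > 0, bc / norm, 0)
  }
  cc <- ifelse(comp_size > 1L, (comp_size - 1L) / dist_sum, 0)
  tab <- data.frame(
    gene = net$nodes,
    degree = deg,
    betweenness = bc,
    closeness = cc,
    stress = as.integer(round(stress)),
    component_size = comp_size,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  class(tab) <- c("centrality_table", "data.frame")
  tab
}

bfs_distances <- function(adj, s, n) {
  dist <- rep(Inf, n)
  dist[s] <- 0
  queue <- s
  while (length(queue) > 0L) {
    v <- queue[[1L]]
    queue <- queue[-1L]
    for (w in adj[[v]]) {
      if (!is.finite(dist[w])) {
        dist[w] <- dist[v] + 1
        queue <- c(queue, w)
      }
    }
  }
  dist
}

# All shortest s-t paths, via recursion backwards from t through nodes that
# lie on some shortest path.
enumerate_shortest_paths <- function(adj, dist, s, t) {
  if (s == t) return(list(s))
  out <- list()
  for (v in adj[[t]]) {
    if (dist[s, v] == dist[s, t] - 1) {
      for (p in enumerate_shortest_paths(adj, dist, s, v)) {
        out[[length(out) + 1L]] <- c(p, t)
      }
    }
  }
  out
}
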