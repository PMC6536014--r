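# Graph builders and independent oracles shared across the suite.

path_graph <- function(labels) {
  ppi_network(cbind(labels[-length(labels)], labels[-1L]))
}

star_graph <- function(m, center = "C") {
  ppi_network(cbind(center, sprintf("L%02d", seq_len(m))))
}

complete_graph <- function(n) {
  labels <- sprintf("K%02d", seq_len(n))
  pairs <- t(utils::combn(labels, 2L))
  ppi_network(pairs)
}

# Erdos-Renyi G(n, p) built directly from a Bernoulli draw per pair; used to
# feed the property suites with arbitrary (possibly disconnected) graphs.
random_graph <- function(n, p, seed, prefix = "N") {
  set.seed(seed)
  labels <- sprintf("%s%02d", prefix, seq_len(n))
  if (n < 2L) return(ppi_network(nodes = labels))
  pairs <- t(utils::combn(labels, 2L))
  keep <- stats::runif(nrow(pairs)) < p
  ppi_network(pairs[keep, , drop = FALSE], nodes = labels)
}

# Union-find component oracle, independent of the package's BFS traversal.
union_find_components <- function(net) {
  parent <- seq_along(net$nodes)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (e in seq_len(nrow(net$edges))) {
    i <- find(match(net$edges[e, 1L], net$nodes))
    j <- find(match(net$edges[e, 2L], net$nodes))
    if (i != j) parent[i] <- j
  }
  roots <- vapply(seq_along(net$nodes), find, integer(1L))
  unname(lapply(split(net$nodes, roots), sort))
}

# Canonical sortable representation of a component partition.
canon_partition <- function(comps) {
  sort(vapply(comps, function(x) paste(sort(x), collapse = ","), character(1L)))
}

expect_metrics_equal <- function(a, b, tol = 1e-12) {
  expect_equal(a$gene, b$gene)
  expect_identical(a$degree, b$degree)
  expect_identical(a$stress, b$stress)
  expect_identical(a$component_size, b$component_size)
  expect_equal(a$betweenness, b$betweenness, tolerance = tol)
  expect_equal(a$closeness, b$closeness, tolerance = tol)
}

write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".txt", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
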