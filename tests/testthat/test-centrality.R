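# The four node statistics against closed forms, the brute-force
# enumeration oracle, an external implementation, and structural invariants.

test_that("closed forms hold on stars, paths, complete graphs and triangles", {
  star <- star_graph(4)
  m <- node_metrics(star)
  center <- m[m$gene == "C", ]
  expect_equal(center$degree, 4L)
  expect_equal(center$betweenness, 1.0)
  expect_equal(center$closeness, 1.0)
  expect_equal(center$stress, 6L)  # m(m-1)/2 leaf pairs
  leaves <- m[m$gene != "C", ]
  expect_true(all(leaves$betweenness == 0))
  expect_true(all(leaves$stress == 0L))

  p4 <- path_graph(c("A", "B", "C", "D"))
  m <- node_metrics(p4)
  expect_equal(m$degree, c(1L, 2L, 2L, 1L))
  expect_equal(m$betweenness, c(0, 2 / 3, 2 / 3, 0))
  expect_equal(m$stress, c(0L, 2L, 2L, 0L))
  expect_equal(m$closeness[m$gene == "A"], 3 / 6)

  p3 <- path_graph(c("A", "B", "C"))
  cc <- closeness_centrality(p3)
  expect_equal(unname(cc[c("A", "B", "C")]), c(2 / 3, 1, 2 / 3))

  for (n in c(2, 4, 6)) {
    m <- node_metrics(complete_graph(n))
    expect_true(all(m$betweenness == 0))
    expect_true(all(m$closeness == 1))
    expect_true(all(m$stress == 0L))
    expect_true(all(m$degree == n - 1L))
  }

  tri <- ppi_network(rbind(c("A", "B"), c("B", "C"), c("A", "C")))
  m <- node_metrics(tri)
  expect_equal(m$degree, rep(2L, 3))
  expect_equal(m$betweenness, rep(0, 3))
  expect_equal(m$closeness, rep(1, 3))
})

test_that("isolated nodes get zero for every statistic", {
  net <- ppi_network(cbind("A", "B"), nodes = c("X", "Y"))
  m <- node_metrics(net)
  iso <- m[m$gene %in% c("X", "Y"), ]
  expect_true(all(iso$degree == 0L))
  expect_true(all(iso$betweenness == 0))
  expect_true(all(iso$closeness == 0))
  expect_true(all(iso$stress == 0L))
  expect_true(all(iso$component_size == 1L))
})

test_that("fast engine agrees with the brute-force oracle on random graphs", {
  for (i in 1:120) {
    n <- sample(2:10, 1)
    p <- sample(c(0.2, 0.5, 0.8), 1)
    net <- random_graph(n, p, seed = 5000 + i)
    expect_metrics_equal(node_metrics(net), brute_force_metrics(net))
  }
})

test_that("betweenness and closeness agree with an external implementation", {
  for (seed in 1:10) {
    net <- random_graph(20, 0.15, seed = 900 + seed)
    g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
    g <- igraph::add_vertices(g, sum(!net$nodes %in% igraph::V(g)$name),
                              name = setdiff(net$nodes, igraph::V(g)$name))
    perm <- match(net$nodes, igraph::V(g)$name)
    bc_ref <- igraph::betweenness(g, directed = FALSE)[perm]
    expect_equal(unname(betweenness_centrality(net, normalized = FALSE)),
                 unname(bc_ref), tolerance = 1e-10)
    deg_ref <- igraph::degree(g)[perm]
    expect_equal(unname(degree_centrality(net)), unname(as.integer(deg_ref)))
  }
})

test_that("betweenness is normalized per connected component", {
  # two components of different sizes: P3 (size 3) and P4 (size 4)
  net <- ppi_network(rbind(
    c("A", "B"), c("B", "C"),
    c("W", "X"), c("X", "Y"), c("Y", "Z")
  ))
  bc <- betweenness_centrality(net)
  expect_equal(unname(bc["B"]), 1.0)        # 1 pair / ((3-1)(3-2)/2) = 1
  expect_equal(unname(bc["X"]), 2 / 3)      # 2 pairs / 3
  raw <- betweenness_centrality(net, normalized = FALSE)
  expect_equal(unname(raw["B"]), 1)
  expect_equal(unname(raw["X"]), 2)
  # components of size <= 2 get zero
  pair <- ppi_network(cbind("A", "B"))
  expect_true(all(betweenness_centrality(pair) == 0))
})

test_that("stress counts unordered-pair paths once, doubled when ordered", {
  p4 <- path_graph(c("A", "B", "C", "D"))
  s <- stress_centrality(p4)
  expect_equal(unname(s["B"]), 2)
  expect_equal(unname(stress_centrality(p4, ordered = TRUE)["B"]), 4)
  # diamond: two shortest A-D paths, each interior node carries one
  diamond <- ppi_network(rbind(c("A", "B"), c("A", "C"), c("B", "D"), c("C", "D")))
  s <- stress_centrality(diamond)
  expect_equal(unname(s[c("B", "C")]), c(1, 1))
})

test_that("tree identity: total stress equals sum over pairs of (d - 1)", {
  for (seed in 1:15) {
    # random labelled tree via sequential random parent attachment
    set.seed(seed)
    n <- sample(4:10, 1)
    labels <- sprintf("T%02d", 1:n)
    parents <- vapply(2:n, function(i) sample(i - 1L, 1L), integer(1L))
    net <- ppi_network(cbind(labels[parents], labels[2:n]))
    m <- brute_force_metrics(net)
    # pairwise distances via the closeness relation is circular; recompute
    adj <- lapply(net$nodes, function(v) {
      which(net$nodes %in% c(net$edges[net$edges[, 1] == v, 2],
                             net$edges[net$edges[, 2] == v, 1]))
    })
    dist_total <- 0
    for (s in seq_len(n)) {
      d <- rep(-1L, n); d[s] <- 0L; q <- s
      while (length(q)) {
        v <- q[1]; q <- q[-1]
        for (w in adj[[v]]) if (d[w] < 0L) { d[w] <- d[v] + 1L; q <- c(q, w) }
      }
      dist_total <- dist_total + sum(d)
    }
    n_pairs <- choose(n, 2)
    expect_equal(sum(m$stress), dist_total / 2 - n_pairs)
    expect_metrics_equal(node_metrics(net), m)
  }
})

test_that("metrics lie in range and are permutation equivariant", {
  for (seed in 1:20) {
    net <- random_graph(12, 0.25, seed = 7000 + seed)
    m <- node_metrics(net)
    expect_true(all(m$betweenness >= 0 & m$betweenness <= 1))
    expect_true(all(m$closeness >= 0 & m$closeness <= 1))
    expect_true(all(m$stress >= 0L) && is.integer(m$stress))
    expect_true(all(m$degree >= 0L) && is.integer(m$degree))
    # relabel nodes with a random permutation; metrics must follow the labels
    set.seed(seed)
    relabel <- stats::setNames(sample(sprintf("R%02d", 1:12)), net$nodes)
    net2 <- ppi_network(cbind(relabel[net$edges[, 1]], relabel[net$edges[, 2]]),
                        nodes = unname(relabel))
    m2 <- node_metrics(net2)
    idx <- match(unname(relabel[m$gene]), m2$gene)
    expect_equal(m$betweenness, m2$betweenness[idx])
    expect_equal(m$stress, m2$stress[idx])
    expect_equal(m$closeness, m2$closeness[idx])
    expect_equal(m$degree, m2$degree[idx])
  }
})

test_that("adding an edge never decreases any degree", {
  net <- random_graph(10, 0.2, seed = 31)
  deg <- degree_centrality(net)
  non_edges <- t(utils::combn(net$nodes, 2))
  have <- paste(net$edges[, 1], net$edges[, 2])
  non_edges <- non_edges[!paste(non_edges[, 1], non_edges[, 2]) %in% have, , drop = FALSE]
  for (r in seq_len(min(5, nrow(non_edges)))) {
    net2 <- ppi_network(rbind(net$edges, non_edges[r, ]), nodes = net$nodes)
    expect_true(all(degree_centrality(net2)[names(deg)] >= deg))
  }
})

test_that("all-in-one table equals the individual statistics columnwise", {
  net <- random_graph(15, 0.25, seed = 77)
  m <- node_metrics(net)
  expect_equal(stats::setNames(m$degree, m$gene), degree_centrality(net))
  expect_equal(stats::setNames(m$betweenness, m$gene), betweenness_centrality(net))
  expect_equal(stats::setNames(m$closeness, m$gene), closeness_centrality(net))
  expect_equal(stats::setNames(as.numeric(m$stress), m$gene), stress_centrality(net))
})

test_that("brute-force oracle refuses large graphs and handles empties", {
  expect_error(brute_force_metrics(random_graph(13, 0.3, seed = 1)),
               class = "ppiscreen_config_error")
  expect_equal(nrow(brute_force_metrics(ppi_network())), 0L)
})
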