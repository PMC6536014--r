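---
title: "Topology-based gene screening: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology-based gene screening: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppiscreen)
```

## The screening model

`ppiscreen` operationalizes a common topology-based biomarker screening
procedure. The input is a list of differentially expressed genes (DEGs) and
a scored interaction edge table in the STRING export style (`nodeA`,
`nodeB`, `combined_score` with scores in 0–1000). The pipeline:

1. **Network construction.** Edges at or above a confidence threshold are
   kept; the query network is the sub-network induced on the query genes
   that appear in the edge universe. Query genes the universe does not know
   are reported as *unrecognized*; recognized genes without a surviving
   edge remain in the network as isolated nodes. The graph is undirected
   and simple: self-loops are dropped and reciprocal duplicate rows are
   collapsed to their maximum score.
2. **Centrality.** Four statistics are computed per node on an unweighted
   view of the graph — degree, betweenness, closeness and stress. Edge
   scores are used only for thresholding, never as distances; this matches
   how interactive network-analysis tools treat STRING exports.
3. **Selection cascade.** Hubs are the top fraction of nodes by degree
   (default 10%), bottlenecks the top *k* by betweenness (default 10),
   hub-bottlenecks their intersection, and central nodes the
   hub-bottlenecks that also sit in the top-*k* lists by closeness and by
   stress. The four sets are nested by construction:
   `central_nodes ⊆ hub_bottlenecks = hubs ∩ bottlenecks`.

The rationale is standard in systems biology: interactomes are typically
scale-free, so a small number of high-degree nodes (hubs) carry network
integrity, while high-betweenness nodes (bottlenecks) control information
flow between regions. Genes that are both, and that additionally rank top
by closeness and stress, are the most defensible candidates.

## Statistics and their exact contracts

For a node $v$ in a connected component of size $n_c$:

- **Degree** $D(v)$: number of incident edges (integer; 0 for isolated
  nodes).
- **Betweenness** $BC(v) = \sum_{s \ne v \ne t} \sigma_{st}(v) / \sigma_{st}$
  over unordered pairs in $v$'s component, where $\sigma_{st}$ is the
  number of shortest $s$–$t$ paths and $\sigma_{st}(v)$ the number passing
  through $v$. Computed with Brandes' dependency accumulation, one
  breadth-first search per source. Normalization is per component, by
  $(n_c-1)(n_c-2)/2$, so values lie in $[0,1]$ even in disconnected
  graphs; nodes in components of size $\le 2$ get 0. `normalized = FALSE`
  returns the raw pair-dependency sum.
- **Closeness** $CC(v) = (n_c-1) / \sum_{u} d(v,u)$, the reciprocal mean
  intra-component distance. Isolated nodes get 0 by convention; harmonic
  closeness is deliberately not used, to match the per-component reading of
  screening reports.
- **Stress** $S(v)$: the number of shortest paths between unordered pairs
  of other nodes with $v$ interior, each distinct path counted once. It is
  an exact integer. Tools that count ordered pairs report doubled values;
  `stress_centrality(net, ordered = TRUE)` reproduces that convention.

Stress is accumulated in the same pass as betweenness: in the shortest-path
DAG from source $s$, $\psi_s(v)$ (the number of DAG paths from $v$ to
strictly deeper targets) satisfies $\psi_s(v) = \sum_{w: v \in pred(w)}
(1 + \psi_s(w))$, and $\sigma_{sv}\,\psi_s(v)$ counts the source-$s$
shortest paths through $v$; summing over sources counts every unordered
pair twice.

Because node iteration order is fixed (sorted symbols), floating-point
accumulation order — and hence every output byte — is reproducible across
runs.

An independent oracle, `brute_force_metrics()`, recomputes the full table
by literally enumerating all shortest paths per pair (guarded to $\le 12$
nodes). The test suite checks engine/oracle agreement on hundreds of random
graphs and cross-checks betweenness and degree against igraph.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `score_threshold` | 400 | Minimum combined score (0–1000) for an edge. 400 is the conventional medium-confidence STRING cutoff; source studies often leave their cutoff unstated, so it is explicit and configurable here. |
| `hub_fraction` | 0.10 | Fraction of analyzed nodes selected as hubs; `max(1, floor(f·n))` nodes. |
| `bottleneck_k` | 10 | Absolute size of the bottleneck set (screening practice uses an absolute top-10 here, not a fraction; both knobs exist). |
| `crossval_k` | hub-set size | Size of the closeness and stress top lists used to confirm hub-bottlenecks. The literature rarely states this list size; defaulting to the hub-set size reproduces the usual "all hub-bottlenecks confirmed" outcome while remaining a real filter. |
| `scope` | `main_component` | Whether the centrality table is computed on the main connected component or the whole network. With a 105-node main component inside a 114-node network, `floor(0.10·105) = 10` hubs; over all 114 nodes it would be 11 — the main-component scope is the one consistent with published hub counts. |
| `expand_ties` | `FALSE` | Tie policy at every cutoff: deterministic symbol-ascending truncation by default, or inclusion of all cutoff-tied genes. |

Gene symbols are upper-cased on ingestion and compared literally; alias
resolution (e.g. IL8 vs CXCL8) is out of scope, and query genes absent from
the edge universe are listed in a warning rather than silently dropped.

## The synthetic generator

`generate_network()` emulates the structural features the screening
assumes, with a known ground truth:

- a **scale-free main component** grown by Barabási–Albert preferential
  attachment (`attachment` edges per new node; default 2, which yields an
  average degree near 4 and a heavy degree tail — realistic for
  medium-confidence PPI subnetworks of ~100 DEGs);
- **planted central nodes**: each of `n_planted` nodes is additionally
  wired to a fixed fraction (`planted_coverage`) of the other connected
  nodes, making it simultaneously a degree, betweenness, closeness and
  stress extreme — the ground truth the cascade must recover;
- **isolated query genes** (`n_isolated`) appended without edges, mirroring
  DEGs the interactome recognizes but cannot connect to the rest of the
  query set.

Generation is a pure function of the spec (the caller's RNG state is saved
and restored), and `erdos_renyi_network()` provides a same-density
non-scale-free null for degree-tail contrast checks.

What the generator does *not* emulate: STRING's evidence channels and score
distribution (fixture scores are the constant 999), protein descriptions,
aliasing, and any correlation between expression change and topology.
Passing tests therefore demonstrate that the cascade's algorithmic
behaviour is correct and that planted topological signal is recovered; they
do not validate the biological premise that topological centrality implies
biomarker value on real data.

On disk, a fixture is the edge TSV, the gene list and a flat key–value
truth manifest. Isolated nodes are written as self-loop rows in the edge
table; the reader drops the loop edge but keeps the gene in the node
universe, so a write/read round trip preserves both the node set and the
edge set exactly.

## Numerical and degenerate-input choices

- Ties are always broken by symbol ascending after the ranking metric;
  the main component is chosen by size with ties broken by the
  lexicographically smallest member. Both choices exist purely for
  determinism.
- `hub_fraction` uses `floor` with a minimum of one selected node; on a
  network with fewer nodes than `bottleneck_k`, the whole node set is the
  bottleneck list.
- A network whose main component has fewer than two nodes (e.g. only
  isolated genes survive thresholding) cannot be screened; the pipeline
  raises a classed "degenerate network" error, which the command-line
  interface maps to exit code 4 (2 = usage, 3 = parse errors).
- Betweenness is accumulated in double precision; the engine/oracle
  agreement tests use a 1e-12 tolerance. Degree and stress are exact
  integers and compared identically.

## Problem sizes in the test suite

The suite validates the engine against exhaustive enumeration on 500
random graphs of 2–10 nodes, cascade invariants on over 200 random
networks of 8–30 nodes, and planted-node recovery on 50 seeded
100-node scale-free networks with one node wired to half the graph —
sizes chosen so the exhaustive oracle is transparently correct and the
whole suite runs in well under a minute per property family.

## Known limitations

- Symbols are matched literally; without alias mapping, a query list mixing
  synonyms will undercount recognized genes.
- Centrality is unweighted; confidence scores do not modulate distances.
- No statistical null is attached to hub status (no permutation testing) —
  the cascade is a deterministic ranking procedure, as in screening
  practice.
- Published absolute centrality values from specific studies depend on the
  interactome version and cutoff used there and are generally not
  reproducible from a gene list alone; this package reproduces the
  *procedure* and validates it on ground-truth simulations instead.
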