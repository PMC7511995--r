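---
title: "Community-aware backbone extraction: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community-aware backbone extraction: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science it implements:
the models and their assumptions, the parameters that matter, the numerical
choices made where the design was genuinely open, and what a green test
does and does not establish. It states no empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The problem

A weighted network's interesting structure — its hubs, its strong ties, the
nodes that glue communities together — is usually buried under a mass of
weak edges. A *backbone* is a small subgraph intended to keep exactly that
structure. Edge-statistical filters such as the disparity filter decide
edge by edge; the two methods implemented here instead start from **nodes**
that are structurally privileged: overlapping nodes (members of two or more
communities, which sit where communities meet and are known to be densely
wired) and hubs (top nodes by strength, the sum of incident edge weights).

## The two extractors

Both run the same four-stage pipeline (`extract_backbone()`):

1. **Cover.** An overlapping community cover is either supplied by the user
   (`read_cover()`) or detected with SLPA (`slpa()`).
2. **Seed subgraph.** *Ego* variant: the induced subgraph on the
   overlapping nodes `V_o` plus their one-step neighbours. *Hubs* variant:
   `V_o` plus the top-`t` non-overlapping nodes by strength, with `t` equal
   to the number of (non-overlapping) neighbours of `V_o`. Ranking hubs
   within the non-overlapping nodes makes both seed subgraphs the same
   size, which is what makes the common-node proportion between them a
   meaningful equal-size comparison; it also gives the natural clamping
   behaviour (`t` larger than the remaining nodes simply takes all of
   them).
3. **Edge pruning.** Edges are visited in increasing weight order
   (lexicographic endpoint tie-break) and removed under a connectivity
   constraint. Two readings of "removed as long as the sub-network remains
   connected" exist, and they differ materially:
   * *stop-at-first* (`prune = "stop"`, pipeline default): stop the sweep
     at the first edge whose removal would split a component. The result
     retains roughly twice the edges of a tree. This is the reading
     consistent with the edge densities that published backbones of the
     karate-club network exhibit (mean strength ≈ 12 and mean edge weight
     ≈ 3.3 imply ~1.8 edges per node, far denser than a tree).
   * *skip-and-continue* (`prune = "forest"`, and the default of the
     exported `prune_edges()`): skip bridges and keep sweeping, which
     provably reduces each component to its maximum-weight spanning forest.
     The implementation exploits that equivalence (a union-find Kruskal
     sweep over the reversed deletion order); the test suite checks it
     against a literal delete-and-re-BFS oracle on hundreds of random
     graphs, ties included.
4. **Size cut.** Nodes are removed greedily in increasing order of strength
   *measured in the original network* until at most `⌊s·N⌋` remain,
   skipping nodes whose removal would split a component (top-ranked nodes
   are privileged). If every remaining node is a cut vertex, the weakest is
   removed and the largest component kept. A final pruning pass and a
   largest-component step guarantee the published single-component
   property. `s = 0.3` is the conventional operating point.

Degenerate inputs: a cover without overlapping nodes leaves both methods
undefined (explicit error); `⌊s·N⌋ = 0` is clamped to one node; multi-component
seed subgraphs are pruned per component and reduced to the largest component
only at the very end.

## SLPA as implemented

Each node starts with its own label. For `T` iterations, nodes are visited
in a seeded random order; each neighbour *speaks* one label drawn from its
memory proportionally to frequency, and the listener appends the most
frequent label received. After `T` rounds each node keeps the labels
occupying at least a fraction `r` of its memory (or its single most
frequent label), and any community whose node set is contained in
another's is dropped — the standard nested-community clean-up.

Numerical choices worth knowing:

* **Listener tie-break is random, not lexicographic.** In the first
  iteration every received label is distinct, so *every* listener is tied;
  a deterministic smallest-label rule lets one label (the smallest name,
  typically attached to a hub) cascade and collapse the entire graph into
  one community — we verified this on the karate fixture, where all ten
  seeds produced a single community. Breaking ties uniformly from the
  seeded stream restores the classic behaviour while keeping runs exactly
  reproducible for a fixed seed.
* **Defaults `T = 100`, `r = 0.3`.** `T = 100` is comfortably past memory
  stabilisation for networks of this size. `r` trades overlap sensitivity
  for stability: at `r = 0.3` a secondary community must occupy 30% of a
  node's memory, which only happens for nodes with fairly balanced
  neighbourhoods. The overlap-detection literature often runs far lower
  (`r ≈ 0.05–0.1`).
* **Unweighted propagation.** The classic algorithm ignores edge weights;
  a weighted listener (`weighted = TRUE`) is available but in our
  experiments produced smaller, less stable overlaps on the bundled
  networks, so the default stays unweighted.
* **Mode dynamics under-detect overlap.** Because the listener keeps only
  the *most frequent* received label, the label stream is strongly
  autocorrelated: a node whose neighbourhood leans even mildly to one
  community gets locked into it. Consequently a perfectly balanced bridge
  between two 5-cliques is flagged overlapping in only about a third of
  seeds at `r = 0.3` (clique interiors essentially never are), and planted
  overlapping nodes in the synthetic benchmark are recovered well above
  chance but far below perfectly. The tests assert these measured
  behaviours rather than optimistic constants.

## Disparity filter and calibration

For a node of degree `k` the null model spreads its strength uniformly over
its `k` edges; the probability that a normalized weight `p_ij` is exceeded
under that null has the closed form `α_ij = (1 − p_ij)^(k−1)` (checked
against numeric quadrature to 1e−9 in the tests). Degree-one incidences are
assigned `α_ij = 1`: one edge gives no multiplicity to test against. An
edge is kept if significant on at least one side. Because the backbone node
count is a step function of `α` with jumps at the distinct scores,
`calibrate_alpha()` sweeps the score intervals exhaustively and returns the
midpoint of the interval achieving the closest node count to `⌊s·N⌋`
(the "smallest achieving α" does not exist under a strict inequality —
the achieving set is an open interval). No connectivity repair is applied:
a disconnected disparity backbone is a genuine, reported property of the
method.

## Comparison measures

All rankings sort by strength in the *original* graph with a lexicographic
tie-break, so the measures compare which nodes were selected, not how
pruning rewired them. Two conventions required a decision:

* **RBO at finite depth.** The geometric weights `(1−p)p^(d−1)` sum to 1
  only at infinite depth, yet identical finite rankings must score 1 (the
  published tables show exactly 1.0). The implementation therefore
  evaluates to depth `D = min(|X|, |Y|)` and normalizes by `1 − p^D`;
  `normalize = FALSE` gives the raw sum.
* **Kendall τ-a.** The numerator excludes pairs tied in either ranking;
  the denominator stays `n(n−1)/2` — ties shrink |τ| rather than being
  corrected away. Dense ranks are used, so equal strengths share a rank.
* **Unequal backbone sizes** (possible for the disparity filter): `A_n`
  compares the top-`⌊s·N⌋` ranked nodes of each backbone, the designed
  common size.
* **Effectiveness** is computed on the backbone's surviving-edge subgraph:
  `⟨β⟩` with unweighted shortest paths normalized by `(n−1)(n−2)/2` (0 for
  `n < 3`), `⟨k⟩` the mean strength within the backbone, `⟨w⟩` the mean
  surviving-edge weight. We note that evaluating instead on the induced
  subgraph of the backbone's node set (pass that subgraph to
  `effectiveness()` directly) brings the karate-club values in line with
  the magnitudes the literature reports, suggesting that published
  comparisons measured node-selection quality rather than the pruned edge
  set; the default here stays with the pruned backbone, which is the
  object the pipeline actually returns.

## The synthetic benchmark

`generate_planted_overlap()` states a small world: `n_c` communities of
equal size, consecutive pairs sharing a fixed number of nodes (the planted
overlap), dense strong intra-community edges (`p_in = 0.8`, discretized
log-normal weights with mean ≈ 6) and sparse weak inter-community edges
(`p_out = 0.05`, mean ≈ 2, i.e. intra weights about three times inter
weights — the right-skewed, integer-valued pattern of co-appearance and
message-count data). Stray components are bridged deterministically through
their strongest nodes, so the graph is always connected. It emulates
modularity, planted overlap and skewed weights; it does **not** emulate
heavy-tailed degree distributions, degree–weight correlations, or
hierarchical community structure, so a green test on it establishes
contract correctness (connectivity, size bounds, weight preservation,
ground-truth containment) rather than realism of any particular statistic.

## Known limitations

* SLPA at `r = 0.3` yields sparse, sometimes peripheral overlap sets; on
  the Les Misérables fixture the resulting covers have 5–9 communities and
  the ego/hubs backbones agree with each other less than the published
  ~92% (our multi-run mean is near 54%; the detector settings behind the
  published figure are not reported). The corresponding acceptance check is
  left failing rather than loosened.
* For the same reason the effectiveness comparison against the disparity
  filter does not reproduce the published strict ordering on all three
  statistics: the disparity filter keeps, by construction, each node's
  locally heaviest edges, so its mean surviving-edge weight is hard to beat
  unless the community-based node selection is at least as central.
* Pure-R SLPA is comfortable up to a few thousand nodes (`O(T·L)` label
  draws); beyond that a compiled implementation would be the next step.
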