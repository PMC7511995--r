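# netbackbone

Community-aware backbone extraction for weighted undirected networks.

Large weighted networks — co-appearance counts, message volumes, synapse
counts — hide their load-bearing structure under thousands of weak,
redundant ties. `netbackbone` reduces such a network to a *backbone*: a
small connected subgraph that keeps the structurally relevant nodes and the
strongest links. It implements two node-based filters that exploit the
overlapping community structure, the classic disparity filter as a
calibrated baseline, and the full evaluation suite needed to compare them.

## Methods

Let `G(V, E)` be a weighted undirected network with an overlapping
community cover (detected here with SLPA, the Speaker–Listener Label
Propagation Algorithm). Let `V_o` be the overlapping nodes (those with two
or more community labels).

* **Overlapping-nodes ego backbone (OE).** Induce the subgraph on
  `V_o ∪ N(V_o)` (the overlap plus its one-step neighbours), remove edges
  in increasing weight order while the sub-network stays connected, then
  keep only the top `⌊s·N⌋` nodes by weighted degree (strength),
  preserving connectivity.
* **Overlapping-nodes-and-hubs backbone (OH).** Same pipeline, starting
  from `V_o ∪ H_t`, where `H_t` are the top-`t` non-overlapping nodes by
  strength and `t = |N(V_o) \ V_o|`, so OE and OH start from equally sized
  node sets.
* **Disparity filter (DF).** Each edge weight is normalized by its
  endpoint's strength, `p_ij = w_ij / s_i`, and scored against a uniform
  null: `α_ij = (1 − p_ij)^(k_i − 1)`. Edges significant at level `α` on at
  least one side are kept; `α` is calibrated automatically so the backbone
  holds `⌊s·N⌋` nodes.

Backbones are compared by the common-node proportion
`A_n = |X ∩ Y| / n`, the top-10% rank overlap `A_t`, rank-biased overlap
`r = Σ_d (1−p) p^(d−1) · |X_:d ∩ Y_:d| / d`, Pearson `ρ` and Kendall `τ_a`
on the strength-ranked node lists, and by three effectiveness statistics of
the backbone itself: mean normalized betweenness `⟨β⟩`, mean strength
`⟨k⟩`, and mean surviving-edge weight `⟨w⟩`.

## Worked example

```r
library(netbackbone)

g   <- load_fixture("karate")            # 34 nodes, 78 weighted edges
cov <- slpa(g, T = 100, r = 0.3, seed = 2)
cov
#> community cover: 34 nodes, 2 communities, 1 overlapping

bb  <- extract_backbone(g, cov, method = "ego", s = 0.3, seed = 2)
bb
#> ego backbone: 10 nodes, 18 edges (1 component)
#>   s = 0.3

effectiveness(bb)
#> beta_mean    k_mean    w_mean
#>     0.075    12.600     3.500
```

The backbone keeps at most `⌊0.3 · 34⌋ = 10` nodes in a single connected
component; `effectiveness` says its nodes relay `β ≈ 0.08` of the pairwise
shortest paths on average, carry a mean strength of `12.6` inside the
backbone, and its surviving edges average weight `3.5` (on the karate
scale of 1–8).

A full multi-run comparison (averages over 10 SLPA runs, as commonly
reported):

```r
rep <- compare_backbones(g, methods = c("ego", "hubs", "disparity"),
                         s = 0.3, seeds = 1:40, min_runs = 10)
rep$similarity[rep$similarity$measure == "A_n", ]
#>             pair measure      mean        sd
#>         ego-hubs     A_n 0.6979365 0.2040628
#>    ego-disparity     A_n 0.4896429 0.1709411
#>   hubs-disparity     A_n 0.6717063 0.2204986
```

On karate the ego and hubs backbones share ~70% of their nodes on average
and each agrees less with the disparity filter — the qualitative headline
the community-aware methods are built on.

## Command line

```sh
inst/cli/netbackbone synth --communities 3 --size 20 --overlap 2 \
    --seed 7 --out g.edgelist --truth cover.txt
inst/cli/netbackbone communities g.edgelist --T 100 --r 0.3 --seed 1 \
    --out cover.txt
inst/cli/netbackbone extract g.edgelist --method ego --s 0.3 \
    --cover cover.txt --out backbone.gml
inst/cli/netbackbone compare g.edgelist --methods ego,hubs,disparity \
    --s 0.3 --runs 10 --seed 1 --out report.csv
```

Any whitespace-separated weighted edge list (`u v w`, `#` comments), GML or
GraphML file with a `weight` attribute is accepted.

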