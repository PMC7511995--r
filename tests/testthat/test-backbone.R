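path_graph <- function() {
  weighted_graph(data.frame(from = c("a", "b"), to = c("b", "c"),
                            weight = c(1, 2)))
}

test_that("ego_subnetwork is the union of closed neighbourhoods of the overlap", {
  g <- path_graph()
  cov <- community_cover(list(a = "1", b = c("1", "2"), c = "2"))
  sub <- ego_subnetwork(g, cov)
  expect_setequal(igraph::V(sub)$name, c("a", "b", "c"))
  expect_equal(sub$overlap, "b")

  # no overlapping nodes -> explicit error
  expect_error(ego_subnetwork(g, community_cover(list(a = "1", b = "1", c = "2"))),
               "no overlap in cover")

  # overlap nodes with no outside neighbours: V_q = V_o
  g2 <- weighted_graph(data.frame(from = c("a", "c"), to = c("b", "d"),
                                  weight = c(1, 1)))
  cov2 <- community_cover(list(a = c("1", "2"), b = c("1", "2"),
                               c = "3", d = "3"))
  expect_setequal(igraph::V(ego_subnetwork(g2, cov2))$name, c("a", "b"))

  # oracle: brute-force union of closed neighbourhoods on planted graphs
  for (sd in 1:5) {
    syn <- generate_planted_overlap(2, 10, 2, seed = sd)
    sub <- ego_subnetwork(syn$graph, syn$cover)
    closed <- unique(unlist(lapply(syn$overlap, function(v) {
      el <- igraph::as_edgelist(syn$graph)
      c(v, el[el[, 1] == v, 2], el[el[, 2] == v, 1])
    })))
    expect_setequal(igraph::V(sub)$name, closed)
  }
})

test_that("hubs_subnetwork takes top-strength non-overlap nodes, same size as ego", {
  # star: hub is the strongest node and the overlap's only neighbour
  g <- weighted_graph(data.frame(from = "hub", to = c("a", "b", "c"),
                                 weight = c(5, 1, 1)))
  cov <- community_cover(list(hub = "1", a = c("1", "2"), b = "1", c = "2"))
  ego <- ego_subnetwork(g, cov)
  hub <- hubs_subnetwork(g, cov)
  expect_setequal(igraph::V(hub)$name, igraph::V(ego)$name)  # coincident case
  expect_equal(igraph::vcount(hub), igraph::vcount(ego))

  # clamping: overlap adjacent to everything -> t = |V \ V_o|, V_y = V
  g2 <- weighted_graph(data.frame(from = "o", to = c("x", "y", "z"),
                                  weight = 1:3))
  cov2 <- community_cover(list(o = c("1", "2"), x = "1", y = "1", z = "2"))
  expect_setequal(igraph::V(hubs_subnetwork(g2, cov2))$name,
                  igraph::V(g2)$name)

  # generic: |V_y| = |V_q| whenever enough non-overlap nodes exist
  for (sd in 1:5) {
    syn <- generate_planted_overlap(3, 10, 2, seed = sd)
    expect_equal(igraph::vcount(hubs_subnetwork(syn$graph, syn$cover)),
                 igraph::vcount(ego_subnetwork(syn$graph, syn$cover)))
  }
})

test_that("prune_edges removes exactly the deletable low-weight edges", {
  tri <- weighted_graph(data.frame(from = c("a", "b", "a"),
                                   to = c("b", "c", "c"),
                                   weight = c(1, 2, 3)))
  pr <- prune_edges(tri)
  expect_setequal(edge_keys(pr), c("b|c", "a|c"))

  # a tree is untouched: every edge is a bridge
  tree <- weighted_graph(data.frame(from = c("a", "a", "b"),
                                    to = c("b", "c", "d"),
                                    weight = c(1, 2, 3)))
  expect_setequal(edge_keys(prune_edges(tree)), edge_keys(tree))

  # idempotence
  set.seed(5)
  g <- random_weighted_graph(20, 0.3)
  p1 <- prune_edges(g)
  expect_setequal(edge_keys(prune_edges(p1)), edge_keys(p1))

  # uniform weights: a spanning structure survives per component
  u <- random_weighted_graph(15, 0.4, wmax = 1)
  pu <- prune_edges(u)
  expect_equal(igraph::ecount(pu),
               igraph::vcount(u) - igraph::count_components(u))
  expect_equal(igraph::count_components(pu), igraph::count_components(u))
})

test_that("prune_edges agrees with the fresh-BFS deletion oracle", {
  set.seed(101)
  for (i in 1:25) {
    g <- random_weighted_graph(sample(6:30, 1), runif(1, 0.1, 0.45))
    if (igraph::ecount(g) == 0) next
    expect_setequal(edge_keys(prune_edges(g)), oracle_prune_bfs(g))
  }
})

test_that("stop_at_first pruning halts at the first bridge and keeps heavier edges", {
  # square with a light chord: the sweep deletes the chord (w=1) and then
  # a-b (w=2, cycle edge), meets the bridge b-c and stops, so c-d and a-d
  # survive even though a forest would not need both plus b-c
  sq <- weighted_graph(data.frame(from = c("a", "b", "c", "d", "a"),
                                  to = c("b", "c", "d", "a", "c"),
                                  weight = c(2, 3, 4, 5, 1)))
  pr <- prune_edges(sq, stop_at_first = TRUE)
  expect_setequal(edge_keys(pr), c("b|c", "c|d", "a|d"))
  # the kept set always contains the spec-default forest
  set.seed(17)
  for (i in 1:10) {
    g <- random_weighted_graph(15, 0.35)
    expect_true(all(edge_keys(prune_edges(g)) %in%
                    edge_keys(prune_edges(g, stop_at_first = TRUE))))
  }
})

test_that("apply_size_threshold cuts to floor(s*N) keeping connectivity", {
  set.seed(9)
  g <- random_weighted_graph(20, 0.35)
  sub <- prune_edges(g)
  expect_identical(apply_size_threshold(sub, g, 1), sub)       # s = 1
  expect_error(apply_size_threshold(sub, g, 0), "s must lie")
  expect_error(apply_size_threshold(sub, g, 1.5), "s must lie")

  cut <- apply_size_threshold(sub, g, 0.4)
  expect_equal(igraph::vcount(cut), 8L)                        # floor(0.4*20)
  expect_lte(igraph::count_components(cut), igraph::count_components(sub))

  # greedy-removal oracle: replay the stated rule step by step
  oracle <- sub
  while (igraph::vcount(oracle) > 8L) {
    nms <- igraph::V(oracle)$name
    wd <- weighted_degree(g, nms)
    cand <- nms[order(wd, nms)]
    base <- igraph::count_components(oracle)
    for (v in cand) {
      trial <- igraph::delete_vertices(oracle, v)
      if (igraph::count_components(trial) <= base) { oracle <- trial; break }
    }
  }
  expect_setequal(igraph::V(cut)$name, igraph::V(oracle)$name)

  # already small enough -> unchanged
  small <- igraph::induced_subgraph(g, igraph::V(g)$name[1:3])
  expect_identical(apply_size_threshold(small, g, 0.4), small)
})

test_that("extract_backbone meets its contract on fixtures and planted graphs", {
  g <- load_fixture("karate")
  for (sd in 1:3) {
    cov <- slpa(g, T = 50, r = 0.3, seed = sd)
    if (length(overlapping_nodes(cov)) == 0) next
    for (m in c("ego", "hubs")) {
      bb <- extract_backbone(g, cov, m, s = 0.3, seed = sd)
      expect_lte(igraph::vcount(bb$subgraph), floor(0.3 * 34))
      expect_equal(igraph::count_components(bb$subgraph), 1L)
      expect_s3_class(bb, "backbone")
      expect_equal(bb$method, m)
      expect_true(is.numeric(bb$provenance$m) && bb$provenance$m >= 1)
    }
  }
  expect_error(extract_backbone(g, NULL, "ego"), "require a community cover")
})

test_that("backbone edges keep their original weights", {
  for (sd in 1:4) {
    syn <- generate_planted_overlap(2, 12, 2, seed = sd)
    bb <- extract_backbone(syn$graph, syn$cover, "ego", s = 0.5)
    el <- igraph::as_edgelist(bb$subgraph)
    for (j in seq_len(nrow(el))) {
      orig <- igraph::get_edge_ids(syn$graph, c(el[j, 1], el[j, 2]))
      expect_gt(orig, 0)
      expect_equal(igraph::E(bb$subgraph)$weight[j],
                   igraph::E(syn$graph)$weight[orig])
    }
  }
})

test_that("node sets are nested as s shrinks (same cover, same greedy order)", {
  for (sd in 1:4) {
    syn <- generate_planted_overlap(3, 10, 2, seed = sd)
    prev <- NULL
    for (s in c(0.8, 0.5, 0.3, 0.15)) {
      bb <- extract_backbone(syn$graph, syn$cover, "ego", s = s)
      if (!is.null(prev)) expect_true(all(backbone_nodes(bb) %in% prev))
      prev <- backbone_nodes(bb)
    }
  }
})
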