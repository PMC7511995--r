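test_that("common_node_proportion counts shared members over the set size", {
  expect_equal(common_node_proportion(c("a", "b"), c("a", "b")), 1)
  expect_equal(common_node_proportion(c("a", "b"), c("x", "y")), 0)
  expect_equal(common_node_proportion(c("a", "b", "c", "d"),
                                      c("a", "b", "x", "y")), 0.5)
  expect_error(common_node_proportion(character(0), character(0)), "empty")
  expect_warning(common_node_proportion(c("a", "b", "c"), c("a", "b")),
                 "differ in size")
})

test_that("top_t_overlap compares top strength-ranked sets", {
  g <- weighted_graph(data.frame(from = c("h", "h", "h", "m", "m"),
                                 to = c("a", "b", "c", "a", "b"),
                                 weight = c(5, 5, 5, 2, 2)))
  # N = 6 would give t = 0; t is clamped to 1 and "h" is the top node
  expect_equal(suppressWarnings(top_t_overlap(g, c("h", "a"), 0.1)), 1)
  expect_equal(suppressWarnings(top_t_overlap(g, c("a", "c"), 0.1)), 0)
  karate <- load_fixture("karate")
  top <- utils::head(rank_nodes(karate)$node, 3)
  expect_equal(top_t_overlap(karate, top, 0.1), 1)   # t = floor(3.4) = 3
})

test_that("rank_biased_overlap matches the hand-computed example", {
  expect_equal(rank_biased_overlap(letters[1:4], letters[1:4], 0.7), 1)
  expect_equal(rank_biased_overlap(c("a", "b"), c("x", "y"), 0.7), 0)
  # X=[a,b,c], Y=[b,a,c], p=0.5: unnormalized 0.375, normalized 0.375/0.875
  expect_equal(rank_biased_overlap(c("a", "b", "c"), c("b", "a", "c"), 0.5,
                                   normalize = FALSE), 0.375)
  expect_equal(rank_biased_overlap(c("a", "b", "c"), c("b", "a", "c"), 0.5),
               0.375 / 0.875, tolerance = 1e-12)
  expect_error(rank_biased_overlap(c("a"), c("a"), 1.2), "p must lie")
})

test_that("rank_biased_overlap is symmetric and matches direct summation", {
  set.seed(13)
  for (i in 1:20) {
    n <- sample(3:30, 1)
    X <- sample(sprintf("e%02d", 1:40), n)
    Y <- sample(sprintf("e%02d", 1:40), sample(3:30, 1))
    p <- runif(1, 0.05, 0.95)
    r_xy <- rank_biased_overlap(X, Y, p)
    expect_equal(r_xy, oracle_rbo(X, Y, p), tolerance = 1e-12)
    expect_equal(r_xy, rank_biased_overlap(Y, X, p), tolerance = 1e-12)
    expect_gte(r_xy, 0); expect_lte(r_xy, 1 + 1e-12)
  }
  # appending an agreeing element never decreases the overlap
  X <- c("a", "b", "c"); Y <- c("a", "c", "b")
  expect_gte(rank_biased_overlap(c(X, "z"), c(Y, "z"), 0.8),
             rank_biased_overlap(X, Y, 0.8))
})

test_that("pearson_correlation matches its definition", {
  x <- c(1, 2, 3, 5)
  expect_equal(pearson_correlation(x, 2 * x + 1), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  y <- c(2, 1, 4, 5)
  expect_equal(pearson_correlation(x, y), stats::cor(x, y), tolerance = 1e-12)
  expect_error(pearson_correlation(x, rep(3, 4)), "zero variance")
  expect_error(pearson_correlation(x, y[1:3]), "same length")
})

test_that("kendall_tau is tau-a with tie-excluding numerator", {
  expect_equal(kendall_tau(1:5, 1:5), 1)
  expect_equal(kendall_tau(1:5, 5:1), -1)
  set.seed(19)
  for (i in 1:20) {
    x <- sample(1:5, 8, replace = TRUE)   # ties on purpose
    y <- sample(1:5, 8, replace = TRUE)
    expect_equal(kendall_tau(x, y), oracle_kendall(x, y), tolerance = 1e-12)
    expect_gte(kendall_tau(x, y), -1); expect_lte(kendall_tau(x, y), 1)
  }
  # ties in either margin shrink |tau| through the fixed denominator
  expect_equal(kendall_tau(c(1, 1, 2), c(1, 2, 3)), 2 / 3)
})

test_that("kendall and pearson are 1 under strictly monotone transforms", {
  set.seed(29)
  x <- sort(runif(12), decreasing = TRUE)
  y <- exp(2 * x) + 1
  expect_equal(kendall_tau(x, y), 1)
  expect_equal(pearson_correlation(rank(x), rank(y)), 1)
})

test_that("effectiveness matches closed forms and the brute-force oracle", {
  star <- weighted_graph(data.frame(from = "c0", to = paste0("l", 1:4),
                                    weight = rep(1, 4)))
  e <- effectiveness(star)
  expect_equal(unname(e["beta_mean"]), 1 / 5)   # center 1, leaves 0
  expect_equal(unname(e["w_mean"]), 1)
  expect_equal(unname(e["k_mean"]), mean(c(4, 1, 1, 1, 1)))

  clique <- disjoint_cliques(1, 5)
  expect_equal(unname(effectiveness(clique)["beta_mean"]), 0)

  # dyad: fewer than 3 nodes -> beta 0 by convention
  dyad <- weighted_graph(data.frame(from = "a", to = "b", weight = 2))
  expect_equal(unname(effectiveness(dyad)["beta_mean"]), 0)

  set.seed(37)
  g <- random_weighted_graph(15, 0.3)
  e2 <- effectiveness(g)
  expect_equal(unname(e2["beta_mean"]), mean(oracle_betweenness(g)),
               tolerance = 1e-10)
  expect_equal(unname(e2["k_mean"]), mean(weighted_degree(g)))
  expect_equal(unname(e2["w_mean"]), mean(igraph::E(g)$weight))
})

test_that("identical backbones compare as perfectly similar with zero spread", {
  syn <- generate_planted_overlap(2, 10, 2, seed = 3)
  rep <- compare_backbones(syn$graph, methods = c("ego", "hubs"), s = 1,
                           seeds = 1:2, cover = syn$cover)
  # with s = 1 and a fixed cover, runs are identical -> sd must vanish
  expect_true(all(rep$similarity$sd < 1e-12))
  expect_equal(rep$n_runs, 2L)
  sims <- backbone_similarity(syn$graph,
                              extract_backbone(syn$graph, syn$cover, "ego"),
                              extract_backbone(syn$graph, syn$cover, "ego"))
  expect_equal(unname(sims["A_n"]), 1)
  expect_equal(unname(sims["pearson"]), 1)
  expect_equal(unname(sims["kendall"]), 1)
  expect_true(all(sims[grep("rbo", names(sims))] == 1))
})
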