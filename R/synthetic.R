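# Planted-overlap benchmark generator and bundled real fixtures.

#' Generate a weighted graph with planted overlapping communities
#'
#' Builds a planted-partition graph of `n_communities` communities of
#' `community_size` nodes each, where consecutive community pairs share
#' `overlap_per_pair` nodes (the planted overlapping nodes, which draw
#' intra-community edges into all their communities). Pairs of nodes
#' sharing a community are connected with probability `p_in` and weights
#' from a discretized log-normal with parameters `w_in`; all other pairs
#' with probability `p_out` and weights from `w_out` (lower mean — weak
#' inter-community ties). If the draw is disconnected, each stray component
#' is bridged to the main one through its strongest node, so the output is
#' always connected. Deterministic for a fixed seed.
#'
#' Defaults emulate the modular, right-skewed-weight structure of small
#' co-appearance and message-count networks: three communities of 20 with
#' pairwise overlaps of 2, strong dense intra ties (`p_in = 0.8`, mean
#' weight about 6) and sparse weak inter ties (`p_out = 0.05`, mean weight
#' about 2).
#'
#' @param n_communities number of communities (>= 2).
#' @param community_size nodes per community.
#' @param overlap_per_pair nodes shared by each consecutive community pair
#'   (>= 0, < `community_size / 2`).
#' @param p_in,p_out intra- / inter-community edge probabilities in (0, 1],
#'   with `p_out` allowed to be 0; `p_out < p_in` required.
#' @param w_in,w_out numeric `c(meanlog, sdlog)` of the log-normal weight
#'   distributions (weights are rounded and floored at 1).
#' @param seed integer seed; `NULL` uses the session RNG stream.
#' @return list with elements `graph` (weighted igraph), `cover` (the
#'   ground-truth [community_cover()]) and `overlap` (planted overlapping
#'   node names).
#' @export
generate_planted_overlap <- function(n_communities = 3L, community_size = 20L,
                                     overlap_per_pair = 2L,
                                     p_in = 0.8, p_out = 0.05,
                                     w_in = c(meanlog = log(6), sdlog = 0.5),
                                     w_out = c(meanlog = log(2), sdlog = 0.5),
                                     seed = NULL) {
  n_communities <- as.integer(n_communities)
  community_size <- as.integer(community_size)
  overlap_per_pair <- as.integer(overlap_per_pair)
  if (n_communities < 2L) stop("need at least 2 communities")
  if (community_size < 2L) stop("community_size must be >= 2")
  if (overlap_per_pair < 0L || 2L * overlap_per_pair >= community_size)
    stop("infeasible spec: overlap_per_pair must be < community_size / 2")
  if (p_in <= 0 || p_in > 1 || p_out < 0 || p_out > 1 || p_out >= p_in)
    stop("require 0 <= p_out < p_in <= 1")

  stride <- community_size - overlap_per_pair
  n_total <- n_communities * community_size -
    (n_communities - 1L) * overlap_per_pair
  nodes <- sprintf("n%03d", seq_len(n_total))
  members <- lapply(seq_len(n_communities), function(i) {
    nodes[(i - 1L) * stride + seq_len(community_size)]
  })
  names(members) <- sprintf("C%d", seq_len(n_communities))

  membership <- vector("list", n_total)
  names(membership) <- nodes
  for (cn in names(members))
    for (v in members[[cn]]) membership[[v]] <- c(membership[[v]], cn)
  cover <- community_cover(membership)
  planted <- overlapping_nodes(cover)

  g <- with_seed(seed, {
    pairs <- t(utils::combn(nodes, 2))
    shared <- mapply(function(u, v) {
      length(intersect(membership[[u]], membership[[v]])) > 0L
    }, pairs[, 1], pairs[, 2])
    prob <- ifelse(shared, p_in, p_out)
    drawn <- stats::runif(nrow(pairs)) < prob
    mk_w <- function(k, par) pmax(1, round(stats::rlnorm(k, par[[1]], par[[2]])))
    w <- numeric(nrow(pairs))
    w[shared] <- mk_w(sum(shared), w_in)
    w[!shared] <- mk_w(sum(!shared), w_out)
    edges <- data.frame(from = pairs[drawn, 1], to = pairs[drawn, 2],
                        weight = w[drawn], stringsAsFactors = FALSE)
    gg <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                        vertices = data.frame(name = nodes))
    # deterministic connectivity repair: bridge every stray component to
    # the largest one through their strongest nodes
    comp <- igraph::components(gg)
    if (comp$no > 1L) {
      main <- which.max(comp$csize)
      strongest <- function(ci) {
        vs <- igraph::V(gg)$name[comp$membership == ci]
        rank_nodes(gg, vs)$node[1L]
      }
      anchor <- strongest(main)
      for (ci in setdiff(seq_len(comp$no), main)) {
        gg <- igraph::add_edges(gg, c(strongest(ci), anchor),
                                weight = mk_w(1L, w_out))
      }
    }
    gg
  })
  list(graph = as_weighted_graph(g, warn = FALSE), cover = cover,
       overlap = planted)
}

#' Load a bundled real-world fixture network
#'
#' Two classical weighted toy networks ship with the package as plain edge
#' lists: `"karate"` — Zachary's karate club (34 members, edge weight =
#' strength of association, 1 to 8) — and `"lesmis"` — the Les Miserables
#' character co-appearance network (77 characters, edge weight = number of
#' chapters shared).
#'
#' @param name `"karate"` or `"lesmis"`.
#' @return a weighted igraph object.
#' @export
load_fixture <- function(name = c("karate", "lesmis")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".edgelist"),
                      package = "netbackbone")
  if (!nzchar(path)) stop("fixture not found: ", name)
  read_weighted_graph(path, format = "edgelist")
}
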