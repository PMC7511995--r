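# Similarity and effectiveness measures for comparing backbones:
# common-node proportion, top-rank overlap, rank-biased overlap,
# Pearson and Kendall correlation, and mean betweenness / strength /
# link weight.

#' Proportion of common nodes between two equal-size sets
#'
#' `A_n = |X intersect Y| / n` for two node sets of the same size `n`.
#' If the sets differ in size a warning is emitted and the smaller size is
#' used as `n` (truncation of ranked lists is handled by the callers that
#' know the ranking).
#'
#' @param X,Y character vectors of node names.
#' @return a number in \[0, 1\].
#' @export
common_node_proportion <- function(X, Y) {
  X <- unique(as.character(X)); Y <- unique(as.character(Y))
  if (length(X) == 0L && length(Y) == 0L)
    stop("cannot compare two empty node sets")
  if (length(X) != length(Y))
    warning(sprintf("node sets differ in size (%d vs %d); using the smaller",
                    length(X), length(Y)))
  n <- min(length(X), length(Y))
  length(intersect(X, Y)) / n
}

#' Overlap with the top-ranked nodes of the original network
#'
#' `A_t`: the top `t = max(1, floor(t_fraction * N))` nodes of the original
#' graph by weighted degree are compared with the top `t` nodes of the
#' backbone (ranked by their weighted degree in the original graph); the
#' result is the intersection size divided by `t`. A backbone smaller than
#' `t` is compared in full, with a warning.
#'
#' @param g the original weighted graph.
#' @param backbone_nodes character vector of backbone node names.
#' @param t_fraction fraction of top-ranked nodes to compare; default 0.1.
#' @return a number in \[0, 1\].
#' @export
top_t_overlap <- function(g, backbone_nodes, t_fraction = 0.1) {
  t <- max(1L, floor(t_fraction * igraph::vcount(g)))
  top_g <- utils::head(rank_nodes(g)$node, t)
  if (length(backbone_nodes) < t)
    warning("backbone smaller than t; comparing against all backbone nodes")
  top_b <- utils::head(rank_nodes(g, backbone_nodes)$node, t)
  length(intersect(top_g, top_b)) / t
}

#' Rank-biased overlap of two rankings
#'
#' `r(X, Y) = sum_d w_d A_d`, where `A_d` is the proportion of common
#' elements of the two rankings at depth `d` and `w_d = (1 - p) p^(d - 1)`.
#' Small `p` concentrates the weight on the top of the rankings. The sum is
#' evaluated to the finite depth `D = min(|X|, |Y|)`; since the geometric
#' weights only sum to 1 at infinite depth, the finite sum is by default
#' normalized by `1 - p^D` so that two identical rankings score exactly 1.
#'
#' @param X,Y rankings: character vectors or `ranked_nodes` data frames
#'   (the `node` column is used).
#' @param p weight decay parameter in (0, 1).
#' @param normalize divide by `1 - p^D`? Default `TRUE`.
#' @return a number in \[0, 1\].
#' @export
rank_biased_overlap <- function(X, Y, p, normalize = TRUE) {
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p >= 1)
    stop("p must lie strictly inside (0, 1)")
  X <- ranking_vector(X); Y <- ranking_vector(Y)
  if (length(X) == 0L || length(Y) == 0L) stop("rankings must be non-empty")
  D <- min(length(X), length(Y))
  X <- X[seq_len(D)]; Y <- Y[seq_len(D)]
  # element i of X enters the overlap at depth max(i, position in Y)
  pos <- match(X, Y)
  entry <- pmax(seq_len(D), pos)
  entry <- entry[!is.na(entry) & entry <= D]
  overlap <- cumsum(tabulate(entry, nbins = D))   # |X_{:d} intersect Y_{:d}|
  d <- seq_len(D)
  r <- sum((1 - p) * p^(d - 1) * overlap / d)
  if (normalize) r <- r / (1 - p^D)
  r
}

ranking_vector <- function(x) {
  if (inherits(x, "ranked_nodes") || is.data.frame(x)) x <- x$node
  x <- as.character(x)
  if (anyDuplicated(x)) stop("a ranking must not contain duplicate elements")
  x
}

#' Pearson correlation of two sequences
#'
#' Product-moment coefficient, computed directly from its definition. Used
#' on the weighted-degree sequences of two ordered backbone node sets.
#'
#' @param x,y numeric vectors of equal length `n >= 2`.
#' @return a number in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 2L) stop("need at least two observations")
  dx <- x - mean(x); dy <- y - mean(y)
  den <- sqrt(sum(dx^2) * sum(dy^2))
  if (den == 0) stop("zero variance: Pearson correlation is undefined")
  sum(dx * dy) / den
}

#' Kendall tau-a rank correlation
#'
#' `tau = (n_c - n_d) / (n (n - 1) / 2)` over all pairs of positions, where
#' a pair is concordant if both sequences order it the same way and
#' discordant if they disagree; pairs tied in either sequence count as
#' neither (the denominator is *not* tie-corrected — this is tau-a).
#' Rankings may be given as `ranked_nodes` objects, in which case dense
#' ranks of the weighted degrees are used (tied degrees share a rank).
#'
#' @param X,Y numeric vectors (ranks or scores) of equal length `n >= 2`,
#'   or `ranked_nodes` data frames.
#' @return a number in \[-1, 1\].
#' @export
kendall_tau <- function(X, Y) {
  x <- rank_values(X); y <- rank_values(Y)
  if (length(x) != length(y)) stop("X and Y must have the same length")
  n <- length(x)
  if (n < 2L) stop("need at least two observations")
  sx <- sign(outer(x, x, "-")); sy <- sign(outer(y, y, "-"))
  prod <- sx * sy
  up <- upper.tri(prod)
  nc <- sum(prod[up] > 0)
  nd <- sum(prod[up] < 0)
  (nc - nd) / (n * (n - 1) / 2)
}

# Dense descending ranks from a ranked_nodes object (ties share a rank),
# or pass numeric input through.
rank_values <- function(x) {
  if (inherits(x, "ranked_nodes") || is.data.frame(x)) {
    wd <- x$weighted_degree
    return(match(-wd, sort(unique(-wd))))
  }
  as.numeric(x)
}

#' Backbone effectiveness measures
#'
#' Three summary statistics of a backbone subgraph:
#' * `beta_mean` — mean betweenness centrality of the backbone nodes,
#'   computed on the backbone with unweighted shortest paths and normalized
#'   by `(n - 1)(n - 2) / 2` (0 by convention for fewer than 3 nodes);
#' * `k_mean` — mean weighted degree (strength) within the backbone
#'   (optionally within `degree_graph`, e.g. the original network);
#' * `w_mean` — mean weight of the surviving edges.
#'
#' @param b a `backbone` object or a weighted igraph subgraph.
#' @param weighted_betweenness use edge weights as shortest-path distances?
#'   Default `FALSE` (topological paths).
#' @param degree_graph optional graph in which to measure the weighted
#'   degree of the backbone nodes; default is the backbone subgraph itself.
#' @return named numeric vector `c(beta_mean, k_mean, w_mean)`.
#' @export
effectiveness <- function(b, weighted_betweenness = FALSE,
                          degree_graph = NULL) {
  sub <- if (inherits(b, "backbone")) b$subgraph else b
  n <- igraph::vcount(sub)
  if (n == 0L) stop("empty backbone")
  beta <- if (n < 3L) 0 else {
    bw <- igraph::betweenness(
      sub, directed = FALSE,
      weights = if (weighted_betweenness) igraph::E(sub)$weight else NA,
      normalized = TRUE)
    mean(bw)
  }
  kg <- if (is.null(degree_graph)) sub else degree_graph
  k_mean <- mean(weighted_degree(kg, igraph::V(sub)$name))
  w_mean <- if (igraph::ecount(sub) > 0L) mean(igraph::E(sub)$weight)
            else NA_real_
  c(beta_mean = beta, k_mean = k_mean, w_mean = w_mean)
}
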