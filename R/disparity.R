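# Disparity filter baseline (Serrano-Boguna-Vespignani), with automatic
# calibration of the significance level to a target backbone size.

#' Disparity-filter edge significance scores
#'
#' For every node `i` with degree `k_i >= 2`, each incident edge weight is
#' normalized by the node strength, `p_ij = w_ij / s_i`, and tested against
#' a null model in which the `k_i` normalized weights are uniformly
#' distributed: the tail probability is `alpha_ij = (1 - p_ij)^(k_i - 1)`
#' (the closed form of the integral `(k-1) * int_0^{p} (1-x)^{k-2} dx`
#' complement). Degree-one incidences carry `alpha_ij = 1` — a single edge
#' gives no multiplicity to test against. Small `alpha_ij` means the edge is
#' significantly heavier than the null expects at that endpoint.
#'
#' @param g a weighted graph.
#' @return a `disparity_scores` data frame, one row per edge, with columns
#'   `from`, `to`, `weight`, `alpha_from`, `alpha_to` (the score at each
#'   endpoint) and `alpha_min = min(alpha_from, alpha_to)`.
#' @export
disparity_scores <- function(g) {
  g <- as_weighted_graph(g, warn = FALSE)
  el <- igraph::as_edgelist(g, names = TRUE)
  w <- igraph::E(g)$weight
  deg <- igraph::degree(g)
  str <- igraph::strength(g, weights = w)
  side <- function(endpoint) {
    k <- deg[endpoint]
    p <- w / str[endpoint]
    ifelse(k < 2, 1, (1 - p)^(k - 1))
  }
  a_from <- side(el[, 1])
  a_to <- side(el[, 2])
  out <- data.frame(from = el[, 1], to = el[, 2], weight = w,
                    alpha_from = as.numeric(a_from),
                    alpha_to = as.numeric(a_to),
                    alpha_min = pmin(as.numeric(a_from), as.numeric(a_to)),
                    stringsAsFactors = FALSE)
  class(out) <- c("disparity_scores", "data.frame")
  out
}

#' Disparity-filter backbone
#'
#' Keeps every edge that is significant at level `alpha` for at least one
#' of its endpoints (`alpha_ij < alpha` or `alpha_ji < alpha`); backbone
#' nodes are the endpoints of the kept edges. Unlike the community-aware
#' backbones, no connectivity repair is applied — the result may be
#' disconnected, or empty if `alpha` is below every score.
#'
#' @param g a weighted graph.
#' @param alpha significance level in (0, 1).
#' @return a `backbone` object with `method = "disparity"`.
#' @export
disparity_backbone <- function(g, alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1)
    stop("alpha must lie strictly inside (0, 1)")
  g <- as_weighted_graph(g, warn = FALSE)
  sc <- disparity_scores(g)
  keep <- which(sc$alpha_min < alpha)
  sub <- igraph::subgraph_from_edges(g, eids = keep, delete.vertices = TRUE)
  new_backbone(sub, "disparity",
               params = list(s = NULL, alpha = alpha, seed = NULL),
               provenance = list(n_edges_tested = igraph::ecount(g)))
}

#' Calibrate the disparity significance level to a target size
#'
#' The node count of the disparity backbone is a step function of `alpha`
#' that jumps at the distinct edge scores. This sweeps all candidate
#' thresholds and returns an `alpha` whose backbone node count is the
#' closest achievable to `floor(target_fraction * N)`; among equally close
#' counts the smaller count — and for one count the smallest candidate
#' interval — wins. If the target is not exactly reachable a warning is
#' emitted and the best achievable level is returned.
#'
#' @param g a weighted graph.
#' @param target_fraction desired backbone size as a fraction of the nodes
#'   of `g`, in (0, 1].
#' @return the calibrated `alpha` (numeric scalar in (0, 1)), with the
#'   achieved node count attached as attribute `nodes`.
#' @export
calibrate_alpha <- function(g, target_fraction) {
  if (!is.numeric(target_fraction) || length(target_fraction) != 1L ||
      target_fraction <= 0 || target_fraction > 1)
    stop("target_fraction must lie in (0, 1]")
  g <- as_weighted_graph(g, warn = FALSE)
  n_target <- max(1L, floor(target_fraction * igraph::vcount(g)))
  sc <- disparity_scores(g)
  # candidate alphas: midpoints of the intervals between consecutive
  # distinct scores (plus the open intervals at 0 and 1)
  uniq <- sort(unique(sc$alpha_min))
  breaks <- unique(c(0, uniq[uniq < 1], 1))
  cand <- (utils::head(breaks, -1) + utils::tail(breaks, -1)) / 2
  counts <- vapply(cand, function(a) {
    length(unique(c(sc$from[sc$alpha_min < a], sc$to[sc$alpha_min < a])))
  }, numeric(1))
  err <- abs(counts - n_target)
  best <- which(err == min(err))
  # prefer the smaller backbone, then the smallest alpha
  best <- best[order(counts[best], cand[best])][1L]
  if (counts[best] != n_target)
    warning(sprintf(
      "target of %d nodes not exactly reachable; best achievable is %d",
      n_target, counts[best]))
  structure(cand[best], nodes = counts[best])
}
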