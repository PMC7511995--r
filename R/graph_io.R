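#' netbackbone: community-aware backbone extraction for weighted networks
#'
#' Tools to reduce a weighted undirected network to its backbone using the
#' overlapping community structure: the overlapping-nodes ego backbone and the
#' overlapping-nodes-and-hubs backbone, plus the disparity filter baseline,
#' the SLPA overlapping community detector, a planted-overlap synthetic
#' generator, and similarity/effectiveness measures for comparing backbones.
#'
#' Graphs are plain \pkg{igraph} objects: undirected, with a character
#' `name` vertex attribute and a strictly positive numeric `weight` edge
#' attribute. All functions in the package validate these invariants.
#'
#' @keywords internal
#' @import igraph
"_PACKAGE"

# ---------------------------------------------------------------------------
# Core weighted-graph type: an undirected igraph with named vertices and
# strictly positive edge weights, no loops, no multi-edges.
# ---------------------------------------------------------------------------

#' Validate and normalize a weighted graph
#'
#' Coerces an igraph object into the canonical form used throughout the
#' package: undirected, simple (no loops or parallel edges), every vertex
#' named, every edge carrying a strictly positive finite numeric weight.
#'
#' Directed input is symmetrized by summing reciprocal weights (with a
#' warning). Self-loops are dropped with a warning. Parallel edges collapse
#' to the maximum weight ("strongest tie" policy), with a warning.
#'
#' @param g an igraph object with a `weight` edge attribute.
#' @param warn emit warnings for repairs (loops, duplicates, direction)?
#' @return a validated undirected igraph object.
#' @export
as_weighted_graph <- function(g, warn = TRUE) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::vcount(g) < 1L)
    stop("graph must have at least one node")
  if (!("weight" %in% igraph::edge_attr_names(g)) && igraph::ecount(g) > 0L)
    stop("weights required: graph has no 'weight' edge attribute")
  if (is.null(igraph::V(g)$name))
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
  igraph::V(g)$name <- as.character(igraph::V(g)$name)
  if (igraph::ecount(g) > 0L) {
    w <- igraph::E(g)$weight
    if (!is.numeric(w) || anyNA(w) || any(!is.finite(w)))
      stop("edge weights must be finite numbers")
    if (any(w <= 0))
      stop("edge weights must be strictly positive (found weight <= 0)")
  }
  if (igraph::is_directed(g)) {
    if (warn) warning("directed input symmetrized by summing reciprocal weights")
    g <- igraph::as_undirected(g, mode = "collapse",
                               edge.attr.comb = list(weight = "sum"))
  }
  n_loops <- sum(igraph::which_loop(g))
  if (n_loops > 0L) {
    if (warn) warning(sprintf("dropped %d self-loop(s)", n_loops))
    g <- igraph::simplify(g, remove.multiple = FALSE, remove.loops = TRUE)
  }
  n_multi <- sum(igraph::which_multiple(g))
  if (n_multi > 0L) {
    if (warn) warning(sprintf(
      "collapsed %d duplicate edge(s), keeping the maximum weight", n_multi))
    g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE,
                          edge.attr.comb = list(weight = "max"))
  }
  g
}

#' Build a weighted graph from an edge data frame
#'
#' @param edges data frame with columns `from`, `to`, `weight`.
#' @param warn passed to [as_weighted_graph()].
#' @return an undirected weighted igraph object.
#' @export
weighted_graph <- function(edges, warn = TRUE) {
  stopifnot(is.data.frame(edges), ncol(edges) >= 3L)
  names(edges)[1:3] <- c("from", "to", "weight")
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE)
  as_weighted_graph(g, warn = warn)
}

#' Read a weighted network from a file
#'
#' Supported formats: whitespace-separated weighted edge list (`u v w`, lines
#' starting with `#` are comments), GML and GraphML (both must carry a
#' `weight` edge attribute). Unweighted input is rejected.
#'
#' @param path path to the network file.
#' @param format one of `"edgelist"`, `"gml"`, `"graphml"`; by default
#'   guessed from the file extension (falling back to edge list).
#' @return an undirected weighted igraph object (see [as_weighted_graph()]).
#' @export
read_weighted_graph <- function(path, format = c("auto", "edgelist", "gml", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, gml = "gml", graphml = "graphml", xml = "graphml",
                     "edgelist")
  }
  if (format == "edgelist") {
    lines <- readLines(path, warn = FALSE)
    keep <- !grepl("^\\s*(#|$)", lines)
    idx <- which(keep)
    if (length(idx) == 0L) stop("no edges found in ", path)
    toks <- strsplit(trimws(lines[idx]), "\\s+")
    nt <- lengths(toks)
    if (any(nt < 3L))
      stop(sprintf("weights required: line %d of %s has no weight column",
                   idx[which(nt < 3L)[1]], path))
    if (any(nt > 3L))
      stop(sprintf("malformed edge on line %d of %s (expected 'u v w')",
                   idx[which(nt > 3L)[1]], path))
    m <- do.call(rbind, toks)
    w <- suppressWarnings(as.numeric(m[, 3]))
    if (anyNA(w))
      stop(sprintf("non-numeric weight on line %d of %s",
                   idx[which(is.na(w))[1]], path))
    if (any(w <= 0))
      stop(sprintf("non-positive weight on line %d of %s",
                   idx[which(w <= 0)[1]], path))
    edges <- data.frame(from = m[, 1], to = m[, 2], weight = w,
                        stringsAsFactors = FALSE)
    return(weighted_graph(edges))
  }
  g <- igraph::read_graph(path, format = format)
  if (!("weight" %in% igraph::edge_attr_names(g)))
    stop("weights required: ", path, " has no 'weight' edge attribute")
  as_weighted_graph(g)
}

#' Write a weighted network to a file
#'
#' @param g a weighted graph.
#' @param path output path.
#' @param format one of `"edgelist"`, `"gml"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_weighted_graph <- function(g, path, format = c("edgelist", "gml", "graphml")) {
  format <- match.arg(format)
  g <- as_weighted_graph(g, warn = FALSE)
  if (format == "edgelist") {
    el <- igraph::as_edgelist(g, names = TRUE)
    lines <- if (nrow(el)) {
      paste(el[, 1], el[, 2], format(igraph::E(g)$weight, trim = TRUE,
                                     scientific = FALSE))
    } else character(0)
    writeLines(lines, path)
  } else {
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# Elementary weighted measures
# ---------------------------------------------------------------------------

#' Weighted degree (strength) of nodes
#'
#' The strength of a node is the sum of the weights of its incident edges;
#' an isolated node has strength 0.
#'
#' @param g a weighted graph.
#' @param v node names (character); defaults to all nodes.
#' @return named numeric vector of strengths, in the order of `v`.
#' @export
weighted_degree <- function(g, v = igraph::V(g)$name) {
  v <- as.character(v)
  unknown <- setdiff(v, igraph::V(g)$name)
  if (length(unknown))
    stop("unknown node(s): ", paste(utils::head(unknown, 5), collapse = ", "))
  s <- igraph::strength(g, vids = v, weights = igraph::E(g)$weight)
  stats::setNames(as.numeric(s), v)
}

#' Rank nodes by weighted degree
#'
#' Sorts a node set in decreasing order of weighted degree (strength).
#' Ties are broken lexicographically on the node name, so the ranking is a
#' deterministic function of the graph and the node set.
#'
#' @param g a weighted graph.
#' @param nodes node names to rank; defaults to all nodes of `g`.
#' @return a `ranked_nodes` data frame with columns `node` and
#'   `weighted_degree`, rows in rank order.
#' @export
rank_nodes <- function(g, nodes = igraph::V(g)$name) {
  nodes <- as.character(nodes)
  if (length(nodes) == 0L) {
    out <- data.frame(node = character(0), weighted_degree = numeric(0),
                      stringsAsFactors = FALSE)
    class(out) <- c("ranked_nodes", "data.frame")
    return(out)
  }
  wd <- weighted_degree(g, nodes)
  # descending strength; lexicographic (C-locale) tie-break on node name
  ord <- order(-wd, node_sort_key(nodes))
  out <- data.frame(node = nodes[ord], weighted_degree = as.numeric(wd[ord]),
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("ranked_nodes", "data.frame")
  out
}

# Locale-independent sort key for node identifiers: ranking must not depend
# on the session collation.
node_sort_key <- function(x) {
  xtfrm(factor(x, levels = sort(unique(x), method = "radix")))
}
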