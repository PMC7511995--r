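# Speaker-Listener Label Propagation (SLPA) for overlapping community
# detection, plus the community-cover container it produces.

#' Overlapping community cover
#'
#' A cover assigns every node of a graph to one or more community labels.
#' Nodes with two or more labels are the *overlapping nodes*.
#'
#' @param membership named list: node name -> character vector of labels.
#' @param params optional list of detector parameters (kept as provenance).
#' @return an object of class `community_cover`.
#' @export
community_cover <- function(membership, params = list()) {
  stopifnot(is.list(membership), !is.null(names(membership)))
  if (any(lengths(membership) < 1L))
    stop("every node must carry at least one community label")
  membership <- lapply(membership, function(x) sort(unique(as.character(x)),
                                                    method = "radix"))
  structure(list(membership = membership, params = params),
            class = "community_cover")
}

#' @export
print.community_cover <- function(x, ...) {
  n_comm <- length(unique(unlist(x$membership)))
  cat(sprintf("community cover: %d nodes, %d communities, %d overlapping\n",
              length(x$membership), n_comm, length(overlapping_nodes(x))))
  invisible(x)
}

#' Overlapping nodes of a cover
#'
#' @param cover a [community_cover()].
#' @return character vector of node names with >= 2 community labels
#'   (possibly empty), sorted.
#' @export
overlapping_nodes <- function(cover) {
  stopifnot(inherits(cover, "community_cover"))
  sort(names(cover$membership)[lengths(cover$membership) >= 2L],
       method = "radix")
}

#' Detect overlapping communities with SLPA
#'
#' Speaker-Listener Label Propagation. Each node starts with its own label in
#' memory. For `T` iterations, nodes are visited in a (seeded) random order;
#' the visited listener receives one label from each neighbour — the speaker
#' samples a label from its memory proportionally to the label's frequency —
#' and appends the most frequent received label to its own memory (ties are
#' broken uniformly at random from the seeded stream; the retention phase
#' breaks its ties by the lexicographically smallest label). After the iterations,
#' each node keeps every label occurring in at least a fraction `r` of its
#' memory; if no label reaches `r`, the single most frequent label is kept.
#'
#' The classic algorithm ignores edge weights when propagating labels; set
#' `weighted = TRUE` to make the listener weight incoming labels by the
#' corresponding edge weight.
#'
#' @param g a weighted graph (igraph).
#' @param T number of propagation iterations (>= 1). Default 100.
#' @param r retention threshold in (0, 1]; larger values keep fewer labels
#'   per node and hence fewer overlapping nodes. Default 0.3.
#' @param seed integer seed making the run reproducible; `NULL` uses the
#'   session RNG stream.
#' @param weighted weight incoming labels by edge weight? Default `FALSE`.
#' @param drop_nested apply the standard post-processing that removes a
#'   community whose node set is contained in another's? Default `TRUE`;
#'   set to `FALSE` to study the raw retention output.
#' @return a [community_cover()] with `params = list(T, r, seed)`.
#' @export
slpa <- function(g, T = 100L, r = 0.3, seed = NULL, weighted = FALSE,
                 drop_nested = TRUE) {
  g <- as_weighted_graph(g, warn = FALSE)
  T <- as.integer(T)
  if (is.na(T) || T < 1L) stop("T must be an integer >= 1")
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r > 1)
    stop("r must lie in (0, 1]")
  nodes <- igraph::V(g)$name
  n <- length(nodes)

  mem <- with_seed(seed, slpa_memories(g, T, weighted))

  membership <- vector("list", n)
  names(membership) <- nodes
  for (i in seq_len(n)) {
    m <- mem[[i]]
    counts <- label_counts(m)
    keep <- names(counts)[counts / length(m) >= r]
    if (length(keep) == 0L) keep <- top_label(counts)
    membership[[i]] <- keep
  }
  if (drop_nested) membership <- drop_nested_communities(membership)
  community_cover(membership,
                  params = list(T = T, r = r, seed = seed, weighted = weighted))
}

# Standard SLPA post-processing: a community whose node set is contained in
# another community's node set is removed (its label is dropped from every
# node, all of which also carry the enclosing label). Processed smallest
# first; exact duplicates keep the lexicographically smallest label.
drop_nested_communities <- function(membership) {
  labels <- unique(unlist(membership))
  comm <- lapply(labels, function(l)
    names(membership)[vapply(membership, function(x) l %in% x, logical(1))])
  names(comm) <- labels
  ord <- order(-lengths(comm), node_sort_key(labels))
  keep <- character(0)
  for (l in labels[ord]) {
    nested <- any(vapply(keep, function(k)
      all(comm[[l]] %in% comm[[k]]), logical(1)))
    if (!nested) keep <- c(keep, l)
  }
  lapply(membership, function(x) {
    out <- intersect(x, keep)
    if (length(out) == 0L) out <- x[1L]   # unreachable safeguard
    out
  })
}

# Run the propagation phase and return each node's label memory
# (character vector of length T + 1).
slpa_memories <- function(g, T, weighted) {
  nodes <- igraph::V(g)$name
  n <- length(nodes)
  adj <- igraph::as_adj_list(g, mode = "all")
  adj <- lapply(adj, as.integer)
  ew <- NULL
  if (weighted) {
    # align edge weights with the adjacency order
    ew <- vector("list", n)
    for (i in seq_len(n)) {
      es <- igraph::incident_edges(g, i, mode = "all")[[1]]
      ends <- igraph::ends(g, es, names = FALSE)
      other <- ifelse(ends[, 1] == i, ends[, 2], ends[, 1])
      ew[[i]] <- igraph::E(g)$weight[as.integer(es)][match(adj[[i]], other)]
    }
  }

  mem <- matrix(NA_character_, nrow = n, ncol = T + 1L)
  mem[, 1L] <- nodes
  memlen <- rep(1L, n)

  for (step in seq_len(T)) {
    for (i in sample.int(n)) {
      nbr <- adj[[i]]
      k <- length(nbr)
      if (k == 0L) {           # isolated listener keeps its own label
        memlen[i] <- memlen[i] + 1L
        mem[i, memlen[i]] <- mem[i, 1L]
        next
      }
      # each speaker emits one label, uniform over its memory
      # (= proportional to label frequency)
      ridx <- pmin(floor(stats::runif(k) * memlen[nbr]) + 1L, memlen[nbr])
      labs <- mem[cbind(nbr, ridx)]
      counts <- label_counts(labs, w = if (weighted) ew[[i]] else NULL)
      memlen[i] <- memlen[i] + 1L
      # ties among the most frequent received labels are broken uniformly
      # at random (from the seeded stream): a deterministic tie-break would
      # let one label cascade through the all-tied first iterations and
      # collapse the whole graph into a single community
      mx <- which(counts == max(counts))
      pick <- if (length(mx) == 1L) mx else mx[sample.int(length(mx), 1L)]
      mem[i, memlen[i]] <- names(counts)[pick]
    }
  }
  lapply(seq_len(n), function(i) mem[i, seq_len(memlen[i])])
}

# Counts (or weight sums) per label, names sorted lexicographically
# (radix, locale-independent).
label_counts <- function(labs, w = NULL) {
  if (is.null(w)) w <- rep(1, length(labs))
  out <- vapply(split(w, labs), sum, numeric(1))
  out[sort(names(out), method = "radix")]
}

# Most frequent label; ties -> lexicographically smallest (counts come in
# sorted name order, so the first maximum wins).
top_label <- function(counts) {
  names(counts)[which.max(counts)]
}

# Evaluate `code` under a temporary RNG state seeded with `seed`; the
# session RNG stream is left untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Read a community cover from a file
#'
#' One line per node: `node_id label1,label2,...`.
#'
#' @param path path to the cover file.
#' @return a [community_cover()].
#' @export
read_cover <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  toks <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(toks) != 2L))
    stop("malformed cover file: expected 'node_id label1,label2,...' per line")
  nodes <- vapply(toks, `[[`, character(1), 1L)
  labels <- strsplit(vapply(toks, `[[`, character(1), 2L), ",", fixed = TRUE)
  community_cover(stats::setNames(labels, nodes))
}

#' Write a community cover to a file
#'
#' @param cover a [community_cover()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cover <- function(cover, path) {
  stopifnot(inherits(cover, "community_cover"))
  lines <- vapply(names(cover$membership), function(v) {
    paste(v, paste(cover$membership[[v]], collapse = ","))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
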