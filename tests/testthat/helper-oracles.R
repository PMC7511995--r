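# Independent oracles and small fixture builders shared by the tests.
# Everything here is deliberately brute-force and avoids the code paths it
# is used to check.

# --- hand-written BFS connectivity over an active-edge list -----------------

# Are nodes u and v connected using only the edges flagged active?
bfs_connected <- function(n, from, to, active, u, v) {
  adj <- vector("list", n)
  for (e in which(active)) {
    adj[[from[e]]] <- c(adj[[from[e]]], to[e])
    adj[[to[e]]] <- c(adj[[to[e]]], from[e])
  }
  seen <- logical(n)
  queue <- u
  seen[u] <- TRUE
  while (length(queue)) {
    x <- queue[1]; queue <- queue[-1]
    if (x == v) return(TRUE)
    for (y in adj[[x]]) if (!seen[y]) {
      seen[y] <- TRUE
      queue <- c(queue, y)
    }
  }
  FALSE
}

# Literal pruning procedure: visit edges in ascending weight order
# (lexicographic endpoint tie-break), delete an edge iff its endpoints stay
# connected without it (fresh BFS each time). Returns canonical "u|v" keys
# of surviving edges.
oracle_prune_bfs <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0) return(character(0))
  w <- igraph::E(g)$weight
  nm <- igraph::V(g)$name
  from <- match(el[, 1], nm)
  to <- match(el[, 2], nm)
  a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
  ord <- order(w, match(a, sort(unique(a), method = "radix")),
               match(b, sort(unique(b), method = "radix")))
  active <- rep(TRUE, nrow(el))
  for (e in ord) {
    active[e] <- FALSE
    if (!bfs_connected(length(nm), from, to, active, from[e], to[e]))
      active[e] <- TRUE   # bridge: keep
  }
  paste(a[active], b[active], sep = "|")
}

edge_keys <- function(g) {
  el <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(el) == 0) return(character(0))
  paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|")
}

# --- direct summation of the rank-biased overlap definition -----------------

oracle_rbo <- function(X, Y, p, normalize = TRUE) {
  D <- min(length(X), length(Y))
  r <- 0
  for (d in seq_len(D)) {
    A_d <- length(intersect(X[seq_len(d)], Y[seq_len(d)])) / d
    r <- r + (1 - p) * p^(d - 1) * A_d
  }
  if (normalize) r <- r / (1 - p^D)
  r
}

# --- all-pairs enumeration of Kendall tau-a ---------------------------------

oracle_kendall <- function(x, y) {
  n <- length(x)
  nc <- 0L; nd <- 0L
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sx <- x[i] - x[j]; sy <- y[i] - y[j]
    if (sx * sy > 0) nc <- nc + 1L
    if (sx * sy < 0) nd <- nd + 1L
  }
  (nc - nd) / (n * (n - 1) / 2)
}

# --- numeric quadrature of the disparity-filter null integral ---------------

oracle_disparity_alpha <- function(p, k) {
  if (k < 2) return(1)
  1 - stats::integrate(function(x) (k - 1) * (1 - x)^(k - 2),
                       lower = 0, upper = p,
                       rel.tol = 1e-12, abs.tol = 1e-14)$value
}

# --- brute-force unweighted betweenness (Brandes accumulation) --------------

oracle_betweenness <- function(g, normalized = TRUE) {
  n <- igraph::vcount(g)
  adj <- lapply(igraph::as_adj_list(g, mode = "all"), as.integer)
  cb <- numeric(n)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n); dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(0)
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      order_visited <- c(order_visited, v)
      for (u in adj[[v]]) {
        if (dist[u] < 0) {
          dist[u] <- dist[v] + 1L
          queue <- c(queue, u)
        }
        if (dist[u] == dist[v] + 1L) {
          sigma[u] <- sigma[u] + sigma[v]
          preds[[u]] <- c(preds[[u]], v)
        }
      }
    }
    delta <- numeric(n)
    for (v in rev(order_visited)) {
      for (u in preds[[v]])
        delta[u] <- delta[u] + sigma[u] / sigma[v] * (1 + delta[v])
      if (v != s) cb[v] <- cb[v] + delta[v]
    }
  }
  cb <- cb / 2   # undirected: each pair counted twice
  if (normalized && n > 2) cb <- cb / ((n - 1) * (n - 2) / 2)
  stats::setNames(cb, igraph::V(g)$name)
}

# --- fixture builders -------------------------------------------------------

# random connected-ish weighted graph with integer weights (many ties)
random_weighted_graph <- function(n, p = 0.3, wmax = 5) {
  g <- igraph::sample_gnp(n, p)
  for (a in igraph::graph_attr_names(g))   # keep GML output clean
    g <- igraph::delete_graph_attr(g, a)
  igraph::V(g)$name <- sprintf("v%02d", seq_len(n))
  if (igraph::ecount(g) > 0)
    igraph::E(g)$weight <- sample(seq_len(wmax), igraph::ecount(g),
                                  replace = TRUE)
  g
}

# two k-cliques sharing exactly one bridge node
two_cliques_bridge <- function(k = 5) {
  cl1 <- c(paste0("a", seq_len(k - 1)), "bridge")
  cl2 <- c(paste0("b", seq_len(k - 1)), "bridge")
  edges <- do.call(rbind, lapply(list(cl1, cl2), function(cl) {
    pr <- t(utils::combn(cl, 2))
    data.frame(from = pr[, 1], to = pr[, 2], weight = 1,
               stringsAsFactors = FALSE)
  }))
  weighted_graph(unique(edges), warn = FALSE)
}

# c disjoint k-cliques
disjoint_cliques <- function(c_n = 3, k = 5) {
  edges <- do.call(rbind, lapply(seq_len(c_n), function(ci) {
    cl <- paste0("c", ci, "_", seq_len(k))
    pr <- t(utils::combn(cl, 2))
    data.frame(from = pr[, 1], to = pr[, 2], weight = 1,
               stringsAsFactors = FALSE)
  }))
  weighted_graph(edges, warn = FALSE)
}

write_tmp_edgelist <- function(lines) {
  path <- withr::local_tempfile(fileext = ".edgelist",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}
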