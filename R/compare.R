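# Pairwise backbone comparison and the multi-run comparison report.

#' Similarity measures between two backbones
#'
#' Computes, against the original graph `g`:
#' * `A_n` — common-node proportion between the top-`n` ranked nodes of the
#'   two backbones, with `n = floor(s * N)` when `s` is given (the designed
#'   common size) and otherwise the smaller backbone size;
#' * `rbo_p...` — rank-biased overlap of the two strength-ranked node lists
#'   at each value of `p`;
#' * `pearson` — Pearson correlation of the two descending weighted-degree
#'   sequences (truncated to the common length);
#' * `kendall` — Kendall tau-a of the corresponding dense rank sequences.
#'
#' Node rankings always use the weighted degree measured in the original
#' graph, so the measures compare which nodes the backbones selected, not
#' how pruning rewired them.
#'
#' @param g the original weighted graph.
#' @param bx,by `backbone` objects (or character vectors of node names).
#' @param s optional size threshold defining the comparison depth `n`.
#' @param p numeric vector of rank-biased-overlap decay parameters.
#' @return named numeric vector of similarity measures.
#' @export
backbone_similarity <- function(g, bx, by, s = NULL,
                                p = c(0.5, 0.7, 0.8, 0.9, 0.98)) {
  nx <- if (inherits(bx, "backbone")) backbone_nodes(bx) else as.character(bx)
  ny <- if (inherits(by, "backbone")) backbone_nodes(by) else as.character(by)
  rx <- rank_nodes(g, nx)
  ry <- rank_nodes(g, ny)
  n <- if (!is.null(s)) max(1L, floor(s * igraph::vcount(g)))
       else min(nrow(rx), nrow(ry))
  n <- min(n, nrow(rx), nrow(ry))
  top_x <- utils::head(rx$node, n)
  top_y <- utils::head(ry$node, n)
  a_n <- common_node_proportion(top_x, top_y)
  rbo <- vapply(p, function(pp) rank_biased_overlap(rx, ry, pp), numeric(1))
  names(rbo) <- paste0("rbo_p", p)
  d <- min(nrow(rx), nrow(ry))
  # degenerate constant-degree sequences have no defined correlation;
  # report NA rather than aborting a multi-run comparison
  rho <- tryCatch(pearson_correlation(rx$weighted_degree[seq_len(d)],
                                      ry$weighted_degree[seq_len(d)]),
                  error = function(e) NA_real_)
  tau <- if (d >= 2) kendall_tau(rx[seq_len(d), ], ry[seq_len(d), ])
         else NA_real_
  c(A_n = a_n, rbo, pearson = rho, kendall = tau)
}

#' Compare backbone extraction methods over repeated detector runs
#'
#' Runs the full pipeline `n_runs` times: detect an SLPA cover (one seed per
#' run), extract a backbone per method, and compute all pairwise similarity
#' measures plus the per-method effectiveness statistics. Means and standard
#' deviations across runs are reported. An externally supplied `cover`
#' bypasses detection (and makes every run identical for the deterministic
#' methods).
#'
#' Runs in which the detector finds no overlapping node are skipped with a
#' warning (the community-aware methods are undefined there); the report
#' records how many runs contributed.
#'
#' @param g a weighted graph.
#' @param methods subset of `c("ego", "hubs", "disparity")`.
#' @param s size threshold; default 0.3.
#' @param seeds integer vector of detector seeds, one per run.
#' @param T,r SLPA parameters (see [slpa()]).
#' @param p rank-biased-overlap decay parameters.
#' @param cover optional fixed [community_cover()].
#' @param t_fraction top-rank fraction for `A_t`; default 0.1.
#' @param min_runs if set, seeds are consumed (in order) until this many
#'   usable runs — runs whose cover has overlapping nodes — have completed;
#'   remaining seeds are ignored. Mirrors protocols that average a fixed
#'   number of detector runs.
#' @return a `comparison_report`: list with data frames `similarity`
#'   (pair x measure, mean and sd), `effectiveness` and `top_overlap`
#'   (method x measure), plus `n_runs` (contributing runs).
#' @export
compare_backbones <- function(g, methods = c("ego", "hubs", "disparity"),
                              s = 0.3, seeds = 1:10, T = 100L, r = 0.3,
                              p = c(0.5, 0.7, 0.8, 0.9, 0.98),
                              cover = NULL, t_fraction = 0.1,
                              min_runs = NULL) {
  g <- as_weighted_graph(g, warn = FALSE)
  methods <- match.arg(methods, several.ok = TRUE)
  if (length(methods) < 1L) stop("need at least one method")
  sims <- list(); effs <- list(); tops <- list()
  n_used <- 0L
  for (sd_i in seeds) {
    if (!is.null(min_runs) && n_used >= min_runs) break
    cov_i <- if (is.null(cover)) slpa(g, T = T, r = r, seed = sd_i) else cover
    if (any(methods %in% c("ego", "hubs")) &&
        length(overlapping_nodes(cov_i)) == 0L) {
      warning(sprintf("seed %s: no overlapping nodes; run skipped", sd_i))
      next
    }
    bbs <- lapply(methods, function(m)
      extract_backbone(g, cover = cov_i, method = m, s = s, seed = sd_i))
    names(bbs) <- methods
    n_used <- n_used + 1L
    if (length(methods) >= 2L) {
      prs <- utils::combn(methods, 2, simplify = FALSE)
      for (pr in prs) {
        key <- paste(pr, collapse = "-")
        sims[[key]] <- rbind(sims[[key]],
          backbone_similarity(g, bbs[[pr[1]]], bbs[[pr[2]]], s = s, p = p))
      }
    }
    for (m in methods) {
      effs[[m]] <- rbind(effs[[m]], effectiveness(bbs[[m]]))
      tops[[m]] <- rbind(tops[[m]],
        c(A_t = top_t_overlap(g, backbone_nodes(bbs[[m]]), t_fraction)))
    }
  }
  if (n_used == 0L) stop("no usable runs: no seed produced overlapping nodes")
  summarize <- function(lst, id_col) {
    do.call(rbind, lapply(names(lst), function(key) {
      m <- lst[[key]]
      data.frame(key = key, measure = colnames(m),
                 mean = apply(m, 2, mean), sd = apply(m, 2, stats::sd),
                 row.names = NULL, stringsAsFactors = FALSE,
                 check.names = FALSE) |>
        stats::setNames(c(id_col, "measure", "mean", "sd"))
    }))
  }
  structure(list(similarity = summarize(sims, "pair"),
                 effectiveness = summarize(effs, "method"),
                 top_overlap = summarize(tops, "method"),
                 n_runs = n_used, s = s),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat(sprintf("backbone comparison over %d run(s), s = %g\n", x$n_runs, x$s))
  if (!is.null(x$similarity)) {
    cat("\nsimilarity (mean +/- sd):\n")
    print(format_report_df(x$similarity), row.names = FALSE)
  }
  cat("\neffectiveness (mean +/- sd):\n")
  print(format_report_df(x$effectiveness), row.names = FALSE)
  cat("\ntop-rank overlap A_t (mean +/- sd):\n")
  print(format_report_df(x$top_overlap), row.names = FALSE)
  invisible(x)
}

format_report_df <- function(df) {
  df$mean <- round(df$mean, 4)
  df$sd <- round(df$sd, 4)
  df
}

#' Flatten a comparison report to a single data frame
#'
#' @param report a `comparison_report`.
#' @return data frame with columns `section`, `key`, `measure`, `mean`,
#'   `sd` — convenient for CSV export.
#' @export
report_as_data_frame <- function(report) {
  stopifnot(inherits(report, "comparison_report"))
  parts <- list(similarity = report$similarity,
                effectiveness = report$effectiveness,
                top_overlap = report$top_overlap)
  do.call(rbind, lapply(names(parts), function(nm) {
    df <- parts[[nm]]
    if (is.null(df)) return(NULL)
    names(df)[1] <- "key"
    cbind(section = nm, df, stringsAsFactors = FALSE)
  }))
}
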