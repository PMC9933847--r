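#' Score-weighted harmonic centrality toward the seed set
#'
#' Assigns every edge the cost `w_ij = 2 / (s~_i + s~_j)`, where the
#' normalized score `s~_i` is `s_i / maxS` for seeds and
#' `penalization * minS / maxS` for non-seeds: paths that traverse
#' high-score seed genes are cheap, so nodes reachable through many seeds
#' score high. The measure is `NS_i = sum_{j != i} 1 / d_ij` with `d_ij`
#' the exact weighted shortest-path length (Dijkstra).
#'
#' @param net a connected `pu_network`.
#' @param seeds a `seed_set` on `net`.
#' @param penalization factor in `(0, 1]` applied to the minimum
#'   normalized score for non-seed nodes (default 0.5).
#' @return named numeric vector `NS_i` in network node order.
#' @export
netshort <- function(net, seeds, penalization = 0.5) {
  if (!is.numeric(penalization) || penalization <= 0 || penalization > 1) {
    stop("penalization must lie in (0, 1]")
  }
  s_norm <- setNames(
    rep(penalization * seeds$min_score / seeds$max_score, length(net$nodes)),
    net$nodes
  )
  s_norm[seeds$genes] <- seeds$scores / seeds$max_score
  el <- igraph::as_edgelist(net$graph)
  w <- 2 / (s_norm[el[, 1]] + s_norm[el[, 2]])
  d <- igraph::distances(net$graph, weights = w, algorithm = "dijkstra")
  d <- d[net$nodes, net$nodes]
  diag(d) <- Inf
  rowSums(1 / d)
}

#' Ring decomposition of a network around its seed set
#'
#' Partitions the nodes by their minimal unweighted shortest-path distance
#' to any seed (multi-source BFS levels): ring 0 is the seed set itself,
#' ring `l` the non-seeds at distance `l`.
#'
#' @param net a connected `pu_network`.
#' @param seeds a `seed_set` on `net`.
#' @return object of class `ring_partition`: list with `level` (named
#'   integer vector), `rings` (list of node sets indexed `"0"`, `"1"`, ...)
#'   and `max_level`.
#' @export
ring_partition <- function(net, seeds) {
  d <- igraph::distances(
    net$graph, v = seeds$genes, weights = NA, algorithm = "unweighted"
  )
  lev <- apply(d, 2, min)[net$nodes]
  lev <- as.integer(lev)
  names(lev) <- net$nodes
  rings <- split(names(lev), lev)
  structure(
    list(level = lev, rings = rings, max_level = max(lev)),
    class = "ring_partition"
  )
}

#' @export
print.ring_partition <- function(x, ...) {
  cat(sprintf("<ring_partition> %d nodes in rings 0..%d\n",
              length(x$level), x$max_level))
  invisible(x)
}

#' Ring-based rank of nodes relative to the seed set
#'
#' Builds on [ring_partition()]. Every node gets an initial rank
#' `r^_i = 1 - s_i / maxS` (seeds) or 1 (non-seeds). A seed's final rank is
#' the convex combination `mixing * r^_i + (1 - mixing) * mean_{j in N(i)} r^_j`,
#' so seeds surrounded by seeds rank best (lowest). Non-seeds are processed
#' ring by ring: `r_i = l_i + (1/k_i) * (sum_{j in O_i} r^_j +
#' sum_{j in R_i(l_i - 1)} (r_j - (l_i - 1)))`, where `O_i` are neighbors
#' not in the lower ring and `R_i(l_i - 1)` those in it; subtracting
#' `l_i - 1` puts each lower-ring rank back on the `[0, 1]` scale of
#' `r^`. The integer part of a non-seed rank is therefore its ring level,
#' and the raw rank grows with distance from the disease module.
#'
#' @param net a connected `pu_network`.
#' @param seeds a `seed_set` on `net`.
#' @param rings a `ring_partition` computed from the same `net`/`seeds`
#'   (computed on the fly if `NULL`).
#' @param mixing weight in `[0, 1]` of a seed's own initial rank versus its
#'   neighborhood average (default 0.5).
#' @return named numeric vector of ranks in network node order.
#' @export
netring <- function(net, seeds, rings = NULL, mixing = 0.5) {
  if (!is.numeric(mixing) || mixing < 0 || mixing > 1) {
    stop("mixing must lie in [0, 1]")
  }
  if (is.null(rings)) rings <- ring_partition(net, seeds)
  lev <- rings$level[net$nodes]
  if (anyNA(lev)) stop("ring partition does not cover the network nodes")
  is_seed <- names(lev) %in% seeds$genes
  if (!setequal(names(lev)[lev == 0L], seeds$genes)) {
    stop("ring partition is inconsistent with the seed set (ring 0 != seeds)")
  }
  r_hat <- setNames(rep(1, length(lev)), names(lev))
  r_hat[seeds$genes] <- 1 - seeds$scores / seeds$max_score
  adj <- igraph::adjacent_vertices(net$graph, net$nodes)
  nb <- lapply(adj, function(v) v$name)
  names(nb) <- net$nodes
  r <- setNames(rep(NA_real_, length(lev)), names(lev))
  for (i in seeds$genes) {
    r[i] <- mixing * r_hat[i] + (1 - mixing) * mean(r_hat[nb[[i]]])
  }
  for (l in seq_len(rings$max_level)) {
    for (i in names(lev)[lev == l]) {
      nbr <- nb[[i]]
      lower <- nbr[lev[nbr] == (l - 1L)]
      other <- nbr[lev[nbr] != (l - 1L)]
      r[i] <- l + (sum(r_hat[other]) + sum(r[lower] - (l - 1))) / length(nbr)
    }
  }
  r
}
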