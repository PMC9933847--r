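# Fixtures are built in code; no binary data anywhere.

# path graph 1-2-3-4
path_net <- function() {
  as_pu_network(cbind(c("1", "2", "3"), c("2", "3", "4")))
}

# star: center "c", leaves "l1".."lk"
star_net <- function(k = 5) {
  leaves <- sprintf("l%d", seq_len(k))
  as_pu_network(cbind(rep("c", k), leaves))
}

# connected Erdos-Renyi graph with lexicographically stable names
random_net <- function(n, p = 0.15, seed = 1) {
  set.seed(seed)
  repeat {
    g <- igraph::sample_gnp(n, p)
    if (igraph::is_connected(g) && min(igraph::degree(g)) >= 1) break
  }
  el <- igraph::as_edgelist(g)
  width <- nchar(as.character(n))
  as_pu_network(cbind(sprintf("n%0*d", width, el[, 1]),
                      sprintf("n%0*d", width, el[, 2])))
}

random_seeds <- function(net, n_seeds, seed = 1) {
  set.seed(seed)
  genes <- sort(sample(net$nodes, n_seeds))
  seed_set(genes, 0.3 + 0.7 * runif(n_seeds), net)
}

# independent all-pairs shortest-path oracle (Floyd-Warshall on a dense
# weight matrix), deliberately not igraph
fw_distances <- function(net, edge_weight) {
  nodes <- net$nodes
  n <- length(nodes)
  d <- matrix(Inf, n, n, dimnames = list(nodes, nodes))
  diag(d) <- 0
  el <- igraph::as_edgelist(net$graph)
  w <- edge_weight(el[, 1], el[, 2])
  for (e in seq_len(nrow(el))) {
    d[el[e, 1], el[e, 2]] <- min(d[el[e, 1], el[e, 2]], w[e])
    d[el[e, 2], el[e, 1]] <- d[el[e, 1], el[e, 2]]
  }
  for (k in seq_len(n)) {
    dk <- outer(d[, k], d[k, ], `+`)
    d <- pmin(d, dk)
  }
  d
}

# dense matrix-exponential oracle (Matrix::expm), for n <= 50 only
dense_expm_vec <- function(M, v, t) {
  as.numeric(Matrix::expm(Matrix::Matrix(as.matrix(M) * t)) %*% v)
}

# perfectly separable 5-class feature fixture: one-hot columns + noise-free
separable_fixture <- function(per_class = 30) {
  labels <- rep(c("P", "LP", "WN", "LN", "RN"), each = per_class)
  n <- length(labels)
  X <- matrix(0, n, 5,
              dimnames = list(sprintf("s%03d", seq_len(n)),
                              paste0("f", 1:5)))
  X[cbind(seq_len(n), as.integer(factor(labels, levels = c("P", "LP", "WN", "LN", "RN"))))] <- 1
  list(
    X = structure(X, class = c("feature_matrix", "matrix", "array")),
    labels = setNames(factor(labels, levels = c("P", "LP", "WN", "LN", "RN")),
                      rownames(X))
  )
}
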