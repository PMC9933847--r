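test_that("netshort on the all-seed unit-score path equals harmonic centrality", {
  net <- path_net()
  s <- seed_set(c("1", "2", "3", "4"), rep(1, 4), net)
  ns <- netshort(net, s)
  # every edge has weight 1: NS_1 = 1 + 1/2 + 1/3
  expect_equal(unname(ns["1"]), 11 / 6, tolerance = 1e-12)
  expect_equal(unname(ns["2"]), 1 + 1 + 1 / 2, tolerance = 1e-12)
})

test_that("with uniform scores netshort is proportional to harmonic centrality", {
  for (rs in 1:4) {
    net <- random_net(20, seed = 400 + rs)
    genes <- net$nodes
    s <- seed_set(genes, rep(0.6, 20), net)  # all seeds, equal scores
    ns <- netshort(net, s, penalization = 1)
    # s~ == 1 everywhere -> every edge costs 1; oracle: Floyd-Warshall
    d <- fw_distances(net, function(a, b) rep(1, length(a)))
    diag(d) <- Inf
    expect_equal(ns, rowSums(1 / d), tolerance = 1e-12)
  }
})

test_that("netshort matches the brute-force oracle with heterogeneous scores", {
  net <- random_net(15, seed = 17)
  s <- random_seeds(net, 5, seed = 6)
  pen <- 0.5
  s_norm <- setNames(rep(pen * s$min_score / s$max_score, 15), net$nodes)
  s_norm[s$genes] <- s$scores / s$max_score
  d <- fw_distances(net, function(a, b) 2 / (s_norm[a] + s_norm[b]))
  diag(d) <- Inf
  expect_equal(netshort(net, s, penalization = pen), rowSums(1 / d),
               tolerance = 1e-12)
})

test_that("a star center outranks its leaves and zero penalization errors", {
  net <- star_net(6)
  s <- seed_set(net$nodes, rep(0.5, 7), net)
  ns <- netshort(net, s)
  expect_true(ns["c"] > max(ns[setdiff(net$nodes, "c")]))
  expect_error(netshort(net, s, penalization = 0), "penalization")
})

test_that("ring partition reproduces BFS levels and its invariants", {
  net <- path_net()
  s <- seed_set("1", 1, net)
  rp <- ring_partition(net, s)
  expect_equal(unname(rp$level[c("1", "2", "3", "4")]), 0:3)
  expect_identical(rp$rings[["0"]], "1")
  expect_equal(rp$max_level, 3L)

  # degenerate full-seed case
  s_all <- seed_set(net$nodes, rep(1, 4), net)
  rp_all <- ring_partition(net, s_all)
  expect_equal(rp_all$max_level, 0L)
  expect_setequal(rp_all$rings[["0"]], net$nodes)
})

test_that("ring levels equal the elementwise minimum of per-seed BFS maps", {
  net <- random_net(30, seed = 88)
  s <- random_seeds(net, 3, seed = 9)
  rp <- ring_partition(net, s)
  per_seed <- sapply(s$genes, function(g) {
    igraph::distances(net$graph, v = g, weights = NA)[1, net$nodes]
  })
  expect_equal(unname(rp$level), unname(apply(per_seed, 1, min)))
  # partition invariants
  expect_equal(sort(unlist(rp$rings, use.names = FALSE)), net$nodes)
  el <- igraph::as_edgelist(net$graph)
  expect_true(all(abs(rp$level[el[, 1]] - rp$level[el[, 2]]) <= 1))
})

test_that("netring reproduces the hand-worked path recursion", {
  net <- path_net()
  s <- seed_set("1", 1, net)
  r <- netring(net, s, mixing = 0.5)
  expect_equal(unname(r[c("1", "2", "3", "4")]),
               c(0.5, 1.75, 2.875, 3.875), tolerance = 1e-12)
})

test_that("netring ranks respect the per-ring bounds and neighbor partition", {
  for (rs in 1:10) {
    net <- random_net(25, p = 0.15, seed = 500 + rs)
    s <- random_seeds(net, 4, seed = rs)
    rp <- ring_partition(net, s)
    r <- netring(net, s, rings = rp)
    lev <- rp$level[names(r)]
    seeds <- names(r) %in% s$genes
    expect_true(all(r[seeds] >= 0 & r[seeds] <= 1))
    expect_true(all(r[!seeds] >= lev[!seeds] & r[!seeds] <= lev[!seeds] + 1))
    # neighbors of a ring-l node lie only in rings l-1, l, l+1
    for (i in names(r)[!seeds]) {
      nbr <- igraph::neighbors(net$graph, i)$name
      expect_equal(sum(lev[nbr] == lev[i] - 1L) + sum(lev[nbr] != lev[i] - 1L),
                   unname(network_degrees(net)[i]))
    }
  }
})

test_that("feature assembly normalizes every column to [0,1] in node order", {
  net <- path_net()
  s <- seed_set("1", 1, net)
  X <- assemble_features(net, s)
  expect_identical(dim(X), c(4L, 4L))
  expect_identical(rownames(X), net$nodes)
  expect_identical(colnames(X), c("heat", "balanced", "netshort", "netring"))
  expect_true(all(X >= 0 & X <= 1))
  expect_equal(unname(apply(X, 2, min)), rep(0, 4))
  expect_equal(unname(apply(X, 2, max)), rep(1, 4))
  # inverted ring rank: the seed end of the path must score highest
  expect_equal(unname(X["1", "netring"]), 1)

  expect_equal(netpu:::minmax_scale(c(2, 4, 6), "x"), c(0, 0.5, 1))
  expect_warning(z <- netpu:::minmax_scale(c(5, 5, 5), "x"), "constant")
  expect_equal(z, c(0, 0, 0))
})

test_that("netring orientation flag controls the flip", {
  net <- path_net()
  s <- seed_set("1", 1, net)
  X_flip <- assemble_features(net, s, invert_netring = TRUE)
  X_raw <- assemble_features(net, s, invert_netring = FALSE)
  expect_equal(unname(X_flip[, "netring"]), unname(1 - X_raw[, "netring"]))
})
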