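three_node_features <- function() {
  X <- rbind(a = c(0, 0), b = c(1, 1), c = c(0, 1))
  colnames(X) <- c("f1", "f2")
  X
}

test_that("similarity matrix reproduces the hand-worked three-node case", {
  W <- similarity_matrix(three_node_features())
  # e_ab = 2, e_ac = 1, e_bc = 1 -> m = 1, M = 2
  expect_equal(W["a", "b"], 0)
  expect_equal(W["a", "c"], 1)
  expect_equal(W["b", "c"], 1)
  expect_equal(unname(diag(W)), rep(1, 3))
  expect_equal(W, t(W))
  expect_true(all(W >= 0 & W <= 1))
})

test_that("identical feature rows get similarity 1; n = 2 degenerates to 1", {
  X <- rbind(a = c(0.2, 0.4), b = c(0.2, 0.4), c = c(0.9, 0.1))
  W <- similarity_matrix(X)
  expect_equal(W["a", "b"], 1)

  X2 <- rbind(a = c(0, 0), b = c(1, 0))
  expect_warning(W2 <- similarity_matrix(X2), "equal")
  expect_equal(W2["a", "b"], 1)
})

test_that("quantile reduction keeps the diagonal and renormalizes rows", {
  W <- similarity_matrix(three_node_features())
  tr <- reduce_and_normalize(W, q_w = 0.5)
  # off-diagonal {0, 1, 1}: ECDF-interpolated median 0.5; w_ab dropped
  expect_equal(tr$threshold, 0.5)
  expect_equal(as.numeric(tr$Wn["a", ]), c(0.5, 0, 0.5))
  expect_equal(unname(Matrix::rowSums(tr$Wn)), rep(1, 3), tolerance = 1e-12)

  # q_w = 0 keeps everything
  tr0 <- reduce_and_normalize(W, q_w = 0)
  expect_equal(as.matrix(tr0$Wn) * rowSums(W), unclass(W), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(reduce_and_normalize(W, q_w = 1), "q_w")
})

test_that("row-stochasticity holds for arbitrary feature inputs", {
  set.seed(31)
  X <- matrix(runif(40 * 4), 40, 4,
              dimnames = list(sprintf("n%02d", 1:40), paste0("f", 1:4)))
  for (q in c(0, 0.25, 0.75, 0.95)) {
    tr <- reduce_and_normalize(similarity_matrix(X), q_w = q)
    expect_equal(unname(Matrix::rowSums(tr$Wn)), rep(1, 40), tolerance = 1e-12)
    expect_true(all(tr$Wn@x >= 0))
  }
})

test_that("reliable negatives are the features farthest from the positive centroid", {
  X <- matrix(c(0.9, 1.0, 0.1, 0.5, 0.9), ncol = 1,
              dimnames = list(c("a", "b", "c", "d", "e"), "f"))
  expect_identical(select_reliable_negatives(X, c("a", "b")), c("c", "d"))
  expect_identical(select_reliable_negatives(X, c("a", "b"), n_rn = 3),
                   c("c", "d", "e"))
  # permuting the row order does not change the selection
  perm <- c("d", "a", "e", "c", "b")
  expect_identical(
    select_reliable_negatives(X[perm, , drop = FALSE], c("a", "b")),
    c("c", "d")
  )
  expect_error(select_reliable_negatives(X, c("a", "b"), n_rn = 0), "positive")
  expect_error(select_reliable_negatives(X, c("a", "b"), n_rn = 4), "exceeds")
})

test_that("the initial state is balanced for equal and unequal class sizes", {
  nodes <- sprintf("n%02d", 1:10)
  g0 <- initial_state(nodes, nodes[1:3], nodes[4:6])
  expect_equal(unname(g0[1:6]), c(1, 1, 1, -1, -1, -1))
  expect_equal(sum(g0), 0)

  g0b <- initial_state(nodes, nodes[1:4], nodes[5:6])
  expect_equal(unname(g0b[5:6]), c(-2, -2))
  expect_equal(sum(g0b), 0)

  expect_error(initial_state(nodes, character(0), nodes[1]), "nonempty")
  expect_error(initial_state(nodes, nodes[1], nodes[1]), "overlap")
})

test_that("restart-only propagation returns the initial state", {
  Wn <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  g0 <- setNames(c(1, -1), c("a", "b"))
  prop <- propagate(Wn, g0, alpha = 1)
  expect_equal(prop$g, g0)
  expect_true(prop$converged)
})

test_that("the two-node fixed point is (2/3, -2/3)", {
  Wn <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  g0 <- setNames(c(1, -1), c("a", "b"))
  prop <- propagate(Wn, g0, alpha = 0.8, tol = 1e-12)
  expect_equal(unname(prop$g), c(2 / 3, -2 / 3), tolerance = 1e-9)
})

test_that("propagation matches the direct linear solve on random instances", {
  for (rs in 1:10) {
    set.seed(600 + rs)
    n <- 50
    M <- matrix(runif(n * n), n, n)
    Wn <- M / rowSums(M)
    dimnames(Wn) <- list(sprintf("n%02d", 1:n), sprintf("n%02d", 1:n))
    g0 <- setNames(numeric(n), rownames(Wn))
    g0[1:5] <- 1
    g0[6:10] <- -1
    prop <- propagate(Wn, g0, alpha = 0.8, tol = 1e-10)
    direct <- solve(diag(n) - 0.2 * t(Wn), 0.8 * g0)
    expect_lt(max(abs(prop$g - direct)), 1e-8)
    # geometric contraction of the residual
    ratios <- prop$residuals[-1] / head(prop$residuals, -1)
    expect_true(all(ratios[-(1:3)] <= 0.2 + 1e-6))
  }
})

test_that("non-convergence raises an error carrying the residual", {
  Wn <- matrix(c(0, 1, 1, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  g0 <- setNames(c(1, -1), c("a", "b"))
  expect_error(propagate(Wn, g0, alpha = 0.8, tol = 1e-12, max_iter = 3L),
               "did not converge.*residual")
})

test_that("ranking blocks follow the ceiling-then-remainder rule", {
  make_g <- function(u) {
    nodes <- c(sprintf("p%d", 1:2), sprintf("r%d", 1:2),
               sprintf("u%02d", seq_len(u)))
    g <- setNames(c(2, 2, -2, -2, rev(seq_len(u)) / u), nodes)
    list(g = g, P = c("p1", "p2"), RN = c("r1", "r2"))
  }
  sizes <- function(asg) as.integer(table(asg$labels)[c("LP", "WN", "LN")])

  f <- make_g(9)
  expect_equal(sizes(assign_labels(f$g, f$P, f$RN)), c(3L, 3L, 3L))
  f <- make_g(10)
  expect_equal(sizes(assign_labels(f$g, f$P, f$RN)), c(4L, 4L, 2L))
  expect_equal(sizes(assign_labels(f$g, f$P, f$RN,
                                   fractions = c(0.5, 0.3, 0.2))),
               c(5L, 3L, 2L))
  # the LP block is the top of the ranking
  asg <- assign_labels(f$g, f$P, f$RN)
  expect_identical(asg$ranking[1:4],
                   names(sort(f$g[asg$ranking], decreasing = TRUE))[1:4])
  expect_true(all(asg$labels[asg$ranking[1:4]] == "LP"))
})

test_that("labels partition the node set with P and RN unchanged", {
  set.seed(77)
  X <- matrix(runif(60 * 3), 60, 3,
              dimnames = list(sprintf("n%02d", 1:60), paste0("f", 1:3)))
  P <- sprintf("n%02d", 1:8)
  asg <- apu_label(X, positives = P)
  expect_identical(sort(names(asg$labels)[asg$labels == "P"]), sort(P))
  expect_equal(sum(asg$labels == "RN"), 8)
  tab <- table(asg$labels)
  expect_equal(sum(tab), 60)
  expect_equal(sum(tab[c("LP", "WN", "LN")]), 60 - 8 - 8)
  # empirical propagation bound on similarity-derived instances
  expect_true(all(abs(asg$g) <= 1 + 1e-9))
})

test_that("labeling is deterministic and monotone in the stationary values", {
  set.seed(78)
  X <- matrix(runif(40 * 4), 40, 4,
              dimnames = list(sprintf("n%02d", 1:40), paste0("f", 1:4)))
  P <- sprintf("n%02d", 1:5)
  a1 <- apu_label(X, positives = P)
  a2 <- apu_label(X, positives = P)
  expect_identical(a1$labels, a2$labels)
  expect_equal(a1$g, a2$g)
  # ranking consistency: g values are non-increasing along the ranking
  gr <- a1$g[a1$ranking]
  expect_true(all(diff(gr) <= 1e-12))
})
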