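test_that("metrics reproduce a hand-computed confusion fixture exactly", {
  # truth: 4 P, 3 LP, 3 WN, 2 LN, 2 RN
  truth <- c(rep("P", 4), rep("LP", 3), rep("WN", 3), rep("LN", 2), rep("RN", 2))
  pred <- c("P", "P", "P", "LP",      # P: 3 right, 1 -> LP
            "LP", "LP", "WN",         # LP: 2 right, 1 -> WN
            "WN", "WN", "WN",         # WN: all right
            "LN", "RN",               # LN: 1 right, 1 -> RN
            "RN", "LN")               # RN: 1 right, 1 -> LN
  rep <- eval_report(truth, pred)
  expect_equal(rep$confusion["P", "P"], 3)
  expect_equal(rep$confusion["P", "LP"], 1)
  expect_equal(unname(rowSums(rep$confusion)),
               as.numeric(table(factor(truth, levels = c("P", "LP", "WN", "LN", "RN")))))
  expect_equal(rep$accuracy, 10 / 14)
  pc <- rep$per_class
  expect_equal(pc$precision[pc$label == "P"], 1)          # 3/3
  expect_equal(pc$recall[pc$label == "P"], 3 / 4)
  expect_equal(pc$precision[pc$label == "LP"], 2 / 3)
  expect_equal(pc$recall[pc$label == "LP"], 2 / 3)
  expect_equal(pc$precision[pc$label == "WN"], 3 / 4)
  expect_equal(pc$recall[pc$label == "WN"], 1)
  expect_equal(pc$f1[pc$label == "WN"], 2 * (3 / 4) / (3 / 4 + 1))
  expect_equal(rep$macro_avg[["precision"]],
               mean(c(1, 2 / 3, 3 / 4, 1 / 2, 1 / 2)))
  w <- c(4, 3, 3, 2, 2) / 14
  expect_equal(rep$weighted_avg[["recall"]],
               sum(w * c(3 / 4, 2 / 3, 1, 1 / 2, 1 / 2)))
})

test_that("a separable fixture is classified perfectly by the random forest", {
  fx <- separable_fixture(30)
  rep <- train_eval(fx$X, fx$labels, model = "rf", seed = 5)
  expect_equal(rep$accuracy, 1)
  expect_equal(rep$per_class$f1, rep(1, 5))
})

test_that("train_eval is deterministic given the seed and stratifies the split", {
  fx <- separable_fixture(20)
  r1 <- train_eval(fx$X, fx$labels, model = "rf", seed = 9)
  r2 <- train_eval(fx$X, fx$labels, model = "rf", seed = 9)
  expect_identical(attr(r1, "test_idx"), attr(r2, "test_idx"))
  expect_equal(r1$confusion, r2$confusion)
  # stratified 30% of 20 per class = 6 per class in the test set
  expect_equal(unname(rowSums(r1$confusion)), rep(6, 5))
  # tiny class cannot be stratified
  bad <- fx$labels
  bad[bad == "RN"] <- "LN"
  bad[1] <- "RN"
  expect_error(train_eval(fx$X, bad, model = "rf", seed = 1), "< 2 members")
})

test_that("shuffled labels score near the chance baseline", {
  set.seed(123)
  n <- 150
  X <- matrix(runif(n * 4), n, 4,
              dimnames = list(sprintf("s%03d", 1:n), paste0("f", 1:4)))
  class(X) <- c("feature_matrix", class(X))
  accs <- vapply(1:20, function(i) {
    y <- setNames(factor(sample(rep(c("P", "LP", "WN", "LN", "RN"), each = 30)),
                         levels = c("P", "LP", "WN", "LN", "RN")), rownames(X))
    train_eval(X, y, model = "rf", seed = i)$accuracy
  }, numeric(1))
  # balanced 5-class chance accuracy is 0.2; mean of 20 runs (45 test points
  # each) stays well inside +-3 binomial sd of the baseline
  se3 <- 3 * sqrt(0.2 * 0.8 / (20 * 45))
  expect_lt(abs(mean(accs) - 0.2), 0.05 + se3)
})

test_that("svm and mlp run on the separable fixture", {
  fx <- separable_fixture(15)
  expect_gt(train_eval(fx$X, fx$labels, model = "svm", seed = 3)$accuracy, 0.9)
  expect_gt(train_eval(fx$X, fx$labels, model = "mlp", seed = 3)$accuracy, 0.9)
})

test_that("cross-validation folds partition the data and aggregate correctly", {
  fx <- separable_fixture(10)
  cv <- cross_validate(fx$X, fx$labels, model = "rf", k = 5, seed = 2)
  expect_length(cv$folds, 5)
  expect_equal(sum(vapply(cv$folds, function(r) r$n, numeric(1))), 50)
  # separable everywhere: every fold perfect, pooled sd zero
  accs <- vapply(cv$folds, function(r) r$accuracy, numeric(1))
  expect_equal(accs, rep(1, 5))
  expect_equal(cv$summary$mean[cv$summary$metric == "accuracy"], 1)
  expect_equal(cv$summary$sd[cv$summary$metric == "accuracy"], 0)
  # pooled mean/sd equals a brute-force recomputation over folds
  mf <- vapply(cv$folds, function(r) r$macro_avg[["f1"]], numeric(1))
  expect_equal(cv$summary$mean[cv$summary$metric == "macro_f1"], mean(mf))
  expect_equal(cv$summary$sd[cv$summary$metric == "macro_f1"], sd(mf))
})
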