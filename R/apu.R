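#' Feature-similarity matrix between genes
#'
#' From the squared Euclidean distances `e_ij = sum_k (x_ik - x_jk)^2`
#' between normalized feature vectors, builds the similarity
#' `w_ij = 1 - (e_ij - m) / (M - m)` for `i != j` (with `m`, `M` the
#' off-diagonal min and max of `e`) and `w_ii = 1`: the closest pair gets
#' similarity 1, the farthest 0. When every off-diagonal distance is equal
#' (`M = m`) all similarities are set to 1 with a warning, which keeps the
#' downstream propagation connected instead of failing.
#'
#' @param X a `feature_matrix` (rows = genes).
#' @return symmetric numeric matrix `W` with unit diagonal, entries in
#'   `[0, 1]`, dimnames from `X`.
#' @export
similarity_matrix <- function(X) {
  n <- nrow(X)
  stopifnot(n >= 2)
  e <- as.matrix(stats::dist(X))^2
  off <- e[upper.tri(e)]
  m <- min(off); M <- max(off)
  if (M == m) {
    warning("all pairwise feature distances are equal; similarities set to 1")
    W <- matrix(1, n, n)
  } else {
    W <- 1 - (e - m) / (M - m)
    diag(W) <- 1
  }
  dimnames(W) <- list(rownames(X), rownames(X))
  W
}

#' Quantile reduction and row normalization of the similarity matrix
#'
#' Zeroes every off-diagonal similarity at or below the empirical
#' `q_w`-quantile of the off-diagonal entries, excluding links between
#' poorly related genes from the propagation, then normalizes rows to the
#' row-stochastic transition matrix `W_n = D^{-1} W_r` with
#' `D_ii = sum_j w_r,ij`. The unit diagonal is always retained, so no row
#' can become empty.
#'
#' @param W similarity matrix from [similarity_matrix()].
#' @param q_w quantile in `[0, 1)` (default 0.75). The quantile is taken
#'   over off-diagonal entries only (including the `n` known unit diagonal
#'   entries would bias the threshold upward), with linear interpolation
#'   of the empirical CDF (`stats::quantile` type 4); `q_w = 0` disables
#'   the reduction entirely.
#' @return list of class `transition_matrix`: `Wn` (sparse row-stochastic),
#'   `q_w`, `threshold`, `kept_fraction` (off-diagonal entries surviving).
#' @export
reduce_and_normalize <- function(W, q_w = 0.75) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (!is.numeric(q_w) || q_w < 0 || q_w >= 1) stop("q_w must lie in [0, 1)")
  off <- W[upper.tri(W)]
  thr <- if (q_w == 0) {
    -Inf
  } else {
    as.numeric(quantile(off, q_w, names = FALSE, type = 4))
  }
  Wr <- W
  drop <- Wr <= thr
  diag(drop) <- FALSE
  Wr[drop] <- 0
  diag(Wr) <- 1
  d <- rowSums(Wr)
  stopifnot(all(d > 0))
  Wn <- Matrix::Matrix(Wr / d, sparse = TRUE)
  kept <- 1 - sum(drop) / (nrow(W) * (nrow(W) - 1))
  structure(
    list(Wn = Wn, q_w = q_w, threshold = thr, kept_fraction = kept),
    class = "transition_matrix"
  )
}

#' @export
print.transition_matrix <- function(x, ...) {
  cat(sprintf(
    "<transition_matrix> %d x %d, q_w=%.3g, kept %.1f%% of off-diagonal links\n",
    nrow(x$Wn), ncol(x$Wn), x$q_w, 100 * x$kept_fraction
  ))
  invisible(x)
}

#' Select reliable negatives farthest from the positive centroid
#'
#' Computes the mean feature vector of the positive genes and returns the
#' `n_rn` non-positive genes with the largest Euclidean distance from it.
#' The default `n_rn = |P|` keeps the positive and negative ends of the
#' propagation balanced. Ties are broken by gene identifier so the
#' selection is independent of input order.
#'
#' @param X a `feature_matrix`.
#' @param positives character vector of positive (seed) gene identifiers.
#' @param n_rn number of reliable negatives (default `length(positives)`).
#' @return character vector of selected genes, sorted lexicographically.
#' @export
select_reliable_negatives <- function(X, positives, n_rn = length(positives)) {
  stopifnot(length(positives) > 0, all(positives %in% rownames(X)))
  if (n_rn <= 0) stop("n_rn must be positive")
  cand <- setdiff(rownames(X), positives)
  if (n_rn > length(cand)) stop("n_rn exceeds the number of non-positive genes")
  centroid <- colMeans(X[positives, , drop = FALSE])
  d <- sqrt(colSums((t(X[cand, , drop = FALSE]) - centroid)^2))
  sort(cand[order(-d, cand)][seq_len(n_rn)])
}

#' Balanced initial state vector for the propagation
#'
#' Positives start at `+1`, reliable negatives at `-|P|/|RN|` (so the
#' vector sums to zero regardless of the class sizes), all other genes
#' at 0.
#'
#' @param nodes all gene identifiers (defines the vector order).
#' @param positives,negatives disjoint subsets of `nodes`.
#' @return named numeric vector `g_0` with `sum(g_0) == 0`.
#' @export
initial_state <- function(nodes, positives, negatives) {
  if (length(positives) == 0L || length(negatives) == 0L) {
    stop("both the positive and the reliable-negative set must be nonempty")
  }
  if (length(intersect(positives, negatives)) > 0L) {
    stop("positives and negatives overlap")
  }
  stopifnot(all(c(positives, negatives) %in% nodes))
  g0 <- setNames(numeric(length(nodes)), nodes)
  g0[positives] <- 1
  g0[negatives] <- -length(positives) / length(negatives)
  g0
}

#' Markov propagation with restart
#'
#' Iterates `g_r = (1 - alpha) * t(Wn) %*% g_{r-1} + alpha * g_0` from
#' `g_0` until the L2 norm of successive differences drops below `tol`.
#' The fixed point solves `(I - (1 - alpha) t(Wn)) g = alpha g_0`; the
#' restart term keeps the stationary state anchored to the initial
#' positive/negative labeling while the transition matrix spreads it
#' along the feature-similarity graph.
#'
#' @param trans a `transition_matrix` (or a row-stochastic matrix).
#' @param g0 initial state from [initial_state()].
#' @param alpha restart probability in `(0, 1]` (default 0.8).
#' @param tol L2 convergence tolerance (default 1e-6).
#' @param max_iter iteration cap; exceeding it is an error that reports
#'   the last residual rather than returning silently.
#' @return list of class `propagation_state`: `g` (named stationary
#'   vector), `iterations`, `residuals` (per-iteration L2 differences),
#'   `converged`.
#' @export
propagate <- function(trans, g0, alpha = 0.8, tol = 1e-6, max_iter = 10000L) {
  Wn <- if (inherits(trans, "transition_matrix")) trans$Wn else trans
  stopifnot(nrow(Wn) == length(g0))
  if (!is.numeric(alpha) || alpha <= 0 || alpha > 1) stop("alpha must lie in (0, 1]")
  Wt <- Matrix::t(Wn)
  g <- as.numeric(g0)
  residuals <- numeric(0)
  for (r in seq_len(max_iter)) {
    g_new <- (1 - alpha) * as.numeric(Wt %*% g) + alpha * as.numeric(g0)
    res <- sqrt(sum((g_new - g)^2))
    residuals[r] <- res
    g <- g_new
    if (res < tol) {
      return(structure(
        list(g = setNames(g, names(g0)), iterations = r,
             residuals = residuals, converged = TRUE),
        class = "propagation_state"
      ))
    }
  }
  stop(sprintf(
    "propagation did not converge in %d iterations (last residual %.3e)",
    max_iter, residuals[length(residuals)]
  ))
}

#' Assign the five classes from the stationary state
#'
#' Positives and reliable negatives keep their labels. The remaining
#' genes are ranked by stationary value, descending (ties broken by gene
#' identifier), and the ranking is cut into likely positive, weakly
#' negative and likely negative blocks of sizes `ceiling(f_LP * u)`,
#' `min(ceiling(f_WN * u), remaining)` and the remainder, where `u` is
#' the number of unlabeled genes — the ceiling-then-remainder rule makes
#' the equal-thirds default reproduce "divide into three equal parts"
#' whenever `u` is divisible by 3.
#'
#' @param g stationary state (a `propagation_state` or named vector).
#' @param positives,negatives the P and RN gene sets.
#' @param fractions length-3 positive vector `(f_LP, f_WN, f_LN)` summing
#'   to 1 (default equal thirds).
#' @return object of class `label_assignment`: `labels` (named factor
#'   with levels P, LP, WN, LN, RN), `g` (stationary values), `ranking`
#'   (unlabeled genes in rank order), `fractions`.
#' @export
assign_labels <- function(g, positives, negatives,
                          fractions = c(1, 1, 1) / 3) {
  if (inherits(g, "propagation_state")) g <- g$g
  stopifnot(!is.null(names(g)))
  if (length(fractions) != 3 || any(fractions <= 0) ||
      abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be three positive numbers summing to 1")
  }
  nodes <- names(g)
  unlabeled <- setdiff(nodes, c(positives, negatives))
  o <- order(-g[unlabeled], unlabeled)
  ranking <- unlabeled[o]
  u <- length(ranking)
  n_lp <- min(ceiling(fractions[1] * u), u)
  n_wn <- min(ceiling(fractions[2] * u), u - n_lp)
  labels <- setNames(rep("LN", length(nodes)), nodes)
  labels[positives] <- "P"
  labels[negatives] <- "RN"
  if (n_lp > 0) labels[ranking[seq_len(n_lp)]] <- "LP"
  if (n_wn > 0) labels[ranking[n_lp + seq_len(n_wn)]] <- "WN"
  labels <- factor(labels, levels = c("P", "LP", "WN", "LN", "RN"))
  names(labels) <- nodes
  structure(
    list(labels = labels, g = g, ranking = ranking, fractions = fractions),
    class = "label_assignment"
  )
}

#' @export
print.label_assignment <- function(x, ...) {
  cat("<label_assignment>\n")
  print(table(x$labels))
  invisible(x)
}

#' Run the full adaptive positive-unlabeled labeling
#'
#' Chains the five labeling steps: feature-similarity matrix, quantile
#' reduction + row normalization, reliable-negative selection, Markov
#' propagation with restart, and quantile-based class assignment.
#'
#' @param X a `feature_matrix`.
#' @param positives seed gene identifiers (class P).
#' @param q_w similarity reduction quantile (default 0.75).
#' @param alpha restart probability (default 0.8).
#' @param tol propagation convergence tolerance (default 1e-6).
#' @param max_iter propagation iteration cap.
#' @param n_rn number of reliable negatives (default `|P|`).
#' @param fractions LP/WN/LN ranking fractions (default equal thirds).
#' @return a `label_assignment` (see [assign_labels()]), with the
#'   propagation diagnostics attached as attribute `propagation`.
#' @export
apu_label <- function(X, positives, q_w = 0.75, alpha = 0.8, tol = 1e-6,
                      max_iter = 10000L, n_rn = length(positives),
                      fractions = c(1, 1, 1) / 3) {
  stopifnot(all(positives %in% rownames(X)))
  W <- similarity_matrix(X)
  trans <- reduce_and_normalize(W, q_w = q_w)
  rn <- select_reliable_negatives(X, positives, n_rn = n_rn)
  g0 <- initial_state(rownames(X), positives, rn)
  prop <- propagate(trans, g0, alpha = alpha, tol = tol, max_iter = max_iter)
  out <- assign_labels(prop, positives, rn, fractions = fractions)
  attr(out, "propagation") <- prop[c("iterations", "converged")]
  out
}

#' Write a label assignment as TSV
#'
#' Columns: `gene`, `label`, `g_inf`, `rank` (rank within the unlabeled
#' ranking; `NA` for P and RN genes).
#'
#' @param assignment a `label_assignment`.
#' @param path output file.
#' @param comment optional `#` comment line.
#' @return `path`, invisibly.
#' @export
write_labels <- function(assignment, path, comment = NULL) {
  nodes <- names(assignment$labels)
  rank <- setNames(rep(NA_integer_, length(nodes)), nodes)
  rank[assignment$ranking] <- seq_along(assignment$ranking)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("gene\tlabel\tg_inf\trank", con)
  writeLines(paste(
    nodes, as.character(assignment$labels),
    format_num(assignment$g[nodes]),
    ifelse(is.na(rank), "NA", rank),
    sep = "\t"
  ), con)
  invisible(path)
}
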