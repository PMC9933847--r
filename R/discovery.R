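# mode of association scores, rounded to 2 decimals, smallest on ties
score_mode <- function(x) {
  r <- round(x, 2)
  tab <- table(r)
  as.numeric(names(tab)[which.max(tab)])
}

#' Seed-masking rediscovery protocol
#'
#' Partitions the seed genes into `n_folds` non-overlapping masks of
#' `mask_fraction * |seeds|` genes each (seeds shuffled once under
#' `seed`, then cut into contiguous blocks). For every fold the masked
#' genes are treated as unlabeled in both the feature computation and the
#' labeling, the pipeline is re-run, and the class each masked gene lands
#' in is tallied together with the mean/median/mode of its original
#' association score — a direct measure of whether held-back disease
#' genes are rediscovered as likely positives.
#'
#' @param net a `pu_network`.
#' @param seeds the full `seed_set`.
#' @param mask_fraction fraction of seeds masked per fold (default 0.2);
#'   `mask_fraction * n_folds` must be at most 1.
#' @param n_folds number of non-overlapping folds (default 5).
#' @param config pipeline parameters, see [default_config()]; only the
#'   feature and labeling entries are used.
#' @param seed RNG seed for the single shuffle defining the masks.
#' @return object of class `rediscovery_report`: `per_fold` (data.frame
#'   fold/label/count/percent), `score_stats` (data.frame of per-fold
#'   score mean/median/mode per label), `summary` (per-label mean and sd
#'   over folds), `masked` (list of masked gene sets).
#' @export
mask_and_rediscover <- function(net, seeds, mask_fraction = 0.2,
                                n_folds = 5L, config = default_config(),
                                seed = 1L) {
  if (mask_fraction < 0 || mask_fraction * n_folds > 1 + 1e-12) {
    stop("mask_fraction * n_folds must lie in [0, 1]")
  }
  n_seeds <- length(seeds$genes)
  block <- floor(mask_fraction * n_seeds)
  empty <- data.frame(fold = integer(), label = character(),
                      count = integer(), percent = numeric())
  if (block == 0L) {
    return(structure(
      list(per_fold = empty, score_stats = empty[0, ], summary = empty[0, ],
           masked = list()),
      class = "rediscovery_report"
    ))
  }
  shuffled <- with_rng(seed, sample(seeds$genes))
  masks <- lapply(seq_len(n_folds), function(f) {
    sort(shuffled[(f - 1L) * block + seq_len(block)])
  })
  tallies <- list(); stats <- list()
  for (f in seq_len(n_folds)) {
    masked <- masks[[f]]
    visible <- setdiff(seeds$genes, masked)
    if (length(visible) < 2L) stop("masking leaves < 2 visible seeds")
    vis_seeds <- seed_set(visible, seeds$scores[visible], net)
    X <- assemble_features(
      net, vis_seeds,
      t_heat = config$t_heat, t_balanced = config$t_balanced,
      penalization = config$penalization, mixing = config$mixing
    )
    lab <- apu_label(
      X, positives = visible, q_w = config$q_w, alpha = config$alpha,
      tol = config$tol, n_rn = resolve_rn_size(config, length(visible)),
      fractions = config$fractions
    )
    got <- factor(as.character(lab$labels[masked]),
                  levels = c("LP", "WN", "LN", "RN"))
    cnt <- table(got)
    tallies[[f]] <- data.frame(
      fold = f, label = names(cnt), count = as.integer(cnt),
      percent = 100 * as.integer(cnt) / length(masked)
    )
    stats[[f]] <- do.call(rbind, lapply(names(cnt), function(lv) {
      sc <- seeds$scores[masked[got == lv]]
      data.frame(
        fold = f, label = lv, count = as.integer(cnt[[lv]]),
        score_mean = if (length(sc)) mean(sc) else NA_real_,
        score_median = if (length(sc)) median(sc) else NA_real_,
        score_mode = if (length(sc)) score_mode(sc) else NA_real_
      )
    }))
  }
  per_fold <- do.call(rbind, tallies)
  score_stats <- do.call(rbind, stats)
  summary <- do.call(rbind, lapply(c("LP", "WN", "LN", "RN"), function(lv) {
    p <- per_fold$percent[per_fold$label == lv]
    cnt <- per_fold$count[per_fold$label == lv]
    data.frame(
      label = lv,
      percent_mean = mean(p), percent_sd = sd(p),
      count_mean = mean(cnt), count_sd = sd(cnt)
    )
  }))
  structure(
    list(per_fold = per_fold, score_stats = score_stats, summary = summary,
         masked = masks),
    class = "rediscovery_report"
  )
}

#' @export
print.rediscovery_report <- function(x, ...) {
  cat("<rediscovery_report>\n")
  if (nrow(x$per_fold) == 0) {
    cat("  (no masked genes)\n")
  } else {
    print(x$summary, row.names = FALSE, digits = 3)
  }
  invisible(x)
}

#' Candidate-gene ranking from a label assignment
#'
#' Orders every non-positive gene by stationary propagation value,
#' descending (ties broken by gene identifier): the likely-positive block
#' first, continuing through the weaker classes. The top-`|LP|` prefix
#' equals the LP set.
#'
#' @param assignment a `label_assignment`.
#' @return character vector of genes, best candidate first.
#' @export
rank_candidates <- function(assignment) {
  nodes <- names(assignment$labels)
  cand <- nodes[assignment$labels != "P"]
  cand[order(-assignment$g[cand], cand)]
}

#' Precision/recall/F1 of a ranking against a held-out positive set
#'
#' @param ranking ordered candidate genes (see [rank_candidates()]).
#' @param gold held-out positive genes; must be disjoint from the
#'   positives used to build the ranking (they are not in `ranking`'s
#'   universe of candidates otherwise).
#' @param ks cutoffs (numbers of top candidates) to evaluate.
#' @return data.frame with columns `k`, `precision`, `recall`, `f1`.
#' @export
evaluate_ranking <- function(ranking, gold, ks) {
  if (length(gold) == 0L) stop("empty gold set")
  ks <- sort(unique(as.integer(ks)))
  stopifnot(all(ks >= 1), all(ks <= length(ranking)))
  rows <- lapply(ks, function(k) {
    hits <- sum(ranking[seq_len(k)] %in% gold)
    precision <- hits / k
    recall <- hits / length(gold)
    f1 <- if (precision + recall > 0) {
      2 * precision * recall / (precision + recall)
    } else 0
    data.frame(k = k, precision = precision, recall = recall, f1 = f1)
  })
  do.call(rbind, rows)
}
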