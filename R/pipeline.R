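#' Default pipeline configuration
#'
#' One flat list of every tunable, each validated on load. `rn_size = NA`
#' means "match the number of positives".
#'
#' @return named list of parameters.
#' @export
default_config <- function() {
  list(
    # labeling
    alpha = 0.8, tol = 1e-6, max_iter = 10000L, q_w = 0.75,
    rn_size = NA, fractions = c(1, 1, 1) / 3,
    # features
    t_heat = 0.005, t_balanced = 0.005, penalization = 0.5, mixing = 0.5,
    invert_netring = TRUE,
    # classification
    model = "rf", test_fraction = 0.3, cv = 5L,
    # rediscovery
    mask_fraction = 0.2, n_folds = 5L,
    # synthetic instance
    n = 300L, module_size = 30L, p_in = 0.3, p_out = 0.01,
    hidden_fraction = 0.25, score_low = 0.3, score_high = 1,
    # reproducibility
    seed = 1L
  )
}

resolve_rn_size <- function(config, n_positives) {
  if (is.null(config$rn_size) || is.na(config$rn_size)) {
    n_positives
  } else {
    as.integer(config$rn_size)
  }
}

validate_config <- function(config) {
  defaults <- default_config()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  config <- utils::modifyList(defaults, config)
  chk <- function(ok, what) if (!ok) stop("invalid config: ", what)
  chk(config$alpha > 0 && config$alpha <= 1, "alpha must lie in (0, 1]")
  chk(config$tol > 0, "tol must be positive")
  chk(config$max_iter >= 1, "max_iter must be >= 1")
  chk(config$q_w >= 0 && config$q_w < 1, "q_w must lie in [0, 1)")
  chk(is.na(config$rn_size) || config$rn_size >= 1, "rn_size must be >= 1 or NA")
  chk(length(config$fractions) == 3 && all(config$fractions > 0) &&
        abs(sum(config$fractions) - 1) < 1e-8,
      "fractions must be three positive numbers summing to 1")
  chk(config$t_heat > 0 && config$t_balanced > 0, "diffusion times must be positive")
  chk(config$penalization > 0 && config$penalization <= 1,
      "penalization must lie in (0, 1]")
  chk(config$mixing >= 0 && config$mixing <= 1, "mixing must lie in [0, 1]")
  chk(is.logical(config$invert_netring), "invert_netring must be logical")
  chk(config$model %in% c("rf", "svm", "mlp"), "model must be rf, svm or mlp")
  chk(config$test_fraction > 0 && config$test_fraction < 1,
      "test_fraction must lie in (0, 1)")
  chk(config$cv >= 2, "cv must be >= 2")
  chk(config$mask_fraction >= 0 && config$mask_fraction * config$n_folds <= 1 + 1e-12,
      "mask_fraction * n_folds must lie in [0, 1]")
  chk(config$n_folds >= 1, "n_folds must be >= 1")
  chk(config$module_size >= 2 && config$module_size < config$n,
      "module_size must lie in [2, n)")
  chk(config$p_out > 0 && config$p_out < config$p_in && config$p_in <= 1,
      "need 0 < p_out < p_in <= 1")
  chk(config$hidden_fraction >= 0 && config$hidden_fraction < 1,
      "hidden_fraction must lie in [0, 1)")
  chk(config$score_low >= 0 && config$score_low < config$score_high &&
        config$score_high <= 1, "score range must satisfy 0 <= low < high <= 1")
  config$seed <- as.integer(config$seed)
  config
}

#' Read and write the pipeline configuration
#'
#' The configuration is a flat YAML document; unknown keys are rejected
#' and all values are range-checked. Missing keys fall back to
#' [default_config()].
#'
#' @param path YAML file.
#' @return `read_config()` returns the validated config list;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.null(raw$fractions)) raw$fractions <- as.numeric(raw$fractions)
  validate_config(raw)
}

#' @rdname read_config
#' @param config a config list (validated before writing).
#' @export
write_config <- function(config, path) {
  config <- validate_config(config)
  config$rn_size <- if (is.na(config$rn_size)) NULL else config$rn_size
  yaml::write_yaml(config, path, precision = 15L)
  invisible(path)
}

artifact_comment <- function(stage, config) {
  keys <- c("seed", "alpha", "q_w", "t_heat", "t_balanced", "penalization",
            "mixing", "mask_fraction", "n_folds", "model")
  params <- paste(
    vapply(keys, function(k) sprintf("%s=%s", k, format(config[[k]])), ""),
    collapse = " "
  )
  sprintf("netpu %s | stage=%s | %s",
          as.character(utils::packageVersion("netpu")), stage, params)
}

#' Read a label table written by [write_labels()]
#' @param path labels TSV (`gene`, `label`, `g_inf`, `rank`).
#' @return a `label_assignment`.
#' @export
read_labels <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  labels <- factor(tab$label, levels = class_levels)
  names(labels) <- tab$gene
  g <- setNames(tab$g_inf, tab$gene)
  ranked <- tab[!is.na(tab$rank), ]
  structure(
    list(labels = labels, g = g,
         ranking = ranked$gene[order(ranked$rank)],
         fractions = NULL),
    class = "label_assignment"
  )
}

require_artifact <- function(path, producer) {
  if (!file.exists(path)) {
    stop(sprintf("missing artifact '%s'; run stage '%s' first",
                 basename(path), producer))
  }
  path
}

#' Run the full pipeline (or a subset of its stages) in a directory
#'
#' Stages and their artifacts, all written under `dir`:
#' \describe{
#'   \item{simulate}{`network.tsv`, `seeds.tsv`, `hidden.tsv` from
#'     [generate_instance()].}
#'   \item{features}{`features.tsv` from [assemble_features()].}
#'   \item{label}{`labels.tsv` from [apu_label()].}
#'   \item{classify}{`eval_report.json` and `confusion.tsv` from
#'     [train_eval()] and [cross_validate()].}
#'   \item{discover}{`rediscovery.tsv` from [mask_and_rediscover()], and
#'     `ranking_f1.tsv` against `hidden.tsv` when present.}
#' }
#' Later stages read the artifacts of earlier ones, so stages can be
#' re-run individually; a missing upstream artifact is an error naming
#' the stage to run first. Every artifact starts with a `#` comment line
#' recording the package version and the effective parameters (no
#' timestamps), so a rerun with the same config and seed is byte
#' identical.
#'
#' @param config a config list (see [default_config()] / [read_config()]).
#' @param stages character subset of
#'   `c("simulate", "features", "label", "classify", "discover")`,
#'   in pipeline order.
#' @param dir working directory for artifacts (created if missing).
#' @return named list with the computed objects of the executed stages,
#'   invisibly.
#' @export
run_pipeline <- function(config = default_config(),
                         stages = c("simulate", "features", "label",
                                    "classify", "discover"),
                         dir = ".") {
  config <- validate_config(config)
  all_stages <- c("simulate", "features", "label", "classify", "discover")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  stages <- all_stages[all_stages %in% stages]
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  out <- list()

  if ("simulate" %in% stages) {
    np_log("stage simulate: n=%d module=%d seed=%d",
           config$n, config$module_size, config$seed)
    inst <- generate_instance(
      n = config$n, module_size = config$module_size, p_in = config$p_in,
      p_out = config$p_out, hidden_fraction = config$hidden_fraction,
      score_range = c(config$score_low, config$score_high),
      rng_seed = config$seed
    )
    write_instance(inst, dir, comment = artifact_comment("simulate", config))
    out$instance <- inst
  }

  if ("features" %in% stages) {
    net <- load_network(require_artifact(p("network.tsv"), "simulate"))
    seeds <- load_seeds(require_artifact(p("seeds.tsv"), "simulate"), net)
    np_log("stage features: %d nodes, %d seeds", network_size(net),
           length(seeds$genes))
    X <- assemble_features(
      net, seeds, t_heat = config$t_heat, t_balanced = config$t_balanced,
      penalization = config$penalization, mixing = config$mixing,
      invert_netring = config$invert_netring
    )
    write_features(X, p("features.tsv"),
                   comment = artifact_comment("features", config))
    out$features <- X
  }

  if ("label" %in% stages) {
    X <- read_features(require_artifact(p("features.tsv"), "features"))
    net <- load_network(require_artifact(p("network.tsv"), "simulate"))
    seeds <- load_seeds(require_artifact(p("seeds.tsv"), "simulate"), net)
    np_log("stage label: alpha=%g q_w=%g", config$alpha, config$q_w)
    lab <- apu_label(
      X, positives = seeds$genes, q_w = config$q_w, alpha = config$alpha,
      tol = config$tol, max_iter = config$max_iter,
      n_rn = resolve_rn_size(config, length(seeds$genes)),
      fractions = config$fractions
    )
    write_labels(lab, p("labels.tsv"),
                 comment = artifact_comment("label", config))
    out$labels <- lab
  }

  if ("classify" %in% stages) {
    X <- read_features(require_artifact(p("features.tsv"), "features"))
    lab <- read_labels(require_artifact(p("labels.tsv"), "label"))
    np_log("stage classify: model=%s", config$model)
    rep <- train_eval(X, lab, model = config$model,
                      test_fraction = config$test_fraction,
                      seed = config$seed)
    cv <- cross_validate(X, lab, model = config$model, k = config$cv,
                         seed = config$seed)
    report <- list(
      model = config$model,
      test_fraction = config$test_fraction,
      accuracy = rep$accuracy,
      macro_avg = as.list(rep$macro_avg),
      weighted_avg = as.list(rep$weighted_avg),
      per_class = rep$per_class,
      cv = list(k = cv$k, summary = cv$summary)
    )
    jsonlite::write_json(report, p("eval_report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    cm <- as.data.frame.matrix(rep$confusion)
    con <- file(p("confusion.tsv"), "w")
    writeLines(paste0("# ", artifact_comment("classify", config)), con)
    writeLines(paste(c("truth", colnames(cm)), collapse = "\t"), con)
    writeLines(vapply(seq_len(nrow(cm)), function(i) {
      paste(c(rownames(cm)[i], as.integer(cm[i, ])), collapse = "\t")
    }, ""), con)
    close(con)
    out$classify <- list(holdout = rep, cv = cv)
  }

  if ("discover" %in% stages) {
    net <- load_network(require_artifact(p("network.tsv"), "simulate"))
    seeds <- load_seeds(require_artifact(p("seeds.tsv"), "simulate"), net)
    np_log("stage discover: mask_fraction=%g n_folds=%d",
           config$mask_fraction, config$n_folds)
    redisc <- mask_and_rediscover(
      net, seeds, mask_fraction = config$mask_fraction,
      n_folds = config$n_folds, config = config, seed = config$seed
    )
    con <- file(p("rediscovery.tsv"), "w")
    writeLines(paste0("# ", artifact_comment("discover", config)), con)
    writeLines("fold\tlabel\tcount\tpercent", con)
    pf <- redisc$per_fold
    if (nrow(pf) > 0) {
      writeLines(paste(pf$fold, pf$label, pf$count, format_num(pf$percent),
                       sep = "\t"), con)
    }
    close(con)
    out$rediscovery <- redisc
    if (file.exists(p("hidden.tsv")) && file.exists(p("labels.tsv"))) {
      hidden <- read.table(p("hidden.tsv"), sep = "\t", header = TRUE,
                           comment.char = "#",
                           stringsAsFactors = FALSE)$gene
      lab <- read_labels(p("labels.tsv"))
      ranking <- rank_candidates(lab)
      ks <- unique(pmin(length(ranking),
                        ceiling(c(0.5, 1, 2, 5) * length(hidden))))
      f1 <- evaluate_ranking(ranking, hidden, ks)
      con <- file(p("ranking_f1.tsv"), "w")
      writeLines(paste0("# ", artifact_comment("discover", config)), con)
      writeLines("k\tprecision\trecall\tf1", con)
      writeLines(paste(f1$k, format_num(f1$precision), format_num(f1$recall),
                       format_num(f1$f1), sep = "\t"), con)
      close(con)
      out$ranking_eval <- f1
    }
  }

  invisible(out)
}
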