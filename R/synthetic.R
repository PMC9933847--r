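#' Generate a synthetic network with a planted disease module
#'
#' Draws a planted-partition graph: every pair inside the module is an
#' edge with probability `p_in`, every other pair with probability
#' `p_out` (`p_out < p_in`, so the module is denser than the background,
#' emulating a disease module on an interactome). If the draw is
#' disconnected, minimal random inter-component edges are added (and
#' counted) rather than resampling, so the stated edge probabilities stay
#' honest. Module genes are split into visible seeds — carrying
#' association scores drawn uniformly from `score_range`, echoing the
#' 0.3-1.0 range typical of curated gene-disease association scores — and
#' hidden positives that stand in for to-be-discovered disease genes.
#'
#' @param n total number of genes (default 300).
#' @param module_size planted module size (default 30).
#' @param p_in,p_out within-module and background edge probabilities
#'   (defaults 0.3 and 0.01).
#' @param hidden_fraction fraction of module genes withheld as hidden
#'   positives (default 0.25).
#' @param score_range `(low, high)` of the uniform association scores
#'   (default `c(0.3, 1)`).
#' @param rng_seed integer seed; the whole instance is a deterministic
#'   function of it.
#' @return object of class `synthetic_instance`: `net` (`pu_network`),
#'   `module`, `seeds` (`seed_set` of the visible module genes),
#'   `hidden` (hidden positives), `n_repair_edges`, `rng_seed`.
#' @export
generate_instance <- function(n = 300L, module_size = 30L, p_in = 0.3,
                              p_out = 0.01, hidden_fraction = 0.25,
                              score_range = c(0.3, 1), rng_seed = 1L) {
  stopifnot(module_size < n, module_size >= 2)
  if (!(p_out > 0 && p_out < p_in && p_in <= 1)) {
    stop("need 0 < p_out < p_in <= 1")
  }
  stopifnot(length(score_range) == 2, score_range[1] >= 0,
            score_range[2] <= 1, score_range[1] < score_range[2])
  with_rng(rng_seed, {
    width <- nchar(as.character(n))
    nodes <- sprintf("g%0*d", width, seq_len(n))
    module <- sort(sample(nodes, module_size))
    pair <- which(upper.tri(matrix(FALSE, n, n)), arr.ind = TRUE)
    in_mod <- nodes[pair[, 1]] %in% module & nodes[pair[, 2]] %in% module
    p <- ifelse(in_mod, p_in, p_out)
    keep <- rbinom(length(p), 1L, p) == 1L
    edges <- cbind(nodes[pair[keep, 1]], nodes[pair[keep, 2]])
    g <- igraph::graph_from_data_frame(
      data.frame(from = edges[, 1], to = edges[, 2]),
      directed = FALSE, vertices = nodes
    )
    repairs <- 0L
    repeat {
      comp <- igraph::components(g)
      if (comp$no == 1L) break
      if (repairs > 4L * n) stop("connectivity repair did not terminate")
      # bridge the two first components with one random edge
      # (sample.int guards the length-1 which() case)
      pick <- function(x) x[sample.int(length(x), 1L)]
      c1 <- pick(which(comp$membership == 1L))
      c2 <- pick(which(comp$membership == 2L))
      g <- igraph::add_edges(g, c(c1, c2))
      repairs <- repairs + 1L
    }
    if (repairs > 0L) {
      np_log("generate_instance: added %d edge(s) to connect the graph", repairs)
    }
    net <- as_pu_network(igraph::as_edgelist(g))
    n_hidden <- round(hidden_fraction * module_size)
    if (module_size - n_hidden < 2L) stop("hidden_fraction leaves < 2 visible seeds")
    hidden <- sort(sample(module, n_hidden))
    visible <- setdiff(module, hidden)
    scores <- score_range[1] +
      (score_range[2] - score_range[1]) * runif(length(visible))
    structure(
      list(
        net = net, module = module,
        seeds = seed_set(visible, scores, net),
        hidden = hidden, n_repair_edges = repairs, rng_seed = rng_seed
      ),
      class = "synthetic_instance"
    )
  })
}

#' @export
print.synthetic_instance <- function(x, ...) {
  cat(sprintf(
    "<synthetic_instance> %d nodes, module %d (%d visible seeds, %d hidden), seed %d\n",
    network_size(x$net), length(x$module), length(x$seeds$genes),
    length(x$hidden), x$rng_seed
  ))
  invisible(x)
}

#' Write a synthetic instance as pipeline input files
#'
#' Writes `network.tsv`, `seeds.tsv` and `hidden.tsv` (the held-out
#' positives, one gene per line under a header) in the formats
#' [load_network()] and [load_seeds()] read.
#'
#' @param instance a `synthetic_instance`.
#' @param dir output directory (created if missing).
#' @param comment optional `#` comment line for each file.
#' @return named character vector of the three paths, invisibly.
#' @export
write_instance <- function(instance, dir, comment = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    network = file.path(dir, "network.tsv"),
    seeds = file.path(dir, "seeds.tsv"),
    hidden = file.path(dir, "hidden.tsv")
  )
  write_network(instance$net, paths[["network"]], comment = comment)
  write_seeds(instance$seeds, paths[["seeds"]], comment = comment)
  con <- file(paths[["hidden"]], "w")
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(c("gene", instance$hidden), con)
  close(con)
  invisible(paths)
}
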