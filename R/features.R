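minmax_scale <- function(x, name) {
  rng <- range(x)
  if (rng[1] == rng[2]) {
    warning(sprintf("feature '%s' is constant; normalized to all zeros", name))
    return(rep(0, length(x)))
  }
  (x - rng[1]) / (rng[2] - rng[1])
}

#' Assemble the normalized node-feature matrix
#'
#' Computes the four seed-aware features — heat diffusion, balanced
#' diffusion, score-weighted harmonic centrality ([netshort()]) and the
#' ring rank ([netring()]) — and min-max normalizes each column to
#' `[0, 1]`. The raw ring rank grows with distance from the seeds,
#' opposite to the other three; by default it is flipped
#' (`max - r_i`) before normalization so that in every column larger
#' means closer to the disease module. A constant column normalizes to
#' all zeros with a warning.
#'
#' @param net a connected `pu_network`.
#' @param seeds a `seed_set` on `net`.
#' @param t_heat,t_balanced diffusion times (default 0.005 each).
#' @param penalization non-seed score penalization for [netshort()].
#' @param mixing seed-rank mixing weight for [netring()].
#' @param invert_netring flip the ring rank so larger = closer (default
#'   `TRUE`).
#' @return a `feature_matrix`: numeric matrix, rows named by node in
#'   network order, columns `heat`, `balanced`, `netshort`, `netring`,
#'   all entries in `[0, 1]`.
#' @export
assemble_features <- function(net, seeds, t_heat = 0.005, t_balanced = 0.005,
                              penalization = 0.5, mixing = 0.5,
                              invert_netring = TRUE) {
  heat <- heat_diffusion(net, seeds, t = t_heat)$z
  bal <- balanced_diffusion(net, seeds, t = t_balanced)$z
  ns <- netshort(net, seeds, penalization = penalization)
  nr <- netring(net, seeds, mixing = mixing)
  if (invert_netring) nr <- max(nr) - nr
  X <- cbind(
    heat = minmax_scale(heat, "heat"),
    balanced = minmax_scale(bal, "balanced"),
    netshort = minmax_scale(ns, "netshort"),
    netring = minmax_scale(nr, "netring")
  )
  rownames(X) <- net$nodes
  structure(X, class = c("feature_matrix", class(X)))
}

#' Write a feature matrix as TSV
#' @param X a `feature_matrix` (or any matrix with rownames).
#' @param path output file.
#' @param comment optional `#` comment line.
#' @return `path`, invisibly.
#' @export
write_features <- function(X, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines(paste(c("gene", colnames(X)), collapse = "\t"), con)
  rows <- apply(X, 1, function(v) paste(format_num(v), collapse = "\t"))
  writeLines(paste(rownames(X), rows, sep = "\t"), con)
  invisible(path)
}

#' Read a feature matrix written by [write_features()]
#' @param path TSV path with a `gene` column then numeric feature columns.
#' @return a `feature_matrix`.
#' @export
read_features <- function(path) {
  tab <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
  X <- as.matrix(tab[, -1, drop = FALSE])
  rownames(X) <- tab[[1]]
  structure(X, class = c("feature_matrix", class(X)))
}
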