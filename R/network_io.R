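#' Build a working interaction network from an edge table
#'
#' Cleans an undirected edge list the way interactome preprocessing does:
#' self-loops are dropped, undirected duplicates (`(u,v)` and `(v,u)`)
#' collapsed, and only the largest connected component is retained. Node
#' order is lexicographic so every downstream matrix is reproducible.
#'
#' @param edges two-column character matrix or data.frame of node pairs.
#' @return an object of class `pu_network`: a list with `graph` (igraph),
#'   `nodes` (lexicographically ordered identifiers) and `n_dropped_nodes`
#'   (nodes lost to smaller components).
#' @export
as_pu_network <- function(edges) {
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  storage.mode(edges) <- "character"
  edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]
  if (nrow(edges) == 0L) {
    stop("no edges remain after removing self-loops")
  }
  # undirected dedup: order endpoints within each pair
  a <- pmin(edges[, 1], edges[, 2])
  b <- pmax(edges[, 1], edges[, 2])
  keep <- !duplicated(paste(a, b, sep = "\r"))
  a <- a[keep]; b <- b[keep]
  nodes <- sort(unique(c(a, b)))
  g <- igraph::graph_from_edgelist(cbind(a, b), directed = FALSE)
  g <- igraph::permute(g, match(igraph::V(g)$name, nodes))
  comp <- igraph::components(g)
  dropped <- 0L
  if (comp$no > 1L) {
    keep_comp <- which.max(comp$csize)
    dropped <- as.integer(sum(comp$csize[-keep_comp]))
    warning(sprintf(
      "input has %d components; keeping the largest (%d nodes), dropping %d",
      comp$no, comp$csize[keep_comp], dropped
    ))
    g <- igraph::induced_subgraph(g, which(comp$membership == keep_comp))
    nodes <- sort(igraph::V(g)$name)
    g <- igraph::permute(g, match(igraph::V(g)$name, nodes))
  }
  structure(
    list(graph = g, nodes = nodes, n_dropped_nodes = dropped),
    class = "pu_network"
  )
}

#' @export
print.pu_network <- function(x, ...) {
  cat(sprintf(
    "<pu_network> %d nodes, %d edges (connected)\n",
    length(x$nodes), igraph::ecount(x$graph)
  ))
  invisible(x)
}

#' Number of nodes of a network
#' @param net a `pu_network`.
#' @return integer node count.
#' @export
network_size <- function(net) length(net$nodes)

#' Node degrees in network node order
#' @param net a `pu_network`.
#' @return named integer vector of degrees `k_i`.
#' @export
network_degrees <- function(net) {
  d <- igraph::degree(net$graph)
  d[net$nodes]
}

#' Sparse adjacency matrix in network node order
#' @param net a `pu_network`.
#' @return symmetric sparse 0/1 `Matrix`.
#' @export
network_adjacency <- function(net) {
  A <- igraph::as_adjacency_matrix(net$graph, sparse = TRUE)
  A[net$nodes, net$nodes]
}

# first data row of a 2-column file looks like a header?
looks_like_header <- function(row, numeric_col = NA_integer_) {
  if (!is.na(numeric_col)) {
    return(is.na(suppressWarnings(as.numeric(row[numeric_col]))))
  }
  namey <- c(
    "gene", "genes", "node", "source", "target", "from", "to",
    "interactor_a", "interactor_b", "gene_a", "gene_b", "a", "b"
  )
  any(tolower(row) %in% namey)
}

read_tsv_body <- function(path, header) {
  raw <- read.table(
    path, sep = "\t", header = FALSE, comment.char = "#",
    colClasses = "character", quote = "", stringsAsFactors = FALSE,
    blank.lines.skip = TRUE
  )
  list(body = raw, header_row = header)
}

#' Load an interaction network from an edge-list file
#'
#' Reads a tab-separated edge list (two identifier columns) or a BioGRID
#' TAB3-style export, then applies [as_pu_network()] cleaning: self-loops
#' and redundant undirected pairs removed, largest connected component
#' kept, nodes ordered lexicographically.
#'
#' @param path file path; tab-separated, `#` comment lines ignored.
#' @param format `"tsv"` (default; first two columns are the endpoints) or
#'   `"biogrid"` (columns `Official Symbol Interactor A/B` with an organism
#'   filter on `Organism ID Interactor A/B`).
#' @param header `TRUE`, `FALSE`, or `"auto"` (header detected when the
#'   first row contains common column names such as `gene`/`source`).
#' @param organism_filter organism identifier kept under
#'   `format = "biogrid"` (default `"9606"`, human); `NULL` disables it.
#' @return a `pu_network`.
#' @export
load_network <- function(path, format = c("tsv", "biogrid"),
                         header = "auto", organism_filter = "9606") {
  format <- match.arg(format)
  if (!file.exists(path) || file.size(path) == 0L) {
    stop("empty network file: ", path)
  }
  raw <- read.table(
    path, sep = "\t", header = FALSE, comment.char = "#",
    colClasses = "character", quote = "", stringsAsFactors = FALSE,
    blank.lines.skip = TRUE
  )
  if (nrow(raw) == 0L) stop("empty network file: ", path)
  if (ncol(raw) < 2L) stop("network file needs >= 2 columns: ", path)
  if (format == "biogrid") {
    hdr <- as.character(raw[1, ])
    ia <- match("Official Symbol Interactor A", hdr)
    ib <- match("Official Symbol Interactor B", hdr)
    oa <- match("Organism ID Interactor A", hdr)
    ob <- match("Organism ID Interactor B", hdr)
    if (any(is.na(c(ia, ib)))) {
      stop("biogrid format requires 'Official Symbol Interactor A/B' columns")
    }
    raw <- raw[-1, , drop = FALSE]
    if (!is.null(organism_filter) && !any(is.na(c(oa, ob)))) {
      keep <- raw[[oa]] == organism_filter & raw[[ob]] == organism_filter
      raw <- raw[keep, , drop = FALSE]
    }
    edges <- as.matrix(raw[, c(ia, ib), drop = FALSE])
  } else {
    if (identical(header, "auto")) {
      header <- looks_like_header(as.character(raw[1, 1:2]))
    }
    if (isTRUE(header)) raw <- raw[-1, , drop = FALSE]
    edges <- as.matrix(raw[, 1:2, drop = FALSE])
  }
  if (nrow(edges) == 0L) stop("no edges after filtering: ", path)
  as_pu_network(edges)
}

#' Write a network as a two-column edge list
#'
#' @param net a `pu_network`.
#' @param path output file.
#' @param comment optional `#` comment line written before the header.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, comment = NULL) {
  el <- igraph::as_edgelist(net$graph)
  a <- pmin(el[, 1], el[, 2]); b <- pmax(el[, 1], el[, 2])
  o <- order(a, b)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("gene_a\tgene_b", con)
  writeLines(paste(a[o], b[o], sep = "\t"), con)
  invisible(path)
}

#' Construct a seed set of scored disease genes
#'
#' @param genes character vector of gene identifiers (must be in `net`).
#' @param scores numeric association scores in `(0, 1]`, one per gene.
#' @param net the `pu_network` the seeds live on.
#' @return object of class `seed_set`: list with `genes` (lexicographic),
#'   `scores` (named), `min_score`, `max_score`.
#' @export
seed_set <- function(genes, scores, net) {
  stopifnot(length(genes) == length(scores))
  if (anyDuplicated(genes)) stop("duplicate genes in seed_set(); resolve first")
  bad <- !(genes %in% net$nodes)
  if (any(bad)) stop("seed genes not in network: ", paste(genes[bad], collapse = ", "))
  if (length(genes) == 0L) stop("empty seed set")
  if (any(!is.finite(scores)) || any(scores <= 0) || any(scores > 1)) {
    i <- which(!is.finite(scores) | scores <= 0 | scores > 1)[1]
    stop(sprintf("association score out of (0,1] for gene '%s': %s",
                 genes[i], format(scores[i])))
  }
  o <- order(genes)
  genes <- genes[o]; scores <- scores[o]
  structure(
    list(
      genes = genes,
      scores = setNames(as.numeric(scores), genes),
      min_score = min(scores),
      max_score = max(scores)
    ),
    class = "seed_set"
  )
}

#' @export
print.seed_set <- function(x, ...) {
  cat(sprintf(
    "<seed_set> %d seeds, scores in [%.3g, %.3g]\n",
    length(x$genes), x$min_score, x$max_score
  ))
  invisible(x)
}

#' Load a gene-disease association table as a seed set
#'
#' Reads a `gene<TAB>score` table, drops genes absent from the network
#' (count reported via a message), resolves duplicate genes by keeping the
#' maximum score, and validates that scores lie in `(0, 1]`.
#'
#' @param path TSV path (`#` comments ignored).
#' @param net a `pu_network`.
#' @param header `TRUE`, `FALSE`, or `"auto"` (header assumed when the
#'   score field of the first row is not numeric).
#' @return a `seed_set`.
#' @export
load_seeds <- function(path, net, header = "auto") {
  raw <- read.table(
    path, sep = "\t", header = FALSE, comment.char = "#",
    colClasses = "character", quote = "", stringsAsFactors = FALSE,
    blank.lines.skip = TRUE
  )
  if (nrow(raw) == 0L || ncol(raw) < 2L) stop("seed file needs gene<TAB>score rows: ", path)
  if (identical(header, "auto")) {
    header <- looks_like_header(as.character(raw[1, 1:2]), numeric_col = 2L)
  }
  if (isTRUE(header)) raw <- raw[-1, , drop = FALSE]
  genes <- raw[[1]]
  scores <- suppressWarnings(as.numeric(raw[[2]]))
  if (anyNA(scores)) {
    stop("non-numeric association score at row ", which(is.na(scores))[1])
  }
  bad <- scores <= 0 | scores > 1
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf("association score out of (0,1] at row %d (gene '%s'): %s",
                 i, genes[i], format(scores[i])))
  }
  inside <- genes %in% net$nodes
  if (any(!inside)) {
    np_log("load_seeds: dropped %d gene(s) absent from the network", sum(!inside))
  }
  genes <- genes[inside]; scores <- scores[inside]
  if (length(genes) == 0L) stop("no seed genes remain after network intersection")
  # duplicate rows keep the strongest evidence
  mx <- tapply(scores, genes, max)
  seed_set(names(mx), as.numeric(mx), net)
}

#' Write a seed set as a gene/score TSV
#' @param seeds a `seed_set`.
#' @param path output file.
#' @param comment optional `#` comment line.
#' @return `path`, invisibly.
#' @export
write_seeds <- function(seeds, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  writeLines("gene\tscore", con)
  writeLines(paste(seeds$genes, format_num(seeds$scores), sep = "\t"), con)
  invisible(path)
}

# fixed-format numeric rendering shared by all artifact writers
format_num <- function(x) sprintf("%.10g", x)
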