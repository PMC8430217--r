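#' Construct an interaction network
#'
#' A `ppi_network` bundles an ordered node-label vector with a symmetric,
#' non-negative adjacency matrix whose diagonal is zero.  For unweighted
#' networks every edge weight is exactly 1.
#'
#' @param nodes character vector of unique node labels (row/column order of
#'   the adjacency matrix).
#' @param adjacency symmetric numeric matrix, non-negative, zero diagonal.
#' @param weighted logical; if `FALSE`, nonzero entries must all equal 1.
#' @return An object of class `ppi_network` with elements `nodes`,
#'   `adjacency` (dense base matrix with dimnames), and `weighted`.
#' @export
ppi_network <- function(nodes, adjacency, weighted = FALSE) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("node labels must be unique")
  adjacency <- as.matrix(adjacency)
  n <- length(nodes)
  if (!all(dim(adjacency) == c(n, n)))
    stop("adjacency must be ", n, "x", n, " to match nodes")
  if (any(adjacency < 0)) stop("adjacency entries must be non-negative")
  if (!isTRUE(all.equal(adjacency, t(adjacency), tolerance = 0)))
    stop("adjacency must be exactly symmetric")
  if (any(diag(adjacency) != 0)) stop("adjacency diagonal must be zero")
  if (!weighted && any(adjacency != 0 & adjacency != 1))
    stop("unweighted network has edge weights other than 1")
  dimnames(adjacency) <- list(nodes, nodes)
  structure(list(nodes = nodes, adjacency = adjacency,
                 weighted = isTRUE(weighted)),
            class = "ppi_network")
}

#' @method print ppi_network
#' @export
print.ppi_network <- function(x, ...) {
  m <- sum(x$adjacency != 0) / 2
  cat(sprintf("<ppi_network> %d nodes, %d edges (%s)\n",
              length(x$nodes), m, if (x$weighted) "weighted" else "unweighted"))
  invisible(x)
}

#' Number of nodes / edges of a network
#' @param net a `ppi_network`.
#' @return integer count.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) sum(net$adjacency != 0) / 2

#' Read an edge list file into a network
#'
#' Each non-comment line holds `node_a node_b [weight]`, whitespace- or
#' tab-separated.  Nodes are indexed in order of first appearance.  Duplicate
#' edges (either orientation) collapse to the maximum weight; self-loops are
#' dropped with a warning.  Lines starting with `#` are comments; a first
#' line whose third column is not numeric is treated as a header and skipped
#' with a warning.
#'
#' @param path path to the edge-list file.
#' @param weighted logical; if `TRUE` the third column is used as edge
#'   weight (missing third column means weight 1).
#' @return A [ppi_network()].
#' @export
read_edgelist <- function(path, weighted = FALSE) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("no edge lines in ", path)
  toks <- strsplit(trimws(lines[keep]), "[ \t]+")
  # header heuristic: first data line with a non-numeric third column
  if (length(toks[[1]]) >= 3 && is.na(suppressWarnings(as.numeric(toks[[1]][3])))) {
    warning("skipping apparent header line: ", lines[keep[1]])
    keep <- keep[-1]; toks <- toks[-1]
    if (length(toks) == 0L) stop("no edge lines in ", path)
  }
  nf <- lengths(toks)
  if (any(nf < 2))
    stop("malformed line ", keep[which(nf < 2)[1]], ": fewer than 2 columns")
  a <- vapply(toks, `[`, "", 1L)
  b <- vapply(toks, `[`, "", 2L)
  w <- rep(1, length(toks))
  if (weighted) {
    has3 <- nf >= 3
    w3 <- suppressWarnings(as.numeric(vapply(toks[has3], `[`, "", 3L)))
    if (anyNA(w3))
      stop("malformed line ", keep[has3][which(is.na(w3))[1]],
           ": weight does not parse as a number")
    if (any(w3 < 0))
      stop("negative weight on line ", keep[has3][which(w3 < 0)[1]])
    w[has3] <- w3
  }
  nodes <- unique(as.vector(rbind(a, b)))  # first-appearance order
  self <- a == b
  if (any(self)) {
    warning(sum(self), " self-loop(s) dropped")
    a <- a[!self]; b <- b[!self]; w <- w[!self]
  }
  n <- length(nodes)
  adj <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (length(a)) {
    ia <- match(a, nodes); ib <- match(b, nodes)
    for (e in seq_along(ia)) {           # max-collapse of duplicates
      v <- max(adj[ia[e], ib[e]], w[e])
      adj[ia[e], ib[e]] <- v; adj[ib[e], ia[e]] <- v
    }
  }
  ppi_network(nodes, adj, weighted = weighted)
}

#' Write a network as an edge list
#'
#' Emits one `node_a<TAB>node_b[<TAB>weight]` line per edge (upper triangle),
#' at full precision; round-trips with [read_edgelist()].
#'
#' @param net a `ppi_network`.
#' @param path output file path.
#' @export
write_edgelist <- function(net, path) {
  idx <- which(upper.tri(net$adjacency) & net$adjacency != 0, arr.ind = TRUE)
  lines <- if (net$weighted) {
    sprintf("%s\t%s\t%s", net$nodes[idx[, 1]], net$nodes[idx[, 2]],
            format(net$adjacency[idx], digits = 17, trim = TRUE))
  } else {
    sprintf("%s\t%s", net$nodes[idx[, 1]], net$nodes[idx[, 2]])
  }
  # keep first-appearance node order reproducible: emit isolated nodes? edges only.
  writeLines(lines, path)
  invisible(NULL)
}

#' Write a labeled numeric matrix as TSV
#'
#' Full-precision TSV with a header row of column labels and a first column
#' of row labels; round-trips with [read_matrix_tsv()].
#'
#' @param m numeric matrix.
#' @param row_labels,col_labels label vectors matching `dim(m)`.
#' @param path output file path.
#' @export
write_matrix_tsv <- function(m, row_labels, col_labels, path) {
  m <- as.matrix(m)
  stopifnot(length(row_labels) == nrow(m), length(col_labels) == ncol(m))
  dimnames(m) <- list(row_labels, col_labels)
  utils::write.table(format(m, digits = 17, trim = TRUE), file = path,
                     sep = "\t", quote = FALSE, col.names = NA)
  invisible(NULL)
}

#' @rdname write_matrix_tsv
#' @return `read_matrix_tsv` returns the labeled numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE)
  as.matrix(df)
}
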