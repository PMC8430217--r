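#' Must-link constraint set
#'
#' Unordered node pairs known to belong to the same complex, with a common
#' weight `alpha` that balances prior information against network topology
#' in the SSNMTF objective.
#'
#' @param pairs two-column character matrix (or data.frame) of node labels,
#'   one unordered pair per row.  Self-pairs are rejected; duplicate pairs
#'   (either orientation) are collapsed.
#' @param alpha positive constraint weight (default 10, the value at which
#'   detection performance peaks across interaction networks).
#' @return An object of class `mustlink`, with elements `pairs` (canonical
#'   two-column character matrix) and `alpha`.
#' @export
mustlink <- function(pairs, alpha = 10) {
  stopifnot(alpha > 0)
  pairs <- as.matrix(pairs)
  if (length(pairs) == 0L) {
    pairs <- matrix(character(), 0, 2)
  } else {
    if (ncol(pairs) != 2) stop("pairs must have two columns")
    pairs <- matrix(as.character(pairs), ncol = 2)
    if (any(pairs[, 1] == pairs[, 2])) stop("a node cannot be must-linked to itself")
    swap <- pairs[, 1] > pairs[, 2]      # canonical order inside each pair
    pairs[swap, ] <- pairs[swap, 2:1]
    pairs <- unique(pairs)
  }
  colnames(pairs) <- c("node_a", "node_b")
  structure(list(pairs = pairs, alpha = alpha), class = "mustlink")
}

#' @method print mustlink
#' @export
print.mustlink <- function(x, ...) {
  cat(sprintf("<mustlink> %d pairs, alpha = %g\n", nrow(x$pairs), x$alpha))
  invisible(x)
}

#' Read / write a must-link constraint file
#'
#' TSV with one `node_a<TAB>node_b` pair per line; `#` comments allowed.
#'
#' @param path file path.
#' @param alpha constraint weight attached on read.
#' @return `read_mustlinks` returns a [mustlink()] object.
#' @export
read_mustlinks <- function(path, alpha = 10) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(lines, "[ \t]+")
  if (any(lengths(toks) < 2)) stop("malformed must-link line in ", path)
  mustlink(cbind(vapply(toks, `[`, "", 1L), vapply(toks, `[`, "", 2L)),
           alpha = alpha)
}

#' @rdname read_mustlinks
#' @param ml a `mustlink` object.
#' @export
write_mustlinks <- function(ml, path) {
  writeLines(sprintf("%s\t%s", ml$pairs[, 1], ml$pairs[, 2]), path)
  invisible(NULL)
}

#' Sample must-link constraints from a reference catalog
#'
#' Candidate pairs are formed, within each reference complex, only among
#' members that belong to exactly one complex in the whole catalog (proteins
#' participating in several complexes carry ambiguous pair information and
#' contribute none).  A complex whose single-membership part has
#' \eqn{N_c} proteins therefore contributes \eqn{N_c (N_c - 1) / 2}
#' candidates.  A uniform sample of `round(fraction * total)` pairs
#' (round-half-up) is then drawn without replacement from the pooled
#' candidate list.
#'
#' @param reference a `complex_cover` used as the source of prior knowledge.
#' @param fraction fraction of the candidate pool to sample, in `[0, 1]`.
#' @param alpha constraint weight.
#' @param seed integer RNG seed making the sample reproducible.
#' @return A [mustlink()] object (possibly empty, with a warning).
#' @export
sample_mustlinks <- function(reference, fraction = 0.1, alpha = 10, seed = 1L) {
  stopifnot(fraction >= 0, fraction <= 1)
  membership <- table(unlist(lapply(reference$complexes, unique)))
  single <- names(membership)[membership == 1]
  cand_a <- character(0); cand_b <- character(0)
  for (cx in reference$complexes) {
    mem <- intersect(cx, single)
    if (length(mem) >= 2) {
      p <- utils::combn(mem, 2)
      cand_a <- c(cand_a, p[1, ]); cand_b <- c(cand_b, p[2, ])
    }
  }
  pool <- length(cand_a)
  take <- min(pool, round_half_up(fraction * pool))
  if (take == 0L) {
    if (pool == 0L) warning("no single-membership candidate pairs in reference")
    return(mustlink(matrix(character(), 0, 2), alpha = alpha))
  }
  sel <- with_seed(seed, sample.int(pool, take))
  mustlink(cbind(cand_a[sel], cand_b[sel]), alpha = alpha)
}

#' Build the constraint matrix, its degree matrix and Laplacian
#'
#' Materializes the must-link pairs against a network's node order as the
#' symmetric matrix \eqn{M} (entries \eqn{\alpha} on constrained pairs, 0
#' elsewhere), the diagonal degree matrix \eqn{D} with
#' \eqn{d_{ii} = \sum_j m_{ij}}, and the graph Laplacian \eqn{L = D - M},
#' which is positive semi-definite with zero row sums.  Sparse `Matrix`
#' classes are used throughout; must-link networks are far sparser than the
#' interaction network itself.
#'
#' @param constraints a [mustlink()] object (or `NULL` for the unconstrained
#'   model, giving all-zero matrices).
#' @param net the `ppi_network` fixing node order.
#' @param on_missing `"error"` (default) rejects pairs naming nodes absent
#'   from the network; `"drop"` discards them with a warning (useful when a
#'   catalog and a network only partly overlap).
#' @return A list of class `mustlink_matrices` with sparse matrices `M`,
#'   `D`, `L` (in `net` node order) and the scalar `alpha`.
#' @export
build_constraint_matrices <- function(constraints, net,
                                      on_missing = c("error", "drop")) {
  on_missing <- match.arg(on_missing)
  n <- length(net$nodes)
  if (is.null(constraints))
    constraints <- mustlink(matrix(character(), 0, 2), alpha = 1)
  pr <- constraints$pairs
  ia <- match(pr[, 1], net$nodes); ib <- match(pr[, 2], net$nodes)
  bad <- is.na(ia) | is.na(ib)
  if (any(bad)) {
    labs <- unique(c(pr[is.na(ia), 1], pr[is.na(ib), 2]))
    if (on_missing == "error")
      stop("constraint node(s) not in network: ", paste(labs, collapse = ", "))
    warning(sum(bad), " constraint pair(s) dropped (nodes absent from network: ",
            paste(utils::head(labs, 5), collapse = ", "), ")")
    ia <- ia[!bad]; ib <- ib[!bad]
  }
  M <- Matrix::sparseMatrix(i = c(ia, ib), j = c(ib, ia),
                            x = rep(constraints$alpha, 2L * length(ia)),
                            dims = c(n, n),
                            dimnames = list(net$nodes, net$nodes))
  D <- Matrix::Diagonal(n, x = Matrix::rowSums(M))
  structure(list(M = M, D = D, L = D - M, alpha = constraints$alpha),
            class = "mustlink_matrices")
}
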