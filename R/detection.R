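#' Non-overlapping complex assignment (row argmax)
#'
#' Each node joins the module with the largest entry in its row of the
#' membership matrix `F`; ties break toward the lowest column index.
#' Columns that are the argmax of no row are empty modules and yield no
#' complex — this is how a generously chosen module budget `k` adapts down
#' to the detected number of complexes.  An all-zero row carries no signal
#' and is assigned to the first column with a warning.
#'
#' @param F non-negative membership matrix (n x k).
#' @param nodes node labels for the rows of `F`.
#' @return A [complex_cover()]; before any size filtering it partitions the
#'   node set.
#' @export
assign_nonoverlapping <- function(F, nodes) {
  F <- as.matrix(F)
  stopifnot(nrow(F) == length(nodes), all(F >= 0))
  zero <- rowSums(F) == 0
  if (any(zero))
    warning(sum(zero), " all-zero row(s) assigned to the first module")
  assign <- max.col(F, ties.method = "first")
  occupied <- sort(unique(assign))
  complex_cover(lapply(occupied, function(c) nodes[assign == c]),
                name = "nonoverlap")
}

#' Overlapping complex extraction (propensity accumulation)
#'
#' For each column `c` of `F`, the column's effective module size is
#' \eqn{s_c = (F^T F)_{cc}} (for a binary membership matrix this is exactly
#' the member count).  The column's entries are ranked in descending order
#' (ties toward the lower node index) and accumulated until their running
#' sum first reaches \eqn{s_c}; the nodes contributing to that shortest
#' sufficient prefix form complex `c`.  A node can be selected by many
#' columns, so complexes may overlap.  All-zero columns yield no complex.
#'
#' @inheritParams assign_nonoverlapping
#' @return A [complex_cover()] with at most `ncol(F)` complexes (empty
#'   columns dropped; apply [filter_cover()] and [dedupe_cover()]
#'   downstream, as [predict.ssnmtf()] does).
#' @export
detect_overlapping <- function(F, nodes) {
  F <- as.matrix(F)
  stopifnot(nrow(F) == length(nodes), all(F >= 0))
  sizes <- colSums(F^2)                 # diag of F'F
  sets <- vector("list", ncol(F))
  for (c in seq_len(ncol(F))) {
    if (sizes[c] == 0) next
    ord <- order(-F[, c], seq_len(nrow(F)))   # descending, stable in node index
    len <- which(cumsum(F[ord, c]) >= sizes[c])[1]
    if (is.na(len)) len <- nrow(F)      # guard: cannot occur when sum f >= sum f^2
    sets[[c]] <- nodes[ord[seq_len(len)]]
  }
  complex_cover(sets[!vapply(sets, is.null, TRUE)], name = "overlap")
}
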