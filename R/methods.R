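#' @method print ssnmtf
#' @export
print.ssnmtf <- function(x, ...) {
  cat("Semi-supervised NMTF fit\n")
  cat(sprintf("  nodes: %d   module budget k: %d   alpha: %g\n",
              length(x$nodes), x$k, x$alpha))
  cat(sprintf("  objective: %.6g after %d iteration(s) (%s)\n",
              x$objective, x$iterations,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Summarize an SSNMTF fit
#'
#' Reports convergence, the objective decomposition, and the module
#' occupancy implied by the row-argmax assignment (empty modules are the
#' mechanism by which a generous `k` adapts down to the detected number of
#' complexes).
#'
#' @param object an `ssnmtf` fit.
#' @param ... unused.
#' @return An object of class `summary.ssnmtf`, printed as a short report.
#' @method summary ssnmtf
#' @export
summary.ssnmtf <- function(object, ...) {
  assign <- max.col(object$F, ties.method = "first")
  occ <- tabulate(assign, nbins = object$k)
  out <- list(fit = object, occupied = sum(occ > 0), sizes = occ[occ > 0],
              drop = object$trace[1] - object$objective)
  class(out) <- "summary.ssnmtf"
  out
}

#' @method print summary.ssnmtf
#' @export
print.summary.ssnmtf <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  objective decrease from start: %.6g\n", x$drop))
  cat(sprintf("  non-empty modules (row argmax): %d of %d budgeted\n",
              x$occupied, x$fit$k))
  cat("  occupied module sizes:\n")
  print(summary(x$sizes))
  invisible(x)
}

#' Extract fitted factors
#'
#' `coef()` returns the node-membership matrix `F` (the quantity detection
#' operates on) or the module-relationship matrix `G`.
#'
#' @param object an `ssnmtf` fit.
#' @param which `"F"` (default) or `"G"`.
#' @param ... unused.
#' @return The requested labeled matrix.
#' @export
coef.ssnmtf <- function(object, which = c("F", "G"), ...) {
  object[[match.arg(which)]]
}

#' @method fitted ssnmtf
#' @export
fitted.ssnmtf <- function(object, ...) {
  R <- object$F %*% object$G %*% t(object$F)
  dimnames(R) <- list(object$nodes, object$nodes)
  R
}

#' Residual adjacency of an SSNMTF fit
#'
#' @param object an `ssnmtf` fit.
#' @param net the `ppi_network` the model was fitted to (the fit stores
#'   only node labels, not the adjacency).
#' @param ... unused.
#' @return `net$adjacency - fitted(object)`.
#' @export
residuals.ssnmtf <- function(object, net, ...) {
  stopifnot(identical(net$nodes, object$nodes))
  net$adjacency - fitted(object)
}

#' Plot the objective trace of an SSNMTF fit
#'
#' @param x an `ssnmtf` fit.
#' @param log plot the objective on a log y-axis (default `TRUE`).
#' @param ... passed to [graphics::plot()].
#' @export
plot.ssnmtf <- function(x, log = TRUE, ...) {
  graphics::plot(seq_along(x$trace) - 1L, x$trace, type = "l",
                 log = if (log && all(x$trace > 0)) "y" else "",
                 xlab = "iteration", ylab = "objective J", ...)
  invisible(x)
}

#' Extract protein complexes from an SSNMTF fit
#'
#' The non-overlapping rule (`mode = "nonoverlap"`, the NSSNMTF method)
#' assigns each node to its row-argmax module; the overlapping rule
#' (`mode = "overlap"`, OSSNMTF) accumulates each column's largest
#' propensities until their sum reaches the column's effective module size
#' (see [detect_overlapping()]).  Complexes smaller than `min_size` are
#' filtered out and, in overlapping mode, exact duplicates are removed.
#'
#' @param object an `ssnmtf` fit.
#' @param mode `"nonoverlap"` or `"overlap"`.
#' @param min_size minimum complex size retained (default 3).
#' @param dedupe drop exact duplicate complexes (default `TRUE` in
#'   overlapping mode, ignored otherwise).
#' @param ... unused.
#' @return A [complex_cover()].
#' @export
predict.ssnmtf <- function(object, mode = c("nonoverlap", "overlap"),
                           min_size = 3, dedupe = TRUE, ...) {
  mode <- match.arg(mode)
  cover <- if (mode == "nonoverlap")
    assign_nonoverlapping(object$F, object$nodes)
  else
    detect_overlapping(object$F, object$nodes)
  if (mode == "overlap" && dedupe) cover <- dedupe_cover(cover)
  filter_cover(cover, min_size = min_size)
}
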