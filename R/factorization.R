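#' Fit the semi-supervised non-negative matrix tri-factorization model
#'
#' Approximates the adjacency matrix of an interaction network as
#' \eqn{A \approx F G F^T}, where \eqn{F \ge 0} (n x k) holds node-to-module
#' propensities and \eqn{G \ge 0} (k x k) the module-relationship structure.
#' Must-link prior knowledge enters through two graph-Laplacian penalties,
#' giving the objective
#' \deqn{J(F, G) = \|A - F G F^T\|_F^2 + Tr((FG)^T L (FG)) + Tr(F^T L F),}
#' with \eqn{L = D - M} the Laplacian of the must-link matrix \eqn{M}
#' (entries \eqn{\alpha} on constrained pairs).  The first penalty pulls the
#' reconstructed propensities \eqn{R = FG} of constrained pairs together
#' (sharpening the module structure in \eqn{G}); the second does the same
#' for the raw memberships in \eqn{F}.
#'
#' Optimization alternates the multiplicative updates
#' \deqn{F \leftarrow F \otimes \frac{2AFG + MF(GG + I)}{2FG(F^TF)G + DF(GG + I)}}
#' \deqn{G \leftarrow G \otimes \frac{F^TAF + GF^TMF}{(F^TF)G(F^TF) + GF^TDF}}
#' (Hadamard product and elementwise division), which preserve
#' non-negativity and drive the objective to a local minimum; iteration
#' stops when the relative objective change drops below `rel_tol` or after
#' `max_iter` sweeps.
#'
#' @param net a [ppi_network()].
#' @param constraints must-link prior: a [mustlink()] object, prebuilt
#'   [build_constraint_matrices()] output, or `NULL` for the unconstrained
#'   tri-factorization.
#' @param k module budget (number of columns of `F`).  Set generously —
#'   columns that win no node's argmax are empty modules and are pruned at
#'   detection time, so `k` is an upper bound, not a commitment.
#' @param alpha must-link weight; overrides the weight stored on a
#'   `mustlink` object.  Default 10, where detection performance peaks
#'   across interaction networks; `alpha = 0` recovers plain NMTF.
#' @param max_iter maximum update sweeps (default 1000).
#' @param rel_tol relative objective-change convergence tolerance.  Default
#'   `1e-9`; `paper_strict = TRUE` sets `1e-15`, below double-precision
#'   relative resolution, so `max_iter` then effectively governs.
#' @param init `"seeded"` (degree-and-separation seed heuristic, see
#'   [ssnmtf_init()]) or `"random"` (uniform(0,1) entries).
#' @param seed integer seed for the stochastic parts of initialization.
#' @param symmetrize_G logical; replace `G` by `(G + t(G))/2` after each
#'   update.  The multiplicative `G` update does not structurally preserve
#'   the symmetry the model declares for `G`; the default `FALSE` runs the
#'   update literally (which in practice recovers planted modules slightly
#'   better), `TRUE` re-symmetrizes after every sweep.
#' @param denom_floor elementwise floor applied to update denominators
#'   before division (default `1e-12`), the standard guard in
#'   multiplicative-update practice.
#' @param paper_strict logical shortcut setting `rel_tol = 1e-15`.
#' @return An object of class `ssnmtf`: list with `F`, `G` (labeled
#'   matrices), `objective` (final value), `trace` (objective per sweep,
#'   starting at the initial value), `iterations`, `converged`, `nodes`,
#'   `k`, `alpha`, and the matched `call`.
#' @seealso [predict.ssnmtf()] for extracting complexes,
#'   [ssnmtf_objective()], [ssnmtf_update_F()], [ssnmtf_update_G()].
#' @examples
#' sim <- planted_partition(3, 8, p_in = 0.9, p_out = 0.05, seed = 1)
#' ml <- mustlinks_from_truth(sim$truth, fraction = 0.2, seed = 1)
#' fit <- ssnmtf(sim$network, ml, k = 5, seed = 1)
#' predict(fit, min_size = 3)
#' @export
ssnmtf <- function(net, constraints = NULL, k, alpha = 10, max_iter = 1000,
                   rel_tol = 1e-9, init = c("seeded", "random"), seed = NULL,
                   symmetrize_G = FALSE, denom_floor = 1e-12,
                   paper_strict = FALSE) {
  stopifnot(inherits(net, "ppi_network"), k >= 2, max_iter >= 1,
            rel_tol > 0, denom_floor > 0, alpha >= 0)
  init <- match.arg(init)
  if (paper_strict) rel_tol <- 1e-15
  n <- length(net$nodes)
  if (k > n) stop("k (", k, ") exceeds the number of nodes (", n, ")")

  cm <- if (inherits(constraints, "mustlink_matrices")) constraints
        else if (inherits(constraints, "mustlink"))
          build_constraint_matrices(mustlink(constraints$pairs, alpha = max(alpha, .Machine$double.xmin)), net)
        else if (is.null(constraints)) build_constraint_matrices(NULL, net)
        else stop("constraints must be a mustlink / mustlink_matrices object or NULL")
  if (alpha == 0) cm <- build_constraint_matrices(NULL, net)

  A <- methods::as(methods::as(Matrix::Matrix(net$adjacency), "generalMatrix"),
                   "CsparseMatrix")
  fac <- ssnmtf_init(net, k, init = init, seed = seed)
  F_ <- fac$F; G_ <- fac$G
  normA2 <- sum(net$adjacency^2)

  J <- obj_terms(A, F_, G_, cm$L, normA2)
  trace <- numeric(max_iter + 1L); trace[1L] <- J
  t <- 0L; converged <- FALSE
  while (t < max_iter) {
    t <- t + 1L
    F_ <- mu_update_F(A, F_, G_, cm, denom_floor)
    G_ <- mu_update_G(A, F_, G_, cm, denom_floor, symmetrize_G)
    Jnew <- obj_terms(A, F_, G_, cm$L, normA2)
    if (!is.finite(Jnew))
      stop("objective became non-finite at iteration ", t)
    trace[t + 1L] <- Jnew
    if (J > 0 && abs(Jnew - J) / J < rel_tol) { converged <- TRUE; J <- Jnew; break }
    J <- Jnew
  }
  dimnames(F_) <- list(net$nodes, paste0("m", seq_len(k)))
  dimnames(G_) <- list(colnames(F_), colnames(F_))
  structure(list(F = F_, G = G_, objective = J, trace = trace[seq_len(t + 1L)],
                 iterations = t, converged = converged, nodes = net$nodes,
                 k = k, alpha = if (is.null(constraints)) 0 else alpha,
                 weighted = net$weighted, call = match.call()),
            class = "ssnmtf")
}

# objective J(F,G) without forming the dense n x n reconstruction:
# ||A-FGF'||^2 = ||A||^2 - 2<A, (FG)F'> + Tr((B'B)(F'F)),  B = FG,
# <A, BF'> = sum(B * (A F));  penalties via sparse L.
obj_terms <- function(A, F_, G_, L, normA2) {
  B <- F_ %*% G_
  FtF <- crossprod(F_)
  recon <- normA2 - 2 * sum(B * as.matrix(A %*% F_)) + sum(crossprod(B) * FtF)
  recon <- max(recon, 0)
  pen_r <- sum(B * as.matrix(L %*% B))
  pen_f <- sum(F_ * as.matrix(L %*% F_))
  recon + pen_r + pen_f
}

mu_update_F <- function(A, F_, G_, cm, denom_floor) {
  GGI <- G_ %*% G_ + diag(nrow(G_))
  num <- 2 * as.matrix(A %*% F_) %*% G_ + as.matrix(cm$M %*% F_) %*% GGI
  den <- 2 * F_ %*% (G_ %*% crossprod(F_) %*% G_) + as.matrix(cm$D %*% F_) %*% GGI
  ratio <- num / pmax(den, denom_floor)
  ratio[num == 0 & den == 0] <- 1   # 0/0: leave the entry unchanged
  F_ * ratio
}

mu_update_G <- function(A, F_, G_, cm, denom_floor, symmetrize_G) {
  FtF <- crossprod(F_)
  num <- crossprod(F_, as.matrix(A %*% F_)) + G_ %*% crossprod(F_, as.matrix(cm$M %*% F_))
  den <- FtF %*% G_ %*% FtF + G_ %*% crossprod(F_, as.matrix(cm$D %*% F_))
  ratio <- num / pmax(den, denom_floor)
  ratio[num == 0 & den == 0] <- 1
  G_ <- G_ * ratio
  if (symmetrize_G) G_ <- (G_ + t(G_)) / 2
  G_
}

#' Evaluate the SSNMTF objective
#'
#' Computes \eqn{J(F, G) = \|A - F G F^T\|_F^2 + Tr((FG)^T L (FG)) +
#' Tr(F^T L F)} for given factors and constraint matrices.  Each term is
#' non-negative when \eqn{L} is positive semi-definite; the reconstruction
#' term is clamped at zero against floating-point cancellation.
#'
#' @param net a `ppi_network`.
#' @param F,G non-negative factor matrices (n x k and k x k).
#' @param cm [build_constraint_matrices()] output (or `NULL` for no
#'   penalty).
#' @return The objective value, with the three terms as attribute
#'   `"terms"` (`recon`, `penalty_FG`, `penalty_F`).
#' @export
ssnmtf_objective <- function(net, F, G, cm = NULL) {
  n <- length(net$nodes)
  if (nrow(F) != n || ncol(F) != nrow(G) || nrow(G) != ncol(G))
    stop("factor shapes inconsistent with the network: F is ",
         nrow(F), "x", ncol(F), ", G is ", nrow(G), "x", ncol(G))
  if (is.null(cm)) cm <- build_constraint_matrices(NULL, net)
  A <- net$adjacency
  B <- F %*% G
  R <- B %*% t(F)
  recon <- max(sum((A - R)^2), 0)
  pen_r <- sum(B * as.matrix(cm$L %*% B))
  pen_f <- sum(F * as.matrix(cm$L %*% F))
  structure(recon + pen_r + pen_f,
            terms = c(recon = recon, penalty_FG = pen_r, penalty_F = pen_f))
}

#' One multiplicative update step
#'
#' Exposed for inspection and testing of the optimizer: applies a single
#' update of `F` (with `G` fixed) or of `G` (with `F` fixed), exactly as
#' used inside [ssnmtf()].  Non-negativity is preserved; denominators are
#' floored at `denom_floor`, and entries with a 0/0 factor are left
#' unchanged.
#'
#' @inheritParams ssnmtf_objective
#' @param denom_floor elementwise denominator floor.
#' @param symmetrize_G for the `G` step, symmetrize the result.
#' @return The updated `F` (resp. `G`) matrix.
#' @export
ssnmtf_update_F <- function(net, F, G, cm = NULL, denom_floor = 1e-12) {
  if (is.null(cm)) cm <- build_constraint_matrices(NULL, net)
  A <- methods::as(methods::as(Matrix::Matrix(net$adjacency), "generalMatrix"),
                   "CsparseMatrix")
  out <- mu_update_F(A, F, G, cm, denom_floor)
  if (any(!is.finite(out))) stop("non-finite entries after F update")
  out
}

#' @rdname ssnmtf_update_F
#' @export
ssnmtf_update_G <- function(net, F, G, cm = NULL, denom_floor = 1e-12,
                            symmetrize_G = FALSE) {
  if (is.null(cm)) cm <- build_constraint_matrices(NULL, net)
  A <- methods::as(methods::as(Matrix::Matrix(net$adjacency), "generalMatrix"),
                   "CsparseMatrix")
  out <- mu_update_G(A, F, G, cm, denom_floor, symmetrize_G)
  if (any(!is.finite(out))) stop("non-finite entries after G update")
  out
}

#' Initialize the SSNMTF factors
#'
#' `G` starts near the uninformative flat structure: every entry is
#' \eqn{1/k} plus a small uniform perturbation (breaking symmetry between
#' modules), then each row is rescaled to sum exactly to 1; all entries are
#' strictly positive.
#'
#' `F` in `"random"` mode is uniform(0,1) noise.  In `"seeded"` mode, `k`
#' seed nodes are chosen greedily: the highest-degree node first, then
#' repeatedly the highest-degree node at graph distance >= 2 from every
#' chosen seed (falling back to the highest-degree unchosen node when no
#' such node remains).  Each node's row is then `1 +` its adjacency weight
#' to each seed (seeds anchored to their own column with the maximum edge
#' weight), row-normalized, and floored at `1e-6` — multiplicative updates
#' cannot revive an exact zero, so every entry starts strictly positive.
#'
#' @param net a `ppi_network`.
#' @param k number of modules (2 <= k <= n).
#' @param init `"seeded"` or `"random"`.
#' @param seed integer seed; the same seed reproduces the factors exactly.
#' @return list with components `F` (n x k) and `G` (k x k).
#' @export
ssnmtf_init <- function(net, k, init = c("seeded", "random"), seed = NULL) {
  init <- match.arg(init)
  n <- length(net$nodes)
  stopifnot(k >= 2)
  if (k > n) stop("k (", k, ") exceeds the number of nodes (", n, ")")
  A <- net$adjacency
  with_seed(seed, {
    G <- matrix(1 / k + stats::runif(k * k, 0, 0.1 / k), k, k)
    G <- G / rowSums(G)
    F_ <- if (init == "random") {
      matrix(stats::runif(n * k), n, k)
    } else {
      deg <- rowSums(A)
      amax <- max(A, 1e-12)
      seeds <- integer(0)
      blocked <- rep(FALSE, n)          # seeds and their neighbors
      for (c in seq_len(k)) {
        cand <- which(!blocked)
        if (length(cand) == 0L) cand <- setdiff(seq_len(n), seeds)
        s <- cand[which.max(deg[cand])]
        seeds <- c(seeds, s)
        blocked <- blocked | seq_len(n) == s | A[, s] > 0
      }
      # similarity to each seed: direct edge weight plus shared-neighbor
      # weight (scaled by the mean degree); seeds anchor their own column
      S <- (A[, seeds, drop = FALSE] +
              (A %*% A[, seeds, drop = FALSE]) / max(mean(deg), 1)) / amax
      S[cbind(seeds, seq_len(k))] <- pmax(apply(S, 1, max)[seeds], 1) + 1
      F0 <- 1 + S
      F0 <- F0 / rowSums(F0)
      pmax(F0, 1e-6)
    }
    list(F = F_, G = G)
  })
}
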