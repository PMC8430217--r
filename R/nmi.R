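# Normalized mutual information, for hard partitions and overlapping covers.

# coerce a cover / factor / label vector to integer labels over `universe`;
# nodes uncovered by the cover become singleton blocks.
partition_labels <- function(x, universe) {
  if (inherits(x, "complex_cover")) {
    lab <- rep(NA_integer_, length(universe))
    names(lab) <- universe
    for (i in seq_along(x$complexes)) {
      mem <- intersect(x$complexes[[i]], universe)
      if (anyNA(lab[mem]))
        lab[mem[is.na(lab[mem])]] <- i
      else next
    }
    un <- which(is.na(lab))
    if (length(un)) lab[un] <- length(x$complexes) + seq_along(un)
    unname(lab)
  } else {
    if (length(x) != length(universe))
      stop("label vector length does not match the universe")
    as.integer(factor(x))
  }
}

#' Normalized mutual information between two partitions
#'
#' \eqn{NMI(A, B) = 2 I(A;B) / (H(A) + H(B))} over the label contingency
#' table.  Identical partitions (up to label permutation) score 1; when
#' either partition has zero entropy (a single block) and the partitions
#' differ, the score is defined as 0.
#'
#' @param a,b partitions of the same node universe: `complex_cover`s whose
#'   complexes are disjoint (uncovered nodes become singletons), or plain
#'   label vectors aligned with `universe`.
#' @param universe node labels; required when `a`/`b` are covers, inferred
#'   as `seq_along(a)` for label vectors.
#' @return A value in `[0, 1]`.
#' @export
nmi_partition <- function(a, b, universe = NULL) {
  if (is.null(universe)) {
    if (inherits(a, "complex_cover") || inherits(b, "complex_cover")) {
      universe <- unique(c(unlist(if (inherits(a, "complex_cover")) a$complexes),
                           unlist(if (inherits(b, "complex_cover")) b$complexes)))
    } else universe <- seq_along(a)
  }
  if (length(universe) == 0L) stop("empty node universe")
  la <- partition_labels(a, universe)
  lb <- partition_labels(b, universe)
  tab <- table(la, lb)
  n <- sum(tab)
  pa <- rowSums(tab) / n
  pb <- colSums(tab) / n
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  ha <- ent(pa); hb <- ent(pb)
  pj <- tab / n
  mi <- sum(ifelse(pj > 0, pj * log(pj / outer(pa, pb)), 0))
  if (ha + hb == 0) return(1)                       # both trivial => identical
  if (ha == 0 || hb == 0) return(if (mi > 0) 1 else 0)
  max(0, min(1, 2 * mi / (ha + hb)))
}

#' Normalized mutual information between two overlapping covers
#'
#' The overlapping-cover NMI of Lancichinetti, Fortunato and Kertesz: each
#' community is a binary node-membership variable, each community of one
#' cover is matched to the community of the other cover minimizing its
#' conditional entropy (subject to the standard admissibility constraint
#' \eqn{h(P_{11}) + h(P_{00}) \ge h(P_{01}) + h(P_{10})}), and
#' \deqn{NMI = 1 - \tfrac12\left[\langle H(X_k|Y)/H(X_k)\rangle_k +
#'       \langle H(Y_l|X)/H(Y_l)\rangle_l\right].}
#' Reduces to 1 for identical covers; communities with zero entropy
#' (covering every node or none) contribute 0 to the normalized average.
#'
#' @param a,b `complex_cover`s over the same node universe.
#' @param universe node labels; defaults to the union of all members.
#' @return A value in `[0, 1]`.
#' @export
nmi_cover <- function(a, b, universe = NULL) {
  stopifnot(inherits(a, "complex_cover"), inherits(b, "complex_cover"))
  if (is.null(universe))
    universe <- unique(c(unlist(a$complexes), unlist(b$complexes)))
  n <- length(universe)
  if (n == 0L) stop("empty node universe")
  X <- vapply(a$complexes, function(s) universe %in% s, logical(n))
  Y <- vapply(b$complexes, function(s) universe %in% s, logical(n))
  X <- matrix(X, nrow = n); Y <- matrix(Y, nrow = n)
  half <- function(X, Y) {
    # mean over columns k of X of H(Xk | Y) / H(Xk)
    h <- function(w) ifelse(w > 0, -w * log2(w), 0)
    hx <- h(colMeans(X)) + h(1 - colMeans(X))
    terms <- vapply(seq_len(ncol(X)), function(k) {
      if (hx[k] == 0) return(0)
      xk <- X[, k]
      best <- hx[k]
      for (l in seq_len(ncol(Y))) {
        yl <- Y[, l]
        p11 <- mean(xk & yl);  p10 <- mean(xk & !yl)
        p01 <- mean(!xk & yl); p00 <- mean(!xk & !yl)
        if (h(p11) + h(p00) < h(p01) + h(p10)) next   # inadmissible match
        hy <- h(mean(yl)) + h(1 - mean(yl))
        cond <- h(p11) + h(p10) + h(p01) + h(p00) - hy
        if (cond < best) best <- cond
      }
      best / hx[k]
    }, 0)
    mean(terms)
  }
  max(0, min(1, 1 - (half(X, Y) + half(Y, X)) / 2))
}
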