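#' Neighborhood affinity between two node sets
#'
#' \deqn{NA(p, g) = \frac{|p \cap g|^2}{|p|\,|g|}} — the squared
#' intersection over the size product, the standard overlap score for
#' matching a predicted complex against a reference one (conventional match
#' threshold 0.25).  Symmetric; equals 1 iff the sets are equal.
#'
#' @param p,g non-empty character vectors (treated as sets).
#' @return A value in `[0, 1]`.
#' @export
neighborhood_affinity <- function(p, g) {
  p <- unique(p); g <- unique(g)
  if (length(p) == 0L || length(g) == 0L) stop("sets must be non-empty")
  length(intersect(p, g))^2 / (length(p) * length(g))
}

# all pairwise NA scores: rows = pred, cols = ref
na_matrix <- function(pred, ref) {
  outer(seq_along(pred$complexes), seq_along(ref$complexes),
        Vectorize(function(i, j)
          neighborhood_affinity(pred$complexes[[i]], ref$complexes[[j]])))
}

#' Complex-level precision, recall and F1
#'
#' A reference complex counts as recovered when at least one prediction
#' overlaps it with score >= `threshold`; a predicted complex counts as
#' correct when it overlaps at least one reference that well.  Then
#' precision = correct predictions / all predictions, recall = recovered
#' references / all references, and F1 is their harmonic mean (0 when both
#' rates are 0).  The overlap score is [neighborhood_affinity()]; the
#' conventional threshold for this family of rates is 0.2.
#'
#' @param pred,ref non-empty `complex_cover`s (predicted / gold standard).
#' @param threshold overlap-score threshold (default 0.2).
#' @return Named numeric vector `c(precision, recall, f1)`.
#' @export
precision_recall_f1 <- function(pred, ref, threshold = 0.2) {
  check_covers(pred, ref)
  na <- na_matrix(pred, ref)
  n_cp <- sum(apply(na, 1, max) >= threshold)   # matched predictions
  n_cb <- sum(apply(na, 2, max) >= threshold)   # recovered references
  precision <- n_cp / length(pred$complexes)
  recall <- n_cb / length(ref$complexes)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Cluster-wise sensitivity, positive predictive value and accuracy
#'
#' With \eqn{t_{ij}} the number of shared proteins between prediction
#' \eqn{i} and reference \eqn{j}:
#' \deqn{Sn = \frac{\sum_j \max_i t_{ij}}{\sum_j N_j},\qquad
#'       PPV = \frac{\sum_i \max_j t_{ij}}{\sum_i \sum_j t_{ij}},\qquad
#'       Acc = \sqrt{Sn \times PPV}.}
#' Sn measures how well reference members are covered by their best
#' prediction, PPV how concentrated each prediction is on a single
#' reference, and Acc is their geometric mean.  PPV is defined as 0 when no
#' prediction intersects any reference.
#'
#' @inheritParams precision_recall_f1
#' @return Named numeric vector `c(sn, ppv, acc)`.
#' @export
sn_ppv_acc <- function(pred, ref) {
  check_covers(pred, ref)
  t_ij <- outer(seq_along(pred$complexes), seq_along(ref$complexes),
                Vectorize(function(i, j)
                  length(intersect(pred$complexes[[i]], ref$complexes[[j]]))))
  sn <- sum(apply(t_ij, 2, max)) / sum(lengths(ref$complexes))
  tot <- sum(t_ij)
  ppv <- if (tot == 0) 0 else sum(apply(t_ij, 1, max)) / tot
  c(sn = sn, ppv = ppv, acc = sqrt(sn * ppv))
}

#' Maximum matching ratio
#'
#' Default mode averages, over the reference complexes, each one's best
#' neighborhood-affinity score against any prediction — the formula as
#' conventionally printed.  `strict = TRUE` instead solves the true
#' maximum-weight one-to-one bipartite matching between predictions and
#' references (via [igraph::max_bipartite_match()]) and divides the total
#' matched affinity by the number of reference complexes; reusing one
#' prediction for several references is then disallowed, so the strict
#' value never exceeds the default one.
#'
#' @inheritParams precision_recall_f1
#' @param strict use the one-to-one matching variant.
#' @return A value in `[0, 1]`.
#' @export
mmr <- function(pred, ref, strict = FALSE) {
  check_covers(pred, ref)
  na <- na_matrix(pred, ref)
  if (!strict) return(mean(apply(na, 2, max)))
  np <- nrow(na); ng <- ncol(na)
  idx <- which(na > 0, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(0)
  g <- igraph::graph_from_data_frame(
    data.frame(from = paste0("p", idx[, 1]), to = paste0("g", np + idx[, 2]),
               weight = na[idx]),
    directed = FALSE)
  igraph::V(g)$type <- startsWith(igraph::V(g)$name, "g")
  m <- igraph::max_bipartite_match(g, weights = igraph::E(g)$weight)
  m$matching_weight / ng
}

#' Count matched predicted complexes
#'
#' Number of predicted complexes whose best neighborhood affinity against
#' the reference catalog reaches `threshold` (default 0.25, the
#' conventional match level).
#'
#' @inheritParams precision_recall_f1
#' @param threshold affinity threshold.
#' @return Integer count.
#' @export
count_matched <- function(pred, ref, threshold = 0.25) {
  check_covers(pred, ref)
  sum(apply(na_matrix(pred, ref), 1, max) >= threshold)
}

#' Full evaluation report for a predicted cover
#'
#' Convenience wrapper computing every complex-level statistic at once.
#'
#' @inheritParams precision_recall_f1
#' @param na_threshold match threshold for the matched-complex count
#'   (default 0.25).
#' @param ol_threshold overlap threshold for precision/recall/F1 (default
#'   0.2).
#' @return A one-row data.frame with columns `n_predicted`, `n_matched`,
#'   `precision`, `recall`, `f1`, `sn`, `ppv`, `acc`, `mmr`.
#' @export
evaluate_cover <- function(pred, ref, na_threshold = 0.25, ol_threshold = 0.2) {
  prf <- precision_recall_f1(pred, ref, threshold = ol_threshold)
  spa <- sn_ppv_acc(pred, ref)
  data.frame(n_predicted = length(pred$complexes),
             n_matched = count_matched(pred, ref, threshold = na_threshold),
             precision = prf[["precision"]], recall = prf[["recall"]],
             f1 = prf[["f1"]], sn = spa[["sn"]], ppv = spa[["ppv"]],
             acc = spa[["acc"]], mmr = mmr(pred, ref))
}

check_covers <- function(pred, ref) {
  stopifnot(inherits(pred, "complex_cover"), inherits(ref, "complex_cover"))
  if (length(pred$complexes) == 0L || length(ref$complexes) == 0L)
    stop("both covers must contain at least one complex")
  invisible(NULL)
}

#' Hypergeometric enrichment p-value
#'
#' Upper-tail probability that a complex of size `k_c`, drawn from a
#' background of `t` proteins of which `f` carry an annotation, contains
#' `q` or more annotated members:
#' \deqn{p = \sum_{x=q}^{f} \frac{\binom{f}{x}\binom{t-f}{k_c-x}}{\binom{t}{k_c}}.}
#' Evaluated through the hypergeometric distribution function
#' ([stats::phyper()]), which works in log space internally; smaller values
#' indicate stronger functional enrichment.
#'
#' @param t background (network) protein count.
#' @param k_c complex size.
#' @param f annotated proteins in the background.
#' @param q annotated proteins inside the complex.
#' @return p-value in `(0, 1]`; `q = 0` gives exactly 1.
#' @export
hypergeom_pvalue <- function(t, k_c, f, q) {
  stopifnot(q >= 0, q <= min(k_c, f), f <= t, k_c <= t)
  stats::phyper(q - 1, m = f, n = t - f, k = k_c, lower.tail = FALSE)
}

#' Proportion of enriched complexes per p-value threshold
#'
#' For each threshold, the fraction of complexes with p-value strictly
#' below it, plus the fraction falling in each interval between successive
#' thresholds.  Thresholds are sorted ascending.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @param thresholds numeric vector of thresholds, e.g.
#'   `10^seq(-10, -2)`.
#' @return data.frame with `threshold`, `cumulative` (fraction below), and
#'   `interval` (fraction in `[previous, threshold)`, first interval
#'   starting at 0).
#' @export
enrichment_proportions <- function(pvalues, thresholds) {
  stopifnot(all(pvalues >= 0 & pvalues <= 1))
  thresholds <- sort(unique(thresholds))
  cum <- vapply(thresholds, function(th) mean(pvalues < th), 0)
  data.frame(threshold = thresholds, cumulative = cum,
             interval = diff(c(0, cum)))
}
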