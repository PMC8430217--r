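# Independent dense oracles, transcribed directly from the model's printed
# formulas and kept free of any package internals, so that each test checks
# the implementation against a second, separate derivation.

# objective via the explicit pairwise-sum form of the Laplacian penalties:
# ||A - FGF'||^2 + 1/2 sum_ij m_ij ||(FG)_i - (FG)_j||^2
#                + 1/2 sum_ij m_ij ||f_i - f_j||^2
oracle_objective <- function(A, F, G, M) {
  R <- F %*% G
  J <- sum((A - R %*% t(F))^2)
  n <- nrow(A)
  for (i in seq_len(n)) for (j in seq_len(n)) if (M[i, j] != 0) {
    J <- J + 0.5 * M[i, j] * sum((R[i, ] - R[j, ])^2)
    J <- J + 0.5 * M[i, j] * sum((F[i, ] - F[j, ])^2)
  }
  J
}

# one multiplicative F step:  F * [2AFG + MF(GG+I)] / [2FGF'FG + DF(GG+I)]
oracle_update_F <- function(A, F, G, M) {
  D <- diag(rowSums(M))
  I <- diag(ncol(G))
  num <- 2 * A %*% F %*% G + M %*% F %*% (G %*% G + I)
  den <- 2 * F %*% G %*% t(F) %*% F %*% G + D %*% F %*% (G %*% G + I)
  F * (num / den)
}

# one multiplicative G step:  G * [F'AF + GF'MF] / [F'FGF'F + GF'DF]
oracle_update_G <- function(A, F, G, M) {
  D <- diag(rowSums(M))
  num <- t(F) %*% A %*% F + G %*% t(F) %*% M %*% F
  den <- t(F) %*% F %*% G %*% t(F) %*% F + G %*% t(F) %*% D %*% F
  G * (num / den)
}

# gradients with the multipliers dropped (KKT stationarity check)
oracle_grad_F <- function(A, F, G, L) {
  2 * F %*% G %*% t(F) %*% F %*% G - 2 * A %*% F %*% G +
    L %*% F %*% G %*% G + L %*% F
}
oracle_grad_G <- function(A, F, G, L) {
  t(F) %*% F %*% G %*% t(F) %*% F - t(F) %*% A %*% F + G %*% t(F) %*% L %*% F
}

# random strictly positive test instance on n nodes, k modules,
# with a symmetric zero-diagonal A and a valid must-link matrix M
random_instance <- function(n, k, n_pairs = 2, alpha = 3, seed = 1) {
  set.seed(seed)
  A <- matrix(runif(n * n), n)
  A <- (A + t(A)) / 2; diag(A) <- 0
  F <- matrix(runif(n * k, 0.1, 1), n, k)
  G <- matrix(runif(k * k, 0.1, 1), k, k)
  M <- matrix(0, n, n)
  if (n_pairs > 0) {
    pr <- replicate(n_pairs, sample(n, 2))
    for (q in seq_len(ncol(pr))) {
      M[pr[1, q], pr[2, q]] <- alpha; M[pr[2, q], pr[1, q]] <- alpha
    }
  }
  nodes <- paste0("n", seq_len(n))
  dimnames(A) <- list(nodes, nodes)
  net <- ppi_network(nodes, A, weighted = TRUE)
  ml <- if (n_pairs > 0)
    mustlink(cbind(nodes[pr[1, ]], nodes[pr[2, ]]), alpha = alpha) else NULL
  cm <- build_constraint_matrices(ml, net)
  list(net = net, A = A, F = F, G = G, M = M, cm = cm, nodes = nodes)
}

# exhaustive maximum-weight one-to-one assignment over a small score matrix
oracle_best_matching <- function(S) {
  np <- nrow(S); ng <- ncol(S)
  if (np <= ng) {
    perms <- combinat_perms(ng, np)
    best <- 0
    for (p in perms) best <- max(best, sum(S[cbind(seq_len(np), p)]))
  } else {
    perms <- combinat_perms(np, ng)
    best <- 0
    for (p in perms) best <- max(best, sum(S[cbind(p, seq_len(ng))]))
  }
  best
}
combinat_perms <- function(n, r) {
  # all ordered selections of r items from 1..n
  if (r == 0) return(list(integer(0)))
  out <- list()
  for (i in seq_len(n)) {
    for (rest in combinat_perms(n, r - 1)) {
      if (!(i %in% rest)) out[[length(out) + 1L]] <- c(i, rest)
    }
  }
  out
}
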