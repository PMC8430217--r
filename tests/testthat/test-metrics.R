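test_that("neighborhood affinity matches hand arithmetic and is symmetric", {
  expect_equal(neighborhood_affinity(c("a", "b"), c("a", "b")), 1)
  expect_equal(neighborhood_affinity(c("a", "b"), c("a", "b", "c", "d")), 0.5)
  expect_equal(neighborhood_affinity(c("a"), c("b")), 0)
  expect_error(neighborhood_affinity(character(0), "a"), "non-empty")
  # symmetry and the =1 iff equal property on random sets
  set.seed(3)
  univ <- paste0("p", 1:12)
  for (r in 1:10) {
    p <- sample(univ, sample(2:6, 1)); g <- sample(univ, sample(2:6, 1))
    expect_equal(neighborhood_affinity(p, g), neighborhood_affinity(g, p))
    if (neighborhood_affinity(p, g) == 1) expect_setequal(p, g)
  }
})

test_that("precision/recall/F1 follow the matched-complex definitions", {
  cov <- complex_cover(list(c("a", "b", "c"), c("d", "e", "f", "g")))
  expect_equal(unname(precision_recall_f1(cov, cov)), c(1, 1, 1))

  pred <- complex_cover(list(c("a", "b", "c"), c("x", "y", "z")))
  ref <- complex_cover(list(c("a", "b", "c"), c("q", "r", "s")))
  expect_equal(unname(precision_recall_f1(pred, ref)), c(0.5, 0.5, 0.5))

  # at threshold 1 nothing strictly smaller matches; F1 defined as 0 at 0/0
  pred2 <- complex_cover(list(c("a", "b")))
  ref2 <- complex_cover(list(c("a", "b", "c")))
  expect_equal(unname(precision_recall_f1(pred2, ref2, threshold = 1)),
               c(0, 0, 0))

  # swapping pred and ref swaps precision and recall
  p3 <- complex_cover(list(c("a", "b", "c"), c("d", "e"), c("x", "y")))
  r3 <- complex_cover(list(c("a", "b"), c("d", "e", "q")))
  f <- precision_recall_f1(p3, r3); b <- precision_recall_f1(r3, p3)
  expect_equal(f[["precision"]], b[["recall"]])
  expect_equal(f[["recall"]], b[["precision"]])
  expect_error(precision_recall_f1(complex_cover(list()), ref), "at least one")
})

test_that("Sn/PPV follow the intersection-table definitions with Acc their geometric mean", {
  ref <- complex_cover(list(c("a", "b"), c("c", "d")))
  expect_equal(unname(sn_ppv_acc(ref, ref)), c(1, 1, 1))

  pred <- complex_cover(list(c("a", "b", "c", "d")))
  got <- sn_ppv_acc(pred, ref)
  expect_equal(unname(got), c(1, 0.5, sqrt(0.5)))

  disj <- complex_cover(list(c("x", "y")))
  expect_equal(unname(sn_ppv_acc(disj, ref)), c(0, 0, 0))

  # acc identity on random covers
  set.seed(4)
  univ <- paste0("p", 1:15)
  for (r in 1:8) {
    p <- complex_cover(replicate(3, sample(univ, sample(2:5, 1)), simplify = FALSE))
    g <- complex_cover(replicate(2, sample(univ, sample(2:5, 1)), simplify = FALSE))
    v <- sn_ppv_acc(p, g)
    expect_equal(v[["acc"]], sqrt(v[["sn"]] * v[["ppv"]]))
    expect_true(all(v >= 0 & v <= 1))
  }
})

test_that("maximum matching ratio: printed best-match average and strict one-to-one mode", {
  cov <- complex_cover(list(c("a", "b", "c"), c("d", "e", "f")))
  expect_equal(mmr(cov, cov), 1)
  expect_equal(mmr(cov, cov, strict = TRUE), 1)

  pred <- complex_cover(list(c("a", "b", "c")))
  ref <- complex_cover(list(c("a", "b", "c"), c("d", "e", "f")))
  expect_equal(mmr(pred, ref), 0.5)

  # strict mode never exceeds the printed-formula value; both match the
  # exhaustive-assignment oracle on small instances
  set.seed(8)
  univ <- paste0("p", 1:14)
  for (r in 1:6) {
    p <- complex_cover(replicate(sample(2:4, 1), sample(univ, sample(2:4, 1)),
                                 simplify = FALSE))
    g <- complex_cover(replicate(sample(2:4, 1), sample(univ, sample(2:4, 1)),
                                 simplify = FALSE))
    S <- outer(seq_along(p$complexes), seq_along(g$complexes),
               Vectorize(function(i, j)
                 neighborhood_affinity(p$complexes[[i]], g$complexes[[j]])))
    strict <- mmr(p, g, strict = TRUE)
    expect_lte(strict, mmr(p, g) + 1e-12)
    expect_equal(strict, oracle_best_matching(S) / length(g$complexes),
                 tolerance = 1e-10)
  }

  # two predictions both best-matching one reference: strict <= printed
  p2 <- complex_cover(list(c("a", "b", "c"), c("a", "b", "d")))
  r2 <- complex_cover(list(c("a", "b", "c"), c("x", "y", "z")))
  expect_lte(mmr(p2, r2, strict = TRUE), mmr(p2, r2))
})

test_that("matched-complex counting uses the 0.25 affinity convention", {
  cov <- complex_cover(list(c("a", "b", "c"), c("d", "e")))
  expect_equal(count_matched(cov, cov), 2)
  expect_equal(count_matched(complex_cover(list(c("x", "y"))), cov), 0)
  # NA = 4/8 = 0.5 >= 0.25
  expect_equal(count_matched(complex_cover(list(c("a", "b"))),
                             complex_cover(list(c("a", "b", "c", "d")))), 1)
})

test_that("hypergeometric p-values equal direct combinatorial sums", {
  expect_equal(hypergeom_pvalue(t = 10, k_c = 3, f = 4, q = 0), 1)
  expect_equal(hypergeom_pvalue(t = 5, k_c = 2, f = 2, q = 2),
               choose(2, 2) * choose(3, 0) / choose(5, 2))

  direct <- function(t, k, f, q) {
    x <- q:f
    sum(choose(f, x) * choose(t - f, k - x)) / choose(t, k)
  }
  expect_equal(hypergeom_pvalue(100, 10, 10, 10), direct(100, 10, 10, 10),
               tolerance = 1e-12)
  for (q in 0:5)
    expect_equal(hypergeom_pvalue(40, 8, 12, q), direct(40, 8, 12, q),
                 tolerance = 1e-12)
  # monotone non-increasing in q
  ps <- sapply(0:8, function(q) hypergeom_pvalue(60, 8, 20, q))
  expect_true(all(diff(ps) <= 0))
  expect_error(hypergeom_pvalue(10, 3, 2, 3), "q")
})

test_that("enrichment proportions bin p-values against sorted thresholds", {
  out <- enrichment_proportions(rep(1, 4), c(1e-10, 0.01))
  expect_equal(out$cumulative, c(0, 0))

  out <- enrichment_proportions(c(1e-12, 1e-5, 0.5), c(0.01, 1e-10))
  expect_equal(out$threshold, c(1e-10, 0.01))      # canonicalized order
  expect_equal(out$cumulative, c(1 / 3, 2 / 3))
  expect_equal(out$interval, c(1 / 3, 1 / 3))
})

test_that("the combined evaluation report is internally consistent", {
  sim <- planted_partition(3, 6, 0.9, 0.05, seed = 12)
  rep1 <- evaluate_cover(sim$truth, sim$truth)
  expect_equal(rep1$precision, 1)
  expect_equal(rep1$acc, 1)
  expect_equal(rep1$n_matched, 3)
  expect_equal(rep1$acc^2, rep1$sn * rep1$ppv, tolerance = 1e-12)
})
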