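test_that("the paired t-map matches hand computation and degenerates safely", {
  A <- matrix(c(1, 2, 3, 4, 5, 5, 5, 5), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  B <- matrix(c(0, 0, 0, 0, 4, 4, 4, 4), ncol = 2,
              dimnames = list(NULL, c("a", "b")))
  expect_warning(t <- paired_t_map(A, B), "zero difference variance")
  # d = (1,2,3,4): mean 2.5, sd 1.2910, t = 3.873
  expect_equal(unname(t["a"]), 3.872983, tolerance = 1e-6)
  expect_equal(unname(t["b"]), 0)  # constant differences -> degenerate
  expect_equal(unname(suppressWarnings(paired_t_map(A, A))), c(0, 0))
})

test_that("exact enumeration counts match the paired design arithmetic", {
  g <- path_graph(c("a", "b", "c"))
  for (n in c(8, 10)) {
    set.seed(n)
    A <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, g$nodes))
    B <- matrix(rnorm(3 * n), n, 3, dimnames = list(NULL, g$nodes))
    ct <- cluster_permutation_test(A, B, g)
    expect_equal(ct$scheme, "exact")
    expect_equal(ct$n_permutations, 2^n)
  }
})

test_that("cluster permutation p-values equal the brute-force enumerator", {
  g <- path_graph(c("e1", "e2", "e3"))
  set.seed(17)
  for (rep_i in 1:5) {
    # integer paired data with a planted offset so clusters actually form
    A <- matrix(sample(0:6, 15, replace = TRUE) +
                  rep(c(3, 3, 0), each = 5), 5, 3,
                dimnames = list(NULL, g$nodes))
    B <- matrix(sample(0:6, 15, replace = TRUE), 5, 3,
                dimnames = list(NULL, g$nodes))
    ct <- cluster_permutation_test(A, B, g)
    oracle <- brute_cluster_oracle(A, B, g$adjacency)
    expect_equal(length(ct$clusters), length(oracle$clusters))
    if (length(ct$clusters) > 0) {
      impl <- ct$clusters[order(vapply(ct$clusters, `[[`, numeric(1),
                                       "mass"))]
      orac <- oracle$clusters[order(vapply(oracle$clusters, `[[`,
                                           numeric(1), "mass"))]
      for (k in seq_along(impl)) {
        expect_identical(sort(impl[[k]]$members), sort(orac[[k]]$members))
        expect_equal(impl[[k]]$mass, orac[[k]]$mass)
        expect_equal(impl[[k]]$p_value, orac[[k]]$p, tolerance = 1e-12)
      }
    }
  }
})

test_that("permutation p-values respect the exact-test symmetries", {
  g <- path_graph(c("e1", "e2", "e3", "e4"))
  set.seed(23)
  A <- matrix(rnorm(24, mean = 1), 6, 4, dimnames = list(NULL, g$nodes))
  B <- matrix(rnorm(24), 6, 4, dimnames = list(NULL, g$nodes))
  ct <- cluster_permutation_test(A, B, g)
  ps <- vapply(ct$clusters, `[[`, numeric(1), "p_value")
  # invariant to subject reordering
  perm <- sample(6)
  ct_r <- cluster_permutation_test(A[perm, ], B[perm, ], g)
  expect_equal(sort(vapply(ct_r$clusters, `[[`, numeric(1), "p_value")),
               sort(ps))
  # two-sided symmetry: swapping the sessions flips polarity, not p
  ct_s <- cluster_permutation_test(B, A, g)
  expect_equal(sort(vapply(ct_s$clusters, `[[`, numeric(1), "p_value")),
               sort(ps))
  expect_equal(sort(-vapply(ct_s$clusters, `[[`, numeric(1), "mass")),
               sort(vapply(ct$clusters, `[[`, numeric(1), "mass")))
  # p bounded below by 1 / n_permutations
  expect_true(all(ps >= 1 / ct$n_permutations))
})

test_that("the Monte-Carlo scheme approximates the exact scheme", {
  g <- path_graph(c("e1", "e2", "e3"))
  set.seed(29)
  A <- matrix(rnorm(15, mean = 1.2), 5, 3, dimnames = list(NULL, g$nodes))
  B <- matrix(rnorm(15), 5, 3, dimnames = list(NULL, g$nodes))
  exact <- cluster_permutation_test(A, B, g)
  mc <- cluster_permutation_test(A, B, g, max_exact_n = 2,
                                 monte_carlo = TRUE, n_draws = 4000,
                                 seed = 7)
  expect_equal(mc$scheme, "monte_carlo")
  expect_equal(mc$n_permutations, 4001)
  if (length(exact$clusters) > 0) {
    expect_equal(mc$clusters[[1]]$p_value, exact$clusters[[1]]$p_value,
                 tolerance = 0.05)
  }
  expect_error(cluster_permutation_test(A, B, g, max_exact_n = 2),
               "Monte-Carlo")
})

test_that("frequency expansion wires spectral and spatial adjacency", {
  g <- path_graph(c("e1", "e2"))
  gf <- expand_graph_frequency(g, c(10, 11, 12))
  expect_length(gf$nodes, 6)
  expect_true("e2@10" %in% gf$adjacency[["e1@10"]])
  expect_true("e1@11" %in% gf$adjacency[["e1@10"]])
  expect_false("e1@12" %in% gf$adjacency[["e1@10"]])
  expect_false("e2@11" %in% gf$adjacency[["e1@10"]])
})

test_that("Wilcoxon signed-rank handles the canonical cases", {
  x <- c(3, 1, 4, 1, 5)
  expect_warning(res0 <- wilcoxon_signed_rank(x, x), "all differences zero")
  expect_equal(res0$p, 1)
  expect_equal(res0$z, 0)

  res <- wilcoxon_signed_rank(c(2, 4, 7, 11, 16), c(1, 2, 4, 7, 11))
  expect_true(res$exact)
  expect_equal(res$p, 2 / 32)
  expect_equal(res$statistic, 15)
})

test_that("exact Wilcoxon p matches full enumeration for n = 12", {
  set.seed(31)
  for (i in 1:4) {
    x <- rnorm(12, 1, 2)
    y <- rnorm(12, 0, 2)
    res <- wilcoxon_signed_rank(x, y)
    expect_true(res$exact)
    expect_equal(res$p, brute_signrank_p(x, y), tolerance = 1e-9)
  }
})

test_that("the exact signed-rank distribution sums to one", {
  for (n in c(5, 8, 12)) {
    probs <- qeegpipe:::.signrank_distribution(1:n)
    expect_equal(sum(probs), 1, tolerance = 1e-12)
    expect_true(all(probs >= 0))
  }
})

test_that("ties fall back to the corrected normal approximation", {
  x <- c(5, 6, 7, 8, 9, 12)
  y <- c(1, 2, 3, 4, 5, 6)  # |d| has ties
  res <- wilcoxon_signed_rank(x, y)
  expect_false(res$exact)
  expect_true(res$p > 0 && res$p <= 1)
})

test_that("effect size follows the two-occasion convention", {
  expect_lt(abs(effect_size_r(3.06, 12) - 0.62), 0.005)
  expect_lt(abs(effect_size_r(-1.38, 12) - (-0.28)), 0.005)
  expect_equal(effect_size_r(0, 10), 0)
})

test_that("Benjamini-Hochberg matches the step-up hand evaluation", {
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  set.seed(37)
  p <- runif(20)
  adj <- benjamini_hochberg(p)
  expect_true(all(diff(adj[order(p)]) >= -1e-12))
  expect_true(all(adj >= p - 1e-12))
  expect_error(benjamini_hochberg(c(0.1, 1.2)), "\\[0, 1\\]")
})
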