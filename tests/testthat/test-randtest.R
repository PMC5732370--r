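fake_result <- function(lambda_pos, lambda_neg) {
  structure(list(lambda_pos = lambda_pos, lambda_neg = lambda_neg),
            class = "spca_result")
}

test_that("cumulative statistics sum the requested eigenvalue prefix", {
  res <- fake_result(c(3, 2, 1), c(-4, -1))
  expect_equal(cumulative_statistics(res, j_pos = 2, j_neg = "all"),
               list(f_pos = 5, f_neg = 5))
  expect_equal(cumulative_statistics(res, j_pos = 1, j_neg = 1),
               list(f_pos = 3, f_neg = 4))
  expect_equal(cumulative_statistics(res)$f_pos, 6)
  expect_error(cumulative_statistics(res, j_pos = 4), "j_pos")
})

test_that("empirical p-values follow the plus-one convention with ties", {
  expect_equal(empirical_pvalue(100, seq_len(99)), 1 / 100)
  expect_equal(empirical_pvalue(1, seq_len(99)), 1)     # obs equals the minimum
  null <- c(rep(5, 4), rep(1, 15))                      # 4 ties of 19
  expect_equal(empirical_pvalue(5, null), 5 / 20)
  expect_error(empirical_pvalue(1, numeric()), "empty")
})

test_that("the Bonferroni cascade reproduces the worked decision sequence", {
  # per-rank thresholds 0.05, 0.025, 0.0167, 0.0125
  expect_equal(bonferroni_cascade(c(0.0105, 0.0137, 0.0136, 0.506), 0.05), 3L)
  expect_equal(bonferroni_cascade(c(0.2, 0.001, 0.001), 0.05), 0L)
  expect_equal(bonferroni_cascade(c(0.04, 0.03), 0.05), 1L)
  # ties at the threshold are non-significant (strict inequality)
  expect_equal(bonferroni_cascade(c(0.05, 0.01), 0.05), 0L)
})

test_that("cascade counts never decrease when alpha increases", {
  set.seed(99)
  for (i in 1:100) {
    pv <- runif(sample(1:8, 1))
    alphas <- sort(runif(2, 0.01, 0.5))
    expect_lte(bonferroni_cascade(pv, alphas[1]), bonferroni_cascade(pv, alphas[2]))
  }
})

test_that("joint relabelling of X and L leaves the recorded spectrum fixed", {
  td <- make_test_data(n = 14, p = 10, seed = 21)
  res <- spca(td$X, td$W)
  set.seed(4)
  perm <- sample(14)
  res_p <- spca(td$X$X[perm, ], td$W$L[perm, perm])
  expect_equal(res_p$lambda_pos, res$lambda_pos, tolerance = 1e-9)
  expect_equal(res_p$lambda_neg, res$lambda_neg, tolerance = 1e-9)
})

test_that("a fixed seed makes the whole test bit-reproducible", {
  td <- make_test_data(n = 12, p = 6, seed = 77)
  r1 <- suppressWarnings(spca_randtest(td$X, td$W, B = 49, seed = 123))
  r2 <- suppressWarnings(spca_randtest(td$X, td$W, B = 49, seed = 123))
  expect_identical(r1$nulls$f_pos_null, r2$nulls$f_pos_null)
  expect_identical(r1$p_global, r2$p_global)
  expect_identical(r1$eig_pvalues_neg, r2$eig_pvalues_neg)
})

test_that("Monte-Carlo p-values agree with exhaustive enumeration at n = 5", {
  set.seed(31)
  X <- centre_frequencies(matrix(runif(15), 5, 3))
  W <- knn_graph(matrix(runif(10), 5, 2), k = 2)
  obs <- spca(X, W)
  f_obs <- cumulative_statistics(obs)$f_pos
  perms <- all_permutations(5)
  f_all <- vapply(perms, function(p) {
    cumulative_statistics(spca(X$X[p, , drop = FALSE], W))$f_pos
  }, numeric(1))
  p_exact <- mean(f_all >= f_obs)  # identity permutation included
  B <- 10000L
  nulls <- suppressWarnings(permutation_null(X, W, B = B, seed = 2024))
  p_mc <- empirical_pvalue(f_obs, nulls$f_pos_null)
  se <- sqrt(p_exact * (1 - p_exact) / B)
  expect_lt(abs(p_mc - p_exact), 3 * se + 2 / (B + 1))
})

test_that("step 2 is gated on step-1 significance but p-values are reported", {
  td <- make_test_data(n = 15, p = 8, seed = 5)
  rt <- suppressWarnings(spca_randtest(td$X, td$W, B = 99, seed = 6))
  expect_true(rt$p_global >= 1 / 100 && rt$p_global <= 1)
  expect_true(rt$p_local >= 1 / 100 && rt$p_local <= 1)
  expect_length(rt$eig_pvalues_pos, length(rt$spca$lambda_pos))
  if (rt$p_global >= rt$alpha) expect_identical(rt$n_sig_pos, 0L)
  if (rt$p_local >= rt$alpha) expect_identical(rt$n_sig_neg, 0L)
  expect_equal(rt$thresholds_pos,
               rt$alpha / seq_along(rt$eig_pvalues_pos))
})

test_that("B below 19 is rejected", {
  td <- make_test_data(n = 10, p = 5)
  expect_error(spca_randtest(td$X, td$W, B = 5), "at least 19")
})
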