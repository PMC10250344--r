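test_that("rank-sum test matches exact enumeration on small samples", {
  # fully separated triples: 2 of 20 equally likely rank assignments are
  # at least this extreme, so the exact two-sided p is 0.1
  expect_equal(rank_sum_test(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(rank_sum_test(c(4, 5, 6), c(1, 2, 3)), 0.1) # label symmetry
  set.seed(1)
  a <- rnorm(30)
  b <- rnorm(25, 1)
  expect_equal(rank_sum_test(a, b), rank_sum_test(b, a))
  expect_warning(p <- rank_sum_test(c(1, 1), c(1, 1)), "identical")
  expect_equal(p, 1)
  expect_error(rank_sum_test(numeric(0), 1), "non-empty")
})

test_that("exact and approximate rank-sum branches agree near the boundary", {
  # at the n_a + n_b = 12 switch point the continuity-corrected normal
  # approximation tracks the exact enumeration to ~0.02 in p
  set.seed(2)
  for (i in 1:20) {
    a <- rnorm(6)
    b <- rnorm(6, 0.5)
    p_exact <- suppressWarnings(stats::wilcox.test(a, b, exact = TRUE)$p.value)
    p_approx <- suppressWarnings(
      stats::wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value
    )
    expect_lt(abs(p_exact - p_approx), 0.02)
    expect_equal(rank_sum_test(a, b), p_exact)
  }
  # just above the boundary the approximate branch is used
  set.seed(3)
  a13 <- rnorm(7)
  b13 <- rnorm(6)
  expect_equal(
    rank_sum_test(a13, b13),
    suppressWarnings(stats::wilcox.test(a13, b13, exact = FALSE, correct = TRUE)$p.value)
  )
})

test_that("quintile groups partition the cohort with the remainder rule", {
  rec <- function(best) {
    structure(
      list(best_response = best, responder = best %in% c("CR", "PR")),
      class = "vp_response"
    )
  }
  # n = 10 distinct values: pairs; medians are pairwise means
  v <- c(10, 1, 3, 8, 5, 2, 9, 4, 7, 6)
  recs <- lapply(rep(c("PR", "PD"), 5), rec)
  q <- quintile_response(v, recs)
  expect_equal(q$n, rep(2, 5))
  expect_equal(q$median_value, c(1.5, 3.5, 5.5, 7.5, 9.5))

  # n = 13: remainder goes to the first groups
  q13 <- quintile_response(seq_len(13), lapply(rep("SD", 13), rec))
  expect_equal(q13$n, c(3, 3, 3, 2, 2))
  expect_equal(sum(q13$n), 13)
  expect_true(max(q13$n) - min(q13$n) <= 1)

  # tie flood: identical medians, rates still computed
  qt <- quintile_response(rep(1, 10), lapply(rep(c("PR", "PD"), 5), rec))
  expect_equal(unique(qt$median_value), 1)
  expect_true(all(qt$orr + qt$pd_rate <= 1 + 1e-12))

  expect_error(quintile_response(1:4, lapply(rep("SD", 4), rec)), "at least 5")
})

test_that("random-forest importance finds the informative feature", {
  set.seed(3)
  n <- 200
  y <- rep(c(TRUE, FALSE), each = n / 2)
  X <- data.frame(
    signal = y + rnorm(n, 0, 0.3), # near-perfect separator
    noise1 = rnorm(n),
    noise2 = rnorm(n),
    noise3 = rnorm(n)
  )
  out <- rf_importance(X, y, seed = 4)
  expect_identical(names(which.max(out$importance)), "signal")
  expect_lt(out$oob_error, 0.2)

  # pure-noise features: observed importances lie inside the spread of a
  # label-permutation null (chance data/label correlation included)
  Xn <- as.data.frame(matrix(rnorm(n * 4), n))
  outn <- rf_importance(Xn, y, seed = 5)
  null_max <- replicate(10, {
    yp <- sample(y)
    max(abs(rf_importance(Xn, yp, seed = sample.int(1e6, 1))$importance))
  })
  expect_lte(max(abs(outn$importance)), max(null_max) * 1.5)
  expect_gt(outn$oob_error, 0.3) # no better than chance-level error

  # duplicating a column does not break the ensemble
  Xd <- cbind(X, signal2 = X$signal)
  outd <- rf_importance(Xd, y, seed = 6)
  expect_lt(outd$oob_error, out$oob_error + 0.05)

  expect_error(rf_importance(X, rep(TRUE, n)), "classes")
  expect_error(rf_importance(X["signal"], y), "2 features")
})

test_that("ROC threshold selection matches the worked example", {
  scores <- c(0.9, 0.8, 0.7, 0.6, 0.2, 0.5, 0.4, 0.3, 0.1, 0.05)
  labels <- c(rep(TRUE, 5), rep(FALSE, 5))
  r <- roc_at_sensitivity(scores, labels, target_sens = 0.8)
  expect_equal(r$threshold, 0.6)
  expect_equal(r$sensitivity, 0.8)
  expect_equal(r$specificity, 1.0)
  expect_equal(r$auroc, 22 / 25)

  # perfect separation
  rp <- roc_at_sensitivity(c(2, 3, 4, 0, 1) / 10, c(TRUE, TRUE, TRUE, FALSE, FALSE), 0.8)
  expect_equal(rp$auroc, 1.0)

  # invariance under a strictly monotone transform of the scores
  r_exp <- roc_at_sensitivity(exp(scores), labels, 0.8)
  expect_equal(r_exp$auroc, r$auroc)
  expect_equal(r_exp$sensitivity, r$sensitivity)
  expect_equal(r_exp$specificity, r$specificity)

  # degenerate scores
  expect_warning(rd <- roc_at_sensitivity(rep(1, 10), labels, 0.8), "degenerate")
  expect_equal(rd$auroc, 0.5)

  expect_error(roc_at_sensitivity(scores, rep(TRUE, 10), 0.8), "classes")
  expect_error(roc_at_sensitivity(scores, labels, 0), "target_sens")
})

test_that("auROC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(7)
  for (i in 1:5) {
    sc <- rnorm(80)
    lb <- rbinom(80, 1, plogis(sc))
    if (length(unique(lb)) < 2) next
    mine <- roc_at_sensitivity(sc, lb, 0.8)$auroc
    ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(lb, sc, quiet = TRUE))))
    expect_equal(mine, ref, tolerance = 1e-10)
  }
})

test_that("shuffled labels give a chance-level auROC", {
  set.seed(8)
  sc <- rnorm(1000)
  lb <- sample(rep(c(TRUE, FALSE), 500))
  expect_lt(abs(roc_at_sensitivity(sc, lb, 0.8)$auroc - 0.5), 0.05)
})

test_that("3D/2D density conversion is linear with round trip identity", {
  expect_equal(density_3d_to_2d(0), 0)
  expect_equal(density_3d_to_2d(1e7, t_eff = 0.011), 110)
  x <- c(0, 1e5, 3.3e7)
  expect_equal(density_2d_to_3d(density_3d_to_2d(x)), x, tolerance = 1e-12)
  expect_error(density_3d_to_2d(1, t_eff = 0), "positive")
  expect_error(density_3d_to_2d(-1), "non-negative")
})

test_that("the correlation screen is rank-based with unit diagonal", {
  set.seed(9)
  x <- rnorm(200)
  f <- data.frame(a = x, b = -x, c = exp(x), d = rnorm(200))
  cm <- correlation_matrix(f)
  expect_equal(unname(diag(cm)), rep(1, 4))
  expect_equal(cm["a", "b"], -1)
  expect_equal(cm["a", "c"], 1) # monotone transform: Spearman rho is 1
  expect_equal(cm, t(cm))
  big <- correlation_matrix(matrix(rnorm(2e4), ncol = 2))
  expect_lt(abs(big[1, 2]), 0.05)
  fc <- data.frame(a = x, const = rep(1, 200))
  expect_true(all(is.na(correlation_matrix(fc)["const", "a"])))
  expect_error(correlation_matrix(f["a"]), "2 features")
})
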