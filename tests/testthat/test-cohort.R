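test_that("Latin-hypercube sampling stratifies every dimension", {
  spec1 <- list(u = param_spec("k_growth", "uniform", min = 0, max = 1))
  s <- lhs_sample(spec1, 4, seed = 1)
  v <- sort(attr(s, "values")[, 1])
  expect_true(all(v >= c(0, 0.25, 0.5, 0.75) & v < c(0.25, 0.5, 0.75, 1)))

  # log-uniform: bounded, and ln(values) uniform-stratified
  spec2 <- list(param_spec("k_growth", "log-uniform", min = 1e-3, max = 1e-1))
  s2 <- lhs_sample(spec2, 8, seed = 2)
  v2 <- attr(s2, "values")[, 1]
  expect_true(all(v2 >= 1e-3 & v2 <= 1e-1))
  lv <- sort((log(v2) - log(1e-3)) / (log(1e-1) - log(1e-3)))
  expect_true(all(floor(lv * 8) == 0:7))

  # 2-D marginals pass a uniformity KS test
  specs <- list(
    param_spec("k_growth", "uniform", min = 0, max = 1),
    param_spec("C_max", "uniform", min = 0, max = 1)
  )
  s3 <- lhs_sample(specs, 1000, seed = 3)
  for (j in 1:2) {
    p <- suppressWarnings(
      stats::ks.test(attr(s3, "values")[, j], "punif")$p.value
    )
    expect_gt(p, 0.01)
  }
  # non-varied parameters keep their baseline
  expect_equal(s3[[1]]$T_PD1, 176)
})

test_that("parameter specs validate and invert correctly", {
  expect_error(param_spec("x", "unknown-dist", min = 0, max = 1))
  expect_error(param_spec("x", "uniform", min = 2, max = 1))
  sp <- param_spec("x", "log-normal", meanlog = 0, sdlog = 1)
  expect_equal(param_spec_quantile(sp, 0.5), 1) # log-normal median
  expect_error(param_spec_quantile(sp, 1), "quantile 0 or 1")
})

test_that("kNN density reproduces hand geometry and analytic scaling", {
  # 1-D, two points {0, 1}, query at 0, N = 1: nearest other point at
  # distance 1, V_1(1) = 2, m = 2 -> density 1/(2*2)
  pts <- matrix(c(0, 1), ncol = 1)
  expect_equal(knn_density(pts, matrix(0), N = 1), 0.25)
  expect_equal(knn_density(pts, N = 1), c(0.25, 0.25)) # self excluded

  # scaling: multiplying coordinates by c multiplies density by c^-d
  set.seed(4)
  x <- matrix(rnorm(600), ncol = 3)
  q <- matrix(rnorm(30), ncol = 3)
  expect_equal(
    knn_density(3 * x, 3 * q, N = 5),
    knn_density(x, q, N = 5) / 27,
    tolerance = 1e-12
  )

  # duplicates at the query collapse the neighbor radius
  dup <- matrix(rep(0, 10), ncol = 1)
  expect_error(knn_density(dup, matrix(0), N = 3), "degenerate")
  expect_error(knn_density(pts, matrix(0), N = 5), "number of points")
})

test_that("kNN density approximates the standard normal pdf", {
  set.seed(5)
  pts <- matrix(rnorm(1e4), ncol = 1)
  q <- matrix(seq(-1.5, 1.5, length.out = 100), ncol = 1)
  rho <- knn_density(pts, q, N = 10)
  rel <- abs(rho - dnorm(q[, 1])) / dnorm(q[, 1])
  expect_lt(median(rel), 0.2)
})

test_that("inclusion probabilities follow the density-ratio formula", {
  set.seed(6)
  x <- matrix(rnorm(300), ncol = 3)
  m_same <- selection_model(x, x, N = 5)
  expect_true(all(inclusion_probabilities(m_same, beta = 1) == 1))
  expect_true(all(inclusion_probabilities(m_same, beta = 0) == 0))

  y <- matrix(rnorm(600, sd = 2), ncol = 3)
  m <- selection_model(x, y, N = 5)
  b <- 1e-4 # small enough that no probability clips
  expect_equal(
    inclusion_probabilities(m, 2 * b),
    2 * inclusion_probabilities(m, b),
    tolerance = 1e-12
  )
  expect_error(selection_model(x[0, ], y), "non-empty")
  expect_error(selection_model(x, y, N = 500), "sample sizes")
})

test_that("the KS wrapper returns the supremum ECDF distance", {
  expect_equal(ks_two_sample(1:10, 1:10)$statistic, 0)
  expect_equal(ks_two_sample(1:10, 1:10)$p.value, 1)
  expect_equal(ks_two_sample(1:5, 11:15)$statistic, 1)
  expect_equal(ks_two_sample(c(1, 2), c(1.5, 2.5))$statistic, 0.5)
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("beta optimization honors its contract on edge cases", {
  set.seed(7)
  obs <- matrix(rnorm(600), ncol = 3)
  pool <- matrix(rnorm(3000, sd = 1.5), ncol = 3)
  model <- selection_model(obs, pool, N = 8)

  # zero-iteration schedule returns the (feasibility-lifted) initial beta
  opt0 <- optimize_beta(model, config = list(n_iter = 0, min_cohort = 50), seed = 1)
  opt0b <- optimize_beta(model, config = list(n_iter = 0, min_cohort = 50), seed = 2)
  expect_equal(opt0$beta_star, opt0b$beta_star)

  # infeasible minimum cohort errors
  expect_error(
    optimize_beta(model, config = list(min_cohort = 5000), seed = 1),
    "infeasible"
  )

  # far outliers in the pool get vanishing inclusion probabilities
  pool2 <- rbind(matrix(rnorm(1500), ncol = 3), matrix(rnorm(150) + 50, ncol = 3))
  m2 <- selection_model(obs, pool2, N = 8)
  opt2 <- optimize_beta(m2, config = list(min_cohort = 50), seed = 3)
  p2 <- inclusion_probabilities(m2, opt2$beta_star)
  expect_true(all(p2[501:550] < 0.01))

  # determinism of the full optimization
  opt_a <- optimize_beta(model, seed = 9)
  opt_b <- optimize_beta(model, seed = 9)
  expect_identical(opt_a$beta_star, opt_b$beta_star)
})

test_that("cohort selection is Bernoulli with the stated probabilities", {
  expect_identical(as.integer(select_cohort(rep(1, 10), seed = 1)), 1:10)
  expect_warning(sel0 <- select_cohort(rep(0, 10), seed = 1), "empty")
  expect_length(sel0, 0)
  sel <- select_cohort(rep(0.5, 1e4), seed = 2)
  expect_true(abs(length(sel) - 5000) <= 3 * 50)
  expect_error(select_cohort(c(0.5, 1.2)), "0, 1")
  # determinism
  expect_identical(
    as.integer(select_cohort(rep(0.3, 100), seed = 5)),
    as.integer(select_cohort(rep(0.3, 100), seed = 5))
  )
})

test_that("selection cannot extrapolate beyond the plausible pool", {
  set.seed(8)
  obs <- matrix(rnorm(450), ncol = 3)
  pool <- matrix(rnorm(2400, sd = 1.6), ncol = 3)
  model <- selection_model(obs, pool, N = 8)
  opt <- optimize_beta(model, seed = 4)
  idx <- select_cohort(inclusion_probabilities(model, opt$beta_star), seed = 5)
  sel <- pool[idx, , drop = FALSE]
  for (j in 1:3) {
    expect_gte(min(sel[, j]), min(pool[, j]))
    expect_lte(max(sel[, j]), max(pool[, j]))
  }
})
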