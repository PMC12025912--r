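test_that("single-point fit reproduces the closed-form normal equations", {
  b <- eigen_basis("matern", m = 1, sigma2 = 1, eps = 0, alpha = 1)
  fit <- lcgp_fit(b, t = 0.5, y = 1, noise_var = 1)
  # M = Phi'Phi + sigma_N^2 / lambda_1 = 2 + pi^2
  L <- lcgp_chol(fit)
  expect_equal(drop(L %*% t(L)), 2 + pi^2, tolerance = 1e-12)
  expect_equal(drop(L), sqrt(2 + pi^2), tolerance = 1e-12)

  p <- predict(fit, 0.5)
  expect_equal(p$mean, 2 / (2 + pi^2), tolerance = 1e-12)
  expect_equal(p$variance, 2 / (2 + pi^2), tolerance = 1e-12)
  expect_false(p$include_noise)
  pn <- predict(fit, 0.5, include_noise = TRUE)
  expect_equal(pn$variance, p$variance + 1)

  expect_equal(log_marginal(fit),
               -0.5 * log(2 / pi^2 + 1) - 0.5 / (2 / pi^2 + 1) -
                 0.5 * log(2 * pi),
               tolerance = 1e-10)
  expect_equal(log_marginal(fit), -1.42695, tolerance = 1e-5)
})

test_that("fit validates inputs and handles degenerate shapes", {
  b <- eigen_basis("matern", m = 10)
  expect_error(lcgp_fit(b, numeric(0), numeric(0), 0.1), "one observation")
  expect_error(lcgp_fit(b, 0.5, c(1, 2), 0.1), "same length")
  expect_error(lcgp_fit(b, 0.5, NA, 0.1), "finite")
  expect_error(lcgp_fit(b, 0.5, 1, 0), "positive")

  # N < m is legal: the prior precision keeps M positive definite
  set.seed(31)
  t <- runif(4); y <- rnorm(4)
  fit <- lcgp_fit(b, t, y, 0.1)
  expect_true(all(is.finite(predict(fit, t)$mean)))
  # duplicated inputs stay finite
  fit2 <- lcgp_fit(b, rep(t, 3), rep(y, 3), 0.1)
  expect_true(is.finite(log_marginal(fit2)))

  # zero responses give identically zero posterior mean
  fit0 <- lcgp_fit(b, t, rep(0, 4), 0.1)
  expect_equal(predict(fit0, t)$mean, rep(0, 4))

  # refitting is bit-identical
  expect_identical(lcgp_fit(b, t, y, 0.1)$chol_w, fit$chol_w)
})

test_that("reduced-rank predictions match the exact GP on the rank-m kernel", {
  set.seed(33)
  for (fam in lcgp_families) {
    for (rep in 1:3) {
      b <- make_basis(fam, m = 8, randomize = TRUE)
      pr <- make_problem(n = sample(5:40, 1))
      fit <- lcgp_fit(b, pr$t, pr$y, noise_var = 0.3)
      oracle <- cgp_fit(truncated_kernel(fit$basis), pr$t, pr$y,
                        noise_var = 0.3)
      p1 <- predict(fit, pr$t_star)
      p2 <- predict(oracle, pr$t_star)
      expect_equal(p1$mean, p2$mean, tolerance = 1e-9, info = fam)
      expect_equal(p1$variance, p2$variance, tolerance = 1e-9, info = fam)
      expect_equal(log_marginal(fit), log_marginal(oracle),
                   tolerance = 1e-8, info = fam)
    }
  }
})

test_that("posterior variance never exceeds the prior variance", {
  set.seed(35)
  for (fam in lcgp_families) {
    b <- make_basis(fam, m = 10)
    pr <- make_problem(n = 25)
    fit <- lcgp_fit(b, pr$t, pr$y, noise_var = 0.2)
    prior_var <- kernel_diag(truncated_kernel(fit$basis), pr$t_star)
    post_var <- predict(fit, pr$t_star)$variance
    expect_true(all(post_var >= 0))
    expect_true(all(post_var <= prior_var + 1e-10), info = fam)
  }
})

test_that("noise variance limits shrink to the prior mean or interpolate", {
  set.seed(37)
  b <- eigen_basis("matern", m = 10)
  t <- runif(8); y <- rnorm(8, sd = 2)
  ts <- runif(10, min(t), max(t))
  # huge noise: posterior mean collapses to the zero prior mean
  big <- lcgp_fit(b, t, y, noise_var = 1e8)
  expect_lt(max(abs(predict(big, ts)$mean)), 1e-4)
  # vanishing noise with N <= m distinct points: interpolation
  small <- lcgp_fit(b, t, y, noise_var = 1e-9)
  expect_equal(predict(small, t)$mean, y, tolerance = 1e-4)
})

test_that("centering restores a nonzero response level", {
  set.seed(38)
  t <- runif(30)
  y <- 5 + 0.1 * rnorm(30)
  fit <- lcgp_fit(eigen_basis("legendre", m = 8), t, y, 0.1, center = TRUE)
  expect_equal(fit$y_offset, mean(y))
  expect_equal(predict(fit, t)$mean, rep(mean(y), 30), tolerance = 0.2)
  # without centering the zero-mean prior drags predictions towards 0
  fit0 <- lcgp_fit(eigen_basis("legendre", m = 8), t, y, 0.1)
  expect_lt(mean(predict(fit0, t)$mean), mean(y))
})

test_that("fitting stores only order-m state however large N is", {
  set.seed(39)
  n <- 12000
  t <- runif(n); y <- rnorm(n)
  b <- eigen_basis("matern", m = 25)
  fit <- lcgp_fit(b, t, y, 0.1, chunk_size = 4096L)
  m <- 25L
  for (nm in setdiff(names(fit), "basis"))
    expect_lte(length(unlist(fit[[nm]])), m * m)
  # chunked accumulation is equivalent to a single pass
  fit1 <- lcgp_fit(b, t, y, 0.1, chunk_size = 100L)
  fit2 <- lcgp_fit(b, t, y, 0.1, chunk_size = n)
  expect_equal(fit1$chol_w, fit2$chol_w, tolerance = 1e-10)
  expect_equal(fit1$proj_data, fit2$proj_data, tolerance = 1e-10)
})
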