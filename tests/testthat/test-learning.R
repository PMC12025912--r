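test_that("gradient matches an independent one-sided difference oracle", {
  set.seed(51)
  t <- runif(40); y <- sin(6 * t) + rnorm(40, sd = 0.3)
  b <- fit_input_map(eigen_basis("matern", m = 10, sigma2 = 1.3,
                                 eps = 0.7), t)
  g <- lcgp_lml_gradient(b, t, y, noise_var = 0.2)
  # one-sided differences at a smaller step, fully outside the package path
  obj <- function(th) {
    b2 <- b; b2$sigma2 <- th[1]; b2$eps <- th[2]
    log_marginal(lcgp_fit(b2, t, y, th[3]))
  }
  th0 <- c(1.3, 0.7, 0.2)
  l0 <- obj(th0)
  h <- 1e-6
  g_ref <- sapply(1:3, function(i) {
    thp <- th0; thp[i] <- exp(log(thp[i]) + h)
    (obj(thp) - l0) / h
  })
  expect_equal(unname(g), g_ref, tolerance = 1e-4)
})

test_that("a fully frozen parameter set yields a zero gradient and a no-op", {
  set.seed(52)
  t <- runif(20); y <- rnorm(20)
  b <- fit_input_map(eigen_basis("legendre", m = 6, amplitude = FALSE), t)
  g <- lcgp_lml_gradient(b, t, y, noise_var = 0.2,
                         params = character())
  expect_length(g, 0)
  opt <- lcgp_learn(b, t, y, noise_var = 0.2, learn_noise = FALSE)
  expect_true(opt$converged)
  expect_identical(opt$iterations, 0L)
  expect_equal(opt$noise_var, 0.2)
})

test_that("ascent is monotone and restarting at the optimum is idle", {
  set.seed(53)
  t <- runif(60); y <- sin(8 * t) + rnorm(60, sd = 0.3)
  b <- eigen_basis("matern", m = 15)
  opt <- lcgp_learn(b, t, y, noise_var = 0.3, max_iters = 150)
  expect_false(is.unsorted(opt$trace))
  expect_gte(utils::tail(opt$trace, 1), opt$trace[1])
  # restart at a converged optimum: the gradient is already below
  # tolerance, so the optimizer returns immediately and unchanged
  bl <- eigen_basis("legendre", m = 10)
  optl <- lcgp_learn(bl, t, y, noise_var = 0.3, tol = 1e-6,
                     max_iters = 1000)
  expect_true(optl$converged)
  opt2 <- lcgp_learn(optl$basis, t, y, noise_var = optl$noise_var,
                     tol = 1e-6, max_iters = 1000)
  expect_lte(opt2$iterations, 3L)
  expect_equal(unname(opt2$theta), unname(optl$theta), tolerance = 1e-3)
})

test_that("multi-start returns the best of its starts", {
  set.seed(54)
  t <- runif(40); y <- sin(8 * t) + rnorm(40, sd = 0.3)
  b <- eigen_basis("legendre", m = 10)
  inits <- list(c(sigma2 = 0.01), c(sigma2 = 1), c(sigma2 = 20))
  multi <- lcgp_learn(b, t, y, noise_var = 0.2, inits = inits,
                      max_iters = 100)
  singles <- sapply(inits, function(init) {
    b2 <- b; b2$sigma2 <- init[["sigma2"]]
    utils::tail(lcgp_learn(b2, t, y, noise_var = 0.2,
                           max_iters = 100)$trace, 1)
  })
  expect_equal(utils::tail(multi$trace, 1), max(singles))
})

test_that("optimizing the reduced-rank objective equals optimizing the exact one", {
  # determinant-lemma consistency: both objectives are the same function
  # of theta, so their maximizers agree
  set.seed(55)
  t <- runif(40); y <- sin(6 * t) + rnorm(40, sd = 0.3)
  b <- fit_input_map(eigen_basis("legendre", m = 8), t)
  opt <- lcgp_learn(b, t, y, noise_var = 0.2, tol = 1e-7, max_iters = 2000)
  neg_exact <- function(lp) {
    b2 <- b; b2$sigma2 <- exp(lp[1])
    -log_marginal(cgp_fit(truncated_kernel(b2), t, y, exp(lp[2])))
  }
  o <- stats::optim(log(c(1, 0.2)), neg_exact, method = "BFGS",
                    control = list(reltol = 1e-14))
  expect_equal(unname(opt$theta), unname(exp(o$par)), tolerance = 0.01)
})

test_that("noise variance is recovered without systematic bias", {
  # data from the model's own prior; the log-noise estimate over replicate
  # datasets should be centred on the truth
  gen <- eigen_basis("matern", m = 25, sigma2 = 2, eps = 2, alpha = 1,
                     map = list(scale = 1, offset = 0))
  est <- sapply(1:10, function(seed) {
    set.seed(seed + 700)
    t <- runif(500)
    f <- drop(sample_prior(gen, t, n_paths = 1)$paths)
    y <- f + rnorm(500, sd = sqrt(0.1))
    b <- eigen_basis("matern", m = 25, sigma2 = 1, eps = 1, alpha = 1,
                     map = list(scale = 1, offset = 0))
    lcgp_learn(b, t, y, noise_var = 0.5, max_iters = 150)$noise_var
  })
  bias <- mean(log(est)) - log(0.1)
  expect_lt(abs(bias), 0.5)
})
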