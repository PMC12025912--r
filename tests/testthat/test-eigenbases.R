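test_that("operator eigenvalues follow the closed forms per family", {
  b <- eigen_basis("matern", m = 5, sigma2 = 2, eps = 2, alpha = 1)
  expect_equal(basis_gamma(b, 1), (2 + pi^2) / 2)
  expect_equal(basis_lambda(b, 1), 2 / (2 + pi^2))

  expect_equal(basis_gamma(eigen_basis("legendre", m = 5), 3), 12)
  expect_equal(basis_gamma(eigen_basis("laguerre", m = 5), 3), 9)
  expect_equal(basis_gamma(eigen_basis("hermite", m = 5), 3), 36)
  expect_equal(basis_gamma(eigen_basis("chebyshev", m = 5), 2), 16)
  bj <- eigen_basis("jacobi", m = 5, alpha_jac = -0.5, beta_jac = -0.3)
  expect_equal(basis_gamma(bj, 2), 2 * (2 - 0.5 - 0.3 + 1))

  # reciprocal identity lambda * gamma = amplitude
  bl <- eigen_basis("legendre", m = 5, amplitude = FALSE)
  expect_equal(basis_lambda(bl, 1), 0.5)
  for (fam in lcgp_families) {
    b <- eigen_basis(fam, m = 8, sigma2 = 1.7)
    amp <- if (fam == "matern") 1 else 1.7
    expect_equal(basis_lambda(b, 1:8) * basis_gamma(b, 1:8),
                 rep(amp, 8), tolerance = 1e-14)
  }

  expect_error(basis_gamma(b, 0), "positive integer")
  expect_error(basis_gamma(b, 1.5), "positive integer")
  expect_error(eigen_basis("matern", m = 5, sigma2 = -1), "sigma2")
  expect_error(eigen_basis("jacobi", m = 5, alpha_jac = -1.2), "> -1")
})

test_that("kernel eigenvalues are strictly decreasing for random valid parameters", {
  set.seed(11)
  for (rep in 1:10) for (fam in lcgp_families) {
    b <- make_basis(fam, m = 20, randomize = TRUE)
    lam <- basis_lambda(b, 1:20)
    expect_true(all(diff(lam) < 0), info = fam)
    expect_true(all(lam > 0), info = fam)
  }
})

test_that("eigenfunctions match the tabulated forms and are L2(rho)-orthonormal", {
  expect_equal(basis_phi(eigen_basis("matern", m = 2), 1, 0.5), sqrt(2))
  expect_equal(basis_phi(eigen_basis("chebyshev", m = 3), 2, 1),
               1 / sqrt(pi / 2))
  # Legendre norm resolution: P_1(t) = t scaled by sqrt(3/2)
  expect_equal(basis_phi(eigen_basis("legendre", m = 2), 1, 0.7),
               0.7 * sqrt(3 / 2))
  # Laguerre L_1(t) = 1 - t already unit norm
  expect_equal(basis_phi(eigen_basis("laguerre", m = 2), 1, 2), -1)
  # Hermite h_2(t) = (4t^2 - 2)/sqrt(sqrt(pi) 2^2 2!)
  expect_equal(basis_phi(eigen_basis("hermite", m = 3), 2, 0.3),
               (4 * 0.09 - 2) / sqrt(sqrt(pi) * 8))

  for (fam in lcgp_families) {
    G <- phi_gram(eigen_basis(fam, m = 10), m = 10, n_nodes = 60)
    expect_lt(max(abs(G - diag(10))), 1e-8)
  }
  expect_error(basis_phi(eigen_basis("matern", m = 2), 1, 1.5), "domain")
  expect_error(basis_phi(eigen_basis("laguerre", m = 2), 1, -0.1), "domain")
})

test_that("design matrix maps data coordinates and validates input", {
  b <- eigen_basis("matern", m = 1, map = list(scale = 1, offset = 0))
  expect_equal(design_matrix(b, 0.5), matrix(sqrt(2), 1, 1))
  expect_error(design_matrix(b, numeric(0)), "length")
  expect_error(design_matrix(b, c(0.5, 2)), "position\\(s\\) 2")
  expect_error(design_matrix(b, c(0.5, NA)), "finite")

  # with a fitted map, the full training set lands inside the domain
  set.seed(4)
  t <- rnorm(50, sd = 10)
  for (fam in lcgp_families) {
    bf <- fit_input_map(eigen_basis(fam, m = 6), t)
    P <- design_matrix(bf, t)
    expect_true(all(is.finite(P)), info = fam)
    expect_identical(dim(P), c(50L, 6L))
  }
})

test_that("input maps place training data per family convention", {
  t <- c(2, 3, 7)
  b <- fit_input_map(eigen_basis("legendre", m = 3), t)
  u <- b$map$scale * t + b$map$offset
  expect_equal(range(u), c(-0.96, 0.96))
  b <- fit_input_map(eigen_basis("matern", m = 3), t)
  expect_equal(range(b$map$scale * t + b$map$offset), c(0.02, 0.98))
  b <- fit_input_map(eigen_basis("laguerre", m = 10), t)
  expect_equal(range(b$map$scale * t + b$map$offset), c(0, 5))
  b <- fit_input_map(eigen_basis("hermite", m = 3), t)
  u <- b$map$scale * t + b$map$offset
  expect_equal(mean(u), 0)
  expect_equal(sd(u), 1)
  # degenerate range: the single point goes to the domain centre
  b <- fit_input_map(eigen_basis("matern", m = 3), 0.5)
  expect_equal(b$map$scale * 0.5 + b$map$offset, 0.5)
})

test_that("MISE closed forms, telescoping and monotone decay hold", {
  bl <- eigen_basis("legendre", m = 30, amplitude = FALSE)
  expect_equal(basis_mise(bl, 25), 1 / 26, tolerance = 1e-14)
  expect_equal(basis_mise(eigen_basis("chebyshev", m = 2,
                                      amplitude = FALSE), 0),
               pi^4 / 90, tolerance = 1e-14)
  expect_equal(basis_mise(eigen_basis("hermite", m = 2,
                                      amplitude = FALSE), 0),
               pi^2 / 24, tolerance = 1e-14)
  expect_error(basis_mise(bl, -1), "nonnegative")

  for (fam in lcgp_families) {
    b <- eigen_basis(fam, m = 10, sigma2 = 1.4, eps = 0.5)
    xi <- sapply(0:12, function(m) basis_mise(b, m))
    expect_true(all(diff(xi) < 0), info = fam)
    # telescoping: xi_m - xi_{m+1} = lambda_{m+1}
    expect_equal(-diff(xi), basis_lambda(b, 1:12),
                 tolerance = 1e-10, info = fam)
    # decay towards zero
    expect_lt(basis_mise(b, 500), basis_mise(b, 10) / 10)
  }
  # Legendre telescoping is exact rational arithmetic in floating point
  b <- eigen_basis("legendre", m = 5, amplitude = FALSE)
  for (m in c(1, 10, 50))
    expect_equal(basis_mise(b, m) - basis_mise(b, m + 1),
                 1 / ((m + 1) * (m + 2)), tolerance = 1e-12)
})

test_that("eps = 0 is a valid degenerate Matern shape", {
  b <- eigen_basis("matern", m = 5, sigma2 = 1, eps = 0, alpha = 1)
  expect_equal(basis_lambda(b, 1), 1 / pi^2)
  expect_true(all(basis_lambda(b, 1:5) > 0))
})
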