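# Shared fixtures: every basis family with valid randomized parameters,
# and small regression problems for cross-route checks.

lcgp_families <- c("matern", "legendre", "laguerre", "hermite",
                   "chebyshev", "jacobi")

# A basis with either default or randomized (but valid) parameters.
make_basis <- function(family, m = 10, randomize = FALSE) {
  if (!randomize)
    return(eigen_basis(family, m = m))
  eigen_basis(family, m = m,
              sigma2 = exp(stats::runif(1, -1, 1)),
              eps = stats::runif(1, 0, 3),
              alpha = sample(1:2, 1),
              alpha_jac = stats::runif(1, -0.9, 2),
              beta_jac = stats::runif(1, -0.9, 2))
}

# Random regression problem on [0,1] with test points inside the training
# range (so the fitted input map covers them).
make_problem <- function(n = 30, n_star = 10) {
  t <- stats::runif(n)
  list(t = t,
       y = stats::rnorm(n),
       t_star = stats::runif(n_star, min(t), max(t)))
}

# Quadrature-based Gram matrix of the first `m` eigenfunctions; the
# orthonormality oracle.
phi_gram <- function(basis, m, n_nodes = 80) {
  q <- basis_quadrature(basis, n_nodes)
  P <- sapply(seq_len(m), function(j) basis_phi(basis, j, q$nodes))
  crossprod(P, q$weights * P)
}
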