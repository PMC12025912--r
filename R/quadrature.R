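#' Gauss quadrature matched to a basis family's weight
#'
#' Nodes and weights for numerical integration against the family weight
#' \eqn{\rho} on the natural domain, so that
#' `sum(w * f(x))` approximates \eqn{\int_I f(t)\rho(t)\,dt}. Used to check
#' orthonormality of the eigenfunctions and the integral-operator
#' eigen-relation; with `n` nodes, polynomial integrands up to degree
#' 2n - 1 are exact.
#'
#' Uniform-weight compact domains use Gauss-Legendre, the half-line
#' Gauss-Laguerre, the real line Gauss-Hermite (all via \pkg{pracma}),
#' the Chebyshev weight its closed-form rule, and the Jacobi weight a
#' Golub-Welsch eigen-decomposition of its recurrence matrix.
#'
#' @param basis an [eigen_basis()] or family name.
#' @param n number of nodes.
#' @param alpha_jac,beta_jac Jacobi exponents, used when `basis` is the
#'   string `"jacobi"`.
#' @return `list(nodes, weights)`, both length `n`.
#' @export
basis_quadrature <- function(basis, n, alpha_jac = -0.5, beta_jac = -0.3) {
  family <- if (inherits(basis, "eigen_basis")) basis$family else basis
  if (inherits(basis, "eigen_basis") && family == "jacobi") {
    alpha_jac <- basis$alpha_jac
    beta_jac <- basis$beta_jac
  }
  n <- as.integer(n)
  stopifnot(n >= 1)
  switch(
    family,
    matern = {
      q <- pracma::gaussLegendre(n, 0, 1)
      list(nodes = q$x, weights = q$w)
    },
    legendre = {
      q <- pracma::gaussLegendre(n, -1, 1)
      list(nodes = q$x, weights = q$w)
    },
    laguerre = gauss_laguerre_accurate(n),
    hermite = gauss_hermite_accurate(n),
    chebyshev = {
      k <- seq_len(n)
      list(nodes = cos((2 * k - 1) * pi / (2 * n)),
           weights = rep(pi / n, n))
    },
    jacobi = gauss_jacobi(n, alpha_jac, beta_jac),
    stop("unknown family: ", family))
}

# Gauss-Laguerre and Gauss-Hermite weights span hundreds of orders of
# magnitude; eigenvector-based (Golub-Welsch) weights lose the tiny ones
# to rounding (components below ~1e-16 of the eigenvector norm are pure
# noise), which breaks high-degree orthonormality checks. We therefore
# take the nodes (from pracma), polish them with Newton steps on the
# degree-n orthonormal polynomial, and evaluate the classical
# derivative-based weight formulas, which represent tiny weights exactly.

# Orthonormal Laguerre values L_0..L_jmax at x: matrix length(x) x (jmax+1)
.lag_all <- function(x, jmax) {
  out <- matrix(0, length(x), jmax + 1)
  out[, 1] <- 1
  if (jmax >= 1) out[, 2] <- 1 - x
  if (jmax >= 2) for (k in 1:(jmax - 1))
    out[, k + 2] <- ((2 * k + 1 - x) * out[, k + 1] - k * out[, k]) / (k + 1)
  out
}

gauss_laguerre_accurate <- function(n) {
  x <- pracma::gaussLaguerre(n, 0)$x
  for (it in 1:3) {                       # Newton: L_n'(x) = n(L_n - L_{n-1})/x
    L <- .lag_all(x, n)
    x <- x - L[, n + 1] * x / (n * (L[, n + 1] - L[, n]))
  }
  L <- .lag_all(x, n + 1)
  list(nodes = x, weights = x / ((n + 1)^2 * L[, n + 2]^2))
}

# Orthonormal Hermite values h_0..h_jmax at x (weight e^{-x^2})
.herm_all <- function(x, jmax) {
  out <- matrix(0, length(x), jmax + 1)
  out[, 1] <- pi^(-0.25)
  if (jmax >= 1) out[, 2] <- sqrt(2) * x * out[, 1]
  if (jmax >= 2) for (k in 1:(jmax - 1))
    out[, k + 2] <- sqrt(2 / (k + 1)) * x * out[, k + 1] -
      sqrt(k / (k + 1)) * out[, k]
  out
}

gauss_hermite_accurate <- function(n) {
  x <- pracma::gaussHermite(n)$x
  for (it in 1:3) {                       # h_n'(x) = sqrt(2n) h_{n-1}(x)
    H <- .herm_all(x, n)
    x <- x - H[, n + 1] / (sqrt(2 * n) * H[, n])
  }
  H <- .herm_all(x, n)
  list(nodes = x, weights = 1 / (n * H[, n]^2))
}

# Golub-Welsch rule for the weight (1-x)^a (1+x)^b on [-1,1].
# Recurrence coefficients of the orthonormal Jacobi polynomials
# (Gautschi's a_k, b_k); nodes are eigenvalues of the symmetric
# tridiagonal Jacobi matrix, weights are mu0 * (first eigenvector row)^2.
gauss_jacobi <- function(n, a, b) {
  ab <- a + b
  mu0 <- exp((ab + 1) * log(2) + lgamma(a + 1) + lgamma(b + 1) -
               lgamma(ab + 2))
  d <- numeric(n)
  e <- numeric(max(n - 1, 0))
  d[1] <- (b - a) / (ab + 2)
  if (n > 1) {
    k <- seq_len(n - 1)
    d[-1] <- (b^2 - a^2) / ((2 * k + ab) * (2 * k + ab + 2))
    e[1] <- sqrt(4 * (a + 1) * (b + 1) / ((ab + 2)^2 * (ab + 3)))
    if (n > 2) {
      k2 <- 2:(n - 1)
      e[-1] <- sqrt(4 * k2 * (k2 + a) * (k2 + b) * (k2 + ab) /
                      ((2 * k2 + ab)^2 * (2 * k2 + ab + 1) *
                         (2 * k2 + ab - 1)))
    }
  }
  J <- diag(d, n, n)
  if (n > 1) {
    J[cbind(1:(n - 1), 2:n)] <- e
    J[cbind(2:n, 1:(n - 1))] <- e
  }
  eg <- eigen(J, symmetric = TRUE)
  ord <- order(eg$values)
  list(nodes = eg$values[ord],
       weights = mu0 * (eg$vectors[1, ord])^2)
}
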