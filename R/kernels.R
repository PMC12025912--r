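#' Truncated Mercer kernel from an eigenbasis
#'
#' The rank-m covariance \eqn{k_m(t,s) = \sum_{j=1}^m \lambda_j
#' \phi_j(t)\phi_j(s)}. Its Gram matrix on any input set factors as
#' \eqn{\tilde K = \Phi \Gamma \Phi^\top} with \eqn{\Gamma =
#' \mathrm{diag}(\lambda_1, \dots, \lambda_m)}, hence has rank at most m.
#'
#' @param basis an [eigen_basis()].
#' @return object of class `"truncated_kernel"`.
#' @export
truncated_kernel <- function(basis) {
  stopifnot(inherits(basis, "eigen_basis"))
  structure(list(basis = basis), class = "truncated_kernel")
}

#' Canonical covariance functions
#'
#' Closed-form covariances used by the exact GP baseline and as validation
#' references:
#' * `squared_exponential`: \eqn{k(t,s) = \sigma^2 e^{-\epsilon^2 (t-s)^2}}
#'   (note the shape parameter enters squared).
#' * `matern_nu`: \eqn{\sigma^2 \frac{2^{1-\nu}}{\Gamma(\nu)}
#'   (\epsilon\sqrt{2\nu}\,d)^\nu K_\nu(\epsilon\sqrt{2\nu}\,d)} with
#'   \eqn{d = |t-s|} and \eqn{K_\nu} the modified Bessel function.
#' * `brownian_motion`: \eqn{\min(t,s)} on \[0,1\].
#' * `brownian_bridge`: \eqn{\min(t,s) - ts} on \[0,1\].
#'
#' The Brownian kernels live in data coordinates on \[0,1\] and exist for
#' validating the Karhunen-Loeve machinery.
#'
#' @param kind one of the four names above.
#' @param sigma2 variance, > 0 (SE and Matern).
#' @param eps shape, > 0 (SE and Matern).
#' @param nu half-integer smoothness (Matern only).
#' @return object of class `"canonical_kernel"`.
#' @export
canonical_kernel <- function(kind = c("squared_exponential", "matern_nu",
                                      "brownian_motion", "brownian_bridge"),
                             sigma2 = 1, eps = 1, nu = 1.5) {
  kind <- match.arg(kind)
  if (sigma2 <= 0) stop("`sigma2` must be > 0")
  if (eps <= 0) stop("`eps` must be > 0")
  if (kind == "matern_nu" && (nu <= 0 || abs(nu %% 1 - 0.5) > 1e-12))
    stop("`nu` must be a positive half-integer (0.5, 1.5, 2.5, ...)")
  structure(list(kind = kind, sigma2 = sigma2, eps = eps, nu = nu),
            class = "canonical_kernel")
}

#' Evaluate a covariance function
#'
#' @param kernel a [truncated_kernel()] or [canonical_kernel()].
#' @param t,s numeric vectors (recycled elementwise).
#' @return numeric vector of covariance values.
#' @export
kernel_cov <- function(kernel, t, s) UseMethod("kernel_cov")

#' @export
kernel_cov.truncated_kernel <- function(kernel, t, s) {
  n <- max(length(t), length(s))
  t <- rep_len(t, n); s <- rep_len(s, n)
  basis <- kernel$basis
  lam <- basis_lambda(basis, seq_len(basis$m))
  pt <- design_matrix(basis, t)
  ps <- design_matrix(basis, s)
  rowSums(pt * sweep(ps, 2, lam, "*"))
}

#' @export
kernel_cov.canonical_kernel <- function(kernel, t, s) {
  n <- max(length(t), length(s))
  t <- rep_len(t, n); s <- rep_len(s, n)
  switch(
    kernel$kind,
    squared_exponential = kernel$sigma2 *
      exp(-kernel$eps^2 * (t - s)^2),
    matern_nu = {
      z <- kernel$eps * sqrt(2 * kernel$nu) * abs(t - s)
      out <- rep(kernel$sigma2, n)
      pos <- z > 0
      out[pos] <- kernel$sigma2 * 2^(1 - kernel$nu) / gamma(kernel$nu) *
        z[pos]^kernel$nu * besselK(z[pos], kernel$nu)
      out
    },
    brownian_motion = {
      .check_unit(t, s)
      pmin(t, s)
    },
    brownian_bridge = {
      .check_unit(t, s)
      pmin(t, s) - t * s
    })
}

.check_unit <- function(t, s) {
  if (any(t < 0 | t > 1 | s < 0 | s > 1))
    stop("Brownian kernels are defined on [0,1]")
  invisible(NULL)
}

#' Gram matrix of a covariance on a set of inputs
#'
#' For a truncated kernel the matrix is assembled in factor form
#' \eqn{\Phi\Gamma\Phi^\top} (never by an entrywise double loop); a
#' diagnostic warning is issued when the spectrum ratio
#' \eqn{\lambda_1/\lambda_m} exceeds 1e12, the regime where the rank-m
#' Gram matrix becomes numerically ill-conditioned.
#'
#' @param kernel a [truncated_kernel()] or [canonical_kernel()].
#' @param t numeric input vector, length >= 1.
#' @param t2 optional second input vector; when given, the
#'   `length(t) x length(t2)` cross-covariance matrix is returned.
#' @return numeric matrix.
#' @export
kernel_gram <- function(kernel, t, t2 = NULL) UseMethod("kernel_gram")

#' @export
kernel_gram.truncated_kernel <- function(kernel, t, t2 = NULL) {
  if (length(t) < 1) stop("`t` must have length >= 1")
  basis <- kernel$basis
  lam <- basis_lambda(basis, seq_len(basis$m))
  if (lam[1] / lam[basis$m] > 1e12)
    warning(sprintf(
      "spectrum ratio lambda_1/lambda_m = %.3g > 1e12: rank-%d Gram matrix is ill-conditioned",
      lam[1] / lam[basis$m], basis$m))
  p1 <- design_matrix(basis, t)
  p2 <- if (is.null(t2)) p1 else design_matrix(basis, t2)
  p1 %*% (lam * t(p2))
}

#' @export
kernel_gram.canonical_kernel <- function(kernel, t, t2 = NULL) {
  if (length(t) < 1) stop("`t` must have length >= 1")
  if (is.null(t2)) t2 <- t
  outer(t, t2, function(a, b) kernel_cov(kernel, a, b))
}

# prior variance k(t,t), used for predictive-variance assembly
kernel_diag <- function(kernel, t) {
  kernel_cov(kernel, t, t)
}
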