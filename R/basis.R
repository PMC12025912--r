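#' Differential-operator eigenbases
#'
#' Construct an eigenbasis of a classical differential operator, the
#' building block of the low-complexity GP covariance
#' \eqn{k_m(t,s) = \sum_{j=1}^m \lambda_j \phi_j(t)\phi_j(s)}.
#'
#' Six families are available. Each lives on a natural domain with a weight
#' \eqn{\rho(t)} under which its eigenfunctions are orthonormal:
#'
#' | family | domain | weight | \eqn{\gamma_j} | \eqn{\phi_j(t)} |
#' |---|---|---|---|---|
#' | `matern` | \[0,1\] | 1 | \eqn{\sigma^{-2}(\epsilon + j^2\pi^2)^\alpha} | \eqn{\sqrt{2}\sin(j\pi t)} |
#' | `legendre` | \[-1,1\] | 1 | \eqn{j(j+1)} | normalized Legendre |
#' | `laguerre` | \[0,Inf) | \eqn{e^{-t}} | \eqn{j^2} | Laguerre |
#' | `hermite` | R | \eqn{e^{-t^2}} | \eqn{4j^2} | normalized Hermite |
#' | `chebyshev` | \[-1,1\] | \eqn{(1-t^2)^{-1/2}} | \eqn{j^4} | normalized Chebyshev |
#' | `jacobi` | \[-1,1\] | \eqn{(1-t)^\alpha(1+t)^\beta} | \eqn{j(j+\alpha+\beta+1)} | normalized Jacobi |
#'
#' Kernel eigenvalues are reciprocals of the operator eigenvalues,
#' \eqn{\lambda_j = 1/\gamma_j}, optionally scaled by a learnable global
#' amplitude `sigma2` for the polynomial families (the Matern family carries
#' its variance inside \eqn{\gamma_j} already). Indexing starts at j = 1:
#' the degree-0 constant modes of the polynomial families have operator
#' eigenvalue 0 and are excluded.
#'
#' Data rarely live on the natural domain, so a basis carries an invertible
#' affine input map. Leave `map = NULL` to have [lcgp_fit()] calibrate it
#' from the training inputs (compact domains: training range onto the
#' central 96 percent; Laguerre: range onto \[0, m/2\];
#' Hermite: standardized), or supply `list(scale =, offset =)` explicitly.
#'
#' @param family one of `"matern"`, `"legendre"`, `"laguerre"`, `"hermite"`,
#'   `"chebyshev"`, `"jacobi"`.
#' @param m truncation order (number of retained eigenpairs), positive integer.
#' @param sigma2 variance amplitude, positive. For `matern` this is the
#'   kernel variance of the spectrum; for polynomial families it is a global
#'   amplitude applied when `amplitude = TRUE`.
#' @param eps Matern shape parameter, nonnegative.
#' @param alpha Matern smoothness, a positive integer
#'   (\eqn{\alpha = \nu + 1/2}).
#' @param alpha_jac,beta_jac Jacobi weight exponents, each greater than -1.
#' @param amplitude logical; multiply the polynomial-family spectrum by
#'   `sigma2`? Set `FALSE` for the literal parameter-free spectrum.
#' @param map `NULL` (calibrate at fit time), or `list(scale, offset)` with
#'   `scale != 0` mapping data coordinates onto the natural domain.
#' @return An object of class `"eigen_basis"`.
#' @examples
#' b <- eigen_basis("matern", m = 25, sigma2 = 2, eps = 2, alpha = 1)
#' basis_gamma(b, 1)            # (2 + pi^2)/2
#' basis_lambda(b, 1:3)
#' basis_mise(b, 25)            # eigenvalue tail beyond m = 25
#' @seealso [basis_phi()], [design_matrix()], [basis_mise()], [lcgp_fit()]
#' @export
eigen_basis <- function(family = c("matern", "legendre", "laguerre",
                                   "hermite", "chebyshev", "jacobi"),
                        m, sigma2 = 1, eps = 1, alpha = 1,
                        alpha_jac = -0.5, beta_jac = -0.3,
                        amplitude = TRUE, map = NULL) {
  family <- match.arg(family)
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("`m` must be a positive integer")
  if (!is.numeric(sigma2) || sigma2 <= 0)
    stop("`sigma2` must be > 0")
  if (!is.numeric(eps) || eps < 0)
    stop("`eps` must be >= 0")
  if (!is.numeric(alpha) || alpha < 1 || alpha != round(alpha))
    stop("`alpha` must be an integer >= 1")
  if (alpha_jac <= -1 || beta_jac <= -1)
    stop("Jacobi parameters must be > -1")
  if (!is.null(map)) {
    if (!is.list(map) || is.null(map$scale) || is.null(map$offset) ||
        map$scale == 0)
      stop("`map` must be list(scale, offset) with scale != 0")
  }
  structure(
    list(family = family, m = as.integer(m), sigma2 = sigma2, eps = eps,
         alpha = as.integer(alpha), alpha_jac = alpha_jac,
         beta_jac = beta_jac, amplitude = isTRUE(amplitude), map = map),
    class = "eigen_basis")
}

#' @export
print.eigen_basis <- function(x, ...) {
  dom <- basis_domain(x)
  cat(sprintf("Eigenbasis: %s, m = %d, domain [%g, %g]\n",
              x$family, x$m, dom[1], dom[2]))
  if (x$family == "matern")
    cat(sprintf("  sigma2 = %g, eps = %g, alpha = %d\n",
                x$sigma2, x$eps, x$alpha))
  else if (x$family == "jacobi")
    cat(sprintf("  alpha = %g, beta = %g, amplitude %s (sigma2 = %g)\n",
                x$alpha_jac, x$beta_jac,
                if (x$amplitude) "on" else "off", x$sigma2))
  else
    cat(sprintf("  amplitude %s (sigma2 = %g)\n",
                if (x$amplitude) "on" else "off", x$sigma2))
  if (!is.null(x$map))
    cat(sprintf("  input map: t -> %g * t + %g\n", x$map$scale, x$map$offset))
  invisible(x)
}

#' Natural domain of a basis family
#'
#' @param basis an [eigen_basis()] (or a family name).
#' @return numeric length-2 vector `c(lower, upper)`; unbounded ends are
#'   `-Inf`/`Inf`.
#' @export
basis_domain <- function(basis) {
  family <- if (inherits(basis, "eigen_basis")) basis$family else basis
  switch(family,
         matern    = c(0, 1),
         legendre  = c(-1, 1),
         laguerre  = c(0, Inf),
         hermite   = c(-Inf, Inf),
         chebyshev = c(-1, 1),
         jacobi    = c(-1, 1),
         stop("unknown family: ", family))
}

#' Weight function rho(t) of a basis family on its natural domain
#'
#' @inheritParams basis_domain
#' @param t evaluation points in the natural domain.
#' @export
basis_weight <- function(basis, t) {
  family <- if (inherits(basis, "eigen_basis")) basis$family else basis
  a <- if (inherits(basis, "eigen_basis")) basis$alpha_jac else -0.5
  b <- if (inherits(basis, "eigen_basis")) basis$beta_jac else -0.3
  switch(family,
         matern    = rep(1, length(t)),
         legendre  = rep(1, length(t)),
         laguerre  = exp(-t),
         hermite   = exp(-t^2),
         chebyshev = 1 / sqrt(1 - t^2),
         jacobi    = (1 - t)^a * (1 + t)^b,
         stop("unknown family: ", family))
}

.check_index <- function(j) {
  if (!is.numeric(j) || any(j < 1) || any(j != round(j)))
    stop("eigenfunction index `j` must be a positive integer (j >= 1)")
  as.integer(j)
}

#' Differential-operator eigenvalues gamma_j
#'
#' The eigenvalue of the (possibly iterated) differential operator to which
#' the j-th eigenfunction belongs. Kernel eigenvalues are their reciprocals,
#' see [basis_lambda()].
#'
#' @param basis an [eigen_basis()].
#' @param j eigenfunction index (vectorized), j >= 1.
#' @return positive numeric vector.
#' @export
basis_gamma <- function(basis, j) {
  stopifnot(inherits(basis, "eigen_basis"))
  j <- .check_index(j)
  switch(basis$family,
         matern    = (basis$eps + (j * pi)^2)^basis$alpha / basis$sigma2,
         legendre  = j * (j + 1),
         laguerre  = j^2,
         hermite   = 4 * j^2,
         chebyshev = as.numeric(j)^4,
         jacobi    = j * (j + basis$alpha_jac + basis$beta_jac + 1))
}

.basis_amplitude <- function(basis) {
  if (basis$family == "matern") 1
  else if (basis$amplitude) basis$sigma2
  else 1
}

#' Kernel (integral-operator) eigenvalues lambda_j
#'
#' \eqn{\lambda_j = A / \gamma_j} where the amplitude A is 1 for the Matern
#' family (its variance already enters \eqn{\gamma_j}) and `sigma2` for the
#' polynomial families when the basis was built with `amplitude = TRUE`.
#'
#' @inheritParams basis_gamma
#' @return positive numeric vector, strictly decreasing in `j`.
#' @export
basis_lambda <- function(basis, j) {
  .basis_amplitude(basis) / basis_gamma(basis, j)
}

# Map data coordinates onto the natural domain. NULL map = identity.
map_input <- function(basis, t) {
  if (is.null(basis$map)) t else basis$map$scale * t + basis$map$offset
}

#' Calibrate the affine input map from training inputs
#'
#' Returns a copy of `basis` whose input map sends the training range into
#' the interior of the natural domain: compact domains get the range mapped
#' onto the central 96 percent (a 2 percent margin each side, so test
#' points slightly beyond the training range remain valid); the Laguerre
#' half-line maps the range onto \[0, m/2\], which keeps the mapped data
#' inside the numerically bounded oscillatory region of every retained
#' eigenfunction; the Hermite line
#' standardizes to zero mean and unit variance. A degenerate
#' (single-point) range is mapped to the domain centre.
#'
#' @param basis an [eigen_basis()].
#' @param t numeric vector of training inputs in data coordinates.
#' @export
fit_input_map <- function(basis, t) {
  stopifnot(inherits(basis, "eigen_basis"), is.numeric(t), length(t) >= 1)
  if (any(!is.finite(t))) stop("training inputs must be finite")
  rng <- range(t)
  span <- rng[2] - rng[1]
  fam <- basis$family
  if (fam == "hermite") {
    s <- stats::sd(t)
    if (length(t) < 2 || !is.finite(s) || s == 0) s <- 1
    map <- list(scale = 1 / s, offset = -mean(t) / s)
  } else if (fam == "laguerre") {
    # Keep mapped data inside the oscillatory region of all m retained
    # eigenfunctions: orthonormal Laguerre functions grow like e^{t/2}
    # beyond it, which destroys the conditioning of Phi'Phi.
    scale <- if (span > 0) (basis$m / 2) / span else 1
    map <- list(scale = scale, offset = -scale * rng[1])
  } else {
    dom <- basis_domain(basis)
    w <- dom[2] - dom[1]
    if (span > 0) {
      scale <- 0.96 * w / span
      map <- list(scale = scale, offset = dom[1] + 0.02 * w - scale * rng[1])
    } else {
      map <- list(scale = 1, offset = mean(dom) - rng[1])
    }
  }
  basis$map <- map
  basis
}

.in_domain <- function(family, t) {
  dom <- basis_domain(family)
  t >= dom[1] & t <= dom[2]
}

# Evaluate orthonormal eigenfunctions 1..jmax at natural-domain points.
# Returns length(t) x jmax matrix. Three-term recurrences throughout; the
# Hermite recurrence carries the normalization incrementally so 2^j j!
# never appears.
phi_matrix <- function(basis, t, jmax) {
  fam <- basis$family
  n <- length(t)
  bad <- !.in_domain(fam, t)
  if (any(bad))
    stop(sprintf("input outside the %s natural domain at position(s) %s",
                 fam, paste(utils::head(which(bad), 5L), collapse = ", ")))
  out <- matrix(NA_real_, n, jmax)
  if (fam == "matern") {
    for (j in seq_len(jmax)) out[, j] <- sqrt(2) * sin(j * pi * t)
    return(out)
  }
  if (fam == "chebyshev") {
    th <- acos(pmin(1, pmax(-1, t)))
    for (j in seq_len(jmax)) out[, j] <- cos(j * th) / sqrt(pi / 2)
    return(out)
  }
  if (fam == "legendre") {
    pm1 <- rep(1, n)                       # P_0
    p <- t                                 # P_1
    out[, 1] <- p * sqrt(3 / 2)
    if (jmax >= 2) for (j in 1:(jmax - 1)) {
      pp <- ((2 * j + 1) * t * p - j * pm1) / (j + 1)   # P_{j+1}
      pm1 <- p; p <- pp
      out[, j + 1] <- p * sqrt((2 * (j + 1) + 1) / 2)
    }
    return(out)
  }
  if (fam == "laguerre") {
    pm1 <- rep(1, n)                       # L_0, already orthonormal
    p <- 1 - t                             # L_1
    out[, 1] <- p
    if (jmax >= 2) for (j in 1:(jmax - 1)) {
      pp <- ((2 * j + 1 - t) * p - j * pm1) / (j + 1)
      pm1 <- p; p <- pp
      out[, j + 1] <- p
    }
    return(out)
  }
  if (fam == "hermite") {
    pm1 <- rep(pi^(-0.25), n)              # h_0 = H_0 / pi^{1/4}
    p <- sqrt(2) * t * pm1                 # h_1
    out[, 1] <- p
    if (jmax >= 2) for (j in 1:(jmax - 1)) {
      pp <- sqrt(2 / (j + 1)) * t * p - sqrt(j / (j + 1)) * pm1
      pm1 <- p; p <- pp
      out[, j + 1] <- p
    }
    return(out)
  }
  # jacobi: standard recurrence, then divide by the L2 norm
  a <- basis$alpha_jac; b <- basis$beta_jac
  pm1 <- rep(1, n)                                          # P_0
  p <- (a - b) / 2 + (a + b + 2) / 2 * t                    # P_1
  out[, 1] <- p / jacobi_norm(1, a, b)
  if (jmax >= 2) for (j in 1:(jmax - 1)) {
    c1 <- 2 * (j + 1) * (j + a + b + 1) * (2 * j + a + b)
    c2 <- (2 * j + a + b + 1) * (a^2 - b^2)
    c3 <- (2 * j + a + b) * (2 * j + a + b + 1) * (2 * j + a + b + 2)
    c4 <- 2 * (j + a) * (j + b) * (2 * j + a + b + 2)
    pp <- ((c2 + c3 * t) * p - c4 * pm1) / c1
    pm1 <- p; p <- pp
    out[, j + 1] <- p / jacobi_norm(j + 1, a, b)
  }
  out
}

# L2((-1,1), (1-t)^a (1+t)^b) norm of the standard Jacobi polynomial P_j^{(a,b)}:
# ||P_j||^2 = 2^(a+b+1) G(j+a+1) G(j+b+1) / ((2j+a+b+1) G(j+a+b+1) j!)
jacobi_norm <- function(j, a, b) {
  log_n2 <- (a + b + 1) * log(2) + lgamma(j + a + 1) + lgamma(j + b + 1) -
    log(2 * j + a + b + 1) - lgamma(j + a + b + 1) - lgamma(j + 1)
  exp(log_n2 / 2)
}

#' Orthonormal eigenfunction phi_j evaluated on the natural domain
#'
#' Eigenfunctions are orthonormal in \eqn{L^2(I, \rho)}: the classical
#' polynomial divided by its weighted L2 norm (Legendre
#' \eqn{\sqrt{2/(2j+1)}}, Hermite \eqn{\sqrt{\sqrt\pi\, 2^j j!}}, Chebyshev
#' \eqn{\sqrt{\pi/2}}, Jacobi the standard norm; Laguerre and the Matern
#' sines already have unit norm). Evaluation uses stable three-term
#' recurrences.
#'
#' @param basis an [eigen_basis()].
#' @param j eigenfunction index, a single integer >= 1.
#' @param t evaluation points in the NATURAL domain (no input map applied;
#'   use [design_matrix()] for data coordinates).
#' @return numeric vector of eigenfunction values.
#' @export
basis_phi <- function(basis, j, t) {
  stopifnot(inherits(basis, "eigen_basis"), length(j) == 1L)
  j <- .check_index(j)
  phi_matrix(basis, t, j)[, j]
}

#' Eigenfunction design matrix
#'
#' Builds the N x m matrix \eqn{\Phi_{ij} = \phi_j(a t_i + b)} where
#' (a, b) is the basis input map. Inputs are given in data coordinates.
#'
#' @param basis an [eigen_basis()].
#' @param t numeric vector of inputs in data coordinates, length >= 1.
#' @param m number of columns; defaults to the basis truncation order.
#' @return numeric `length(t) x m` matrix.
#' @export
design_matrix <- function(basis, t, m = basis$m) {
  stopifnot(inherits(basis, "eigen_basis"))
  if (!is.numeric(t) || length(t) < 1)
    stop("`t` must be a numeric vector of length >= 1")
  if (any(!is.finite(t))) stop("`t` contains non-finite values")
  u <- map_input(basis, t)
  bad <- !.in_domain(basis$family, u)
  if (any(bad))
    stop(sprintf(
      "mapped input falls outside the %s natural domain at position(s) %s",
      basis$family, paste(utils::head(which(bad), 5L), collapse = ", ")))
  phi_matrix(basis, u, m)
}

#' Truncation error (MISE) of the m-term expansion
#'
#' The mean integrated square error of truncating the Karhunen-Loeve
#' expansion after m terms equals the eigenvalue tail
#' \eqn{\xi_m = \sum_{j > m} \lambda_j}, available in closed (or rapidly
#' convergent) form per family: Legendre \eqn{1/(m+1)}; Laguerre
#' \eqn{\pi^2/6 - \sum_{j \le m} j^{-2}}; Hermite a quarter of that;
#' Chebyshev \eqn{\pi^4/90 - \sum_{j \le m} j^{-4}}; Jacobi
#' \eqn{(\psi(m+1+c) - \psi(m+1))/c} with \eqn{c = \alpha + \beta + 1};
#' Matern a numeric tail sum with an integral remainder bound. Scaled by
#' the basis amplitude, so the telescoping identity
#' `basis_mise(b, m) - basis_mise(b, m + 1) == basis_lambda(b, m + 1)` holds.
#'
#' @param basis an [eigen_basis()].
#' @param m number of retained terms, integer >= 0 (`0` = keep nothing).
#' @return nonnegative scalar, strictly decreasing in `m` with limit 0.
#' @export
basis_mise <- function(basis, m = basis$m) {
  stopifnot(inherits(basis, "eigen_basis"))
  if (!is.numeric(m) || length(m) != 1L || m < 0 || m != round(m))
    stop("`m` must be a nonnegative integer")
  amp <- .basis_amplitude(basis)
  js <- seq_len(m)
  tail_val <- switch(
    basis$family,
    legendre  = 1 / (m + 1),
    laguerre  = pi^2 / 6 - sum(1 / js^2),
    hermite   = (pi^2 / 6 - sum(1 / js^2)) / 4,
    chebyshev = pi^4 / 90 - sum(1 / js^4),
    jacobi    = {
      cc <- basis$alpha_jac + basis$beta_jac + 1
      if (abs(cc) < 1e-10) trigamma(m + 1)
      else (digamma(m + 1 + cc) - digamma(m + 1)) / cc
    },
    matern    = {
      f <- function(x) (basis$eps + (pi * x)^2)^(-basis$alpha)
      n_sum <- 2000L
      head_js <- (m + 1):(m + n_sum)
      rem <- stats::integrate(f, m + n_sum + 0.5, Inf,
                              rel.tol = 1e-12, abs.tol = 0)$value
      basis$sigma2 * (sum(f(head_js)) + rem)
    })
  if (basis$family == "matern") tail_val else amp * tail_val
}
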