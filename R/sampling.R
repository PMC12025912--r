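#' Sample GP prior realizations by Karhunen-Loeve expansion
#'
#' Draws paths \eqn{f_m(t) = \sum_{j=1}^m a_j \phi_j(t)} with independent
#' coefficients \eqn{a_j \sim N(0, \lambda_j)}. Reproducible given `seed`.
#'
#' @param basis an [eigen_basis()] with a resolved input map (or one whose
#'   natural domain already contains `grid`).
#' @param grid evaluation points in data coordinates.
#' @param n_paths number of independent realizations.
#' @param seed optional integer seed.
#' @return list of class `"kl_sample"`: `paths`
#'   (`length(grid) x n_paths`), `coefficients` (`m x n_paths`), `grid`,
#'   `lambda`, `seed`.
#' @export
sample_prior <- function(basis, grid, n_paths = 1L, seed = NULL) {
  stopifnot(inherits(basis, "eigen_basis"), n_paths >= 1)
  if (!is.null(seed)) set.seed(seed)
  m <- basis$m
  lam <- basis_lambda(basis, seq_len(m))
  P <- design_matrix(basis, grid)
  a <- matrix(stats::rnorm(m * n_paths, sd = sqrt(lam)), m, n_paths)
  structure(list(paths = P %*% a, coefficients = a, grid = grid,
                 lambda = lam, seed = seed),
            class = "kl_sample")
}

#' Eigenvalues of the Brownian motion / bridge expansions
#'
#' Brownian motion on \[0,1\] (covariance \eqn{\min(t,s)}) has
#' \eqn{\lambda_j = 4/((2j-1)^2\pi^2)} with eigenfunctions
#' \eqn{\sqrt2 \sin((2j-1)\pi t/2)}; the Brownian bridge (covariance
#' \eqn{\min(t,s) - ts}) has \eqn{\lambda_j = 1/(j^2\pi^2)} with
#' \eqn{\sqrt2\sin(j\pi t)}.
#'
#' @param kind `"motion"` or `"bridge"`.
#' @param j index vector, j >= 1.
#' @export
brownian_eigenvalues <- function(kind = c("motion", "bridge"), j) {
  kind <- match.arg(kind)
  j <- .check_index(j)
  if (kind == "motion") 4 / ((2 * j - 1)^2 * pi^2) else 1 / (j * pi)^2
}

#' Sample Brownian motion or bridge via the truncated eigen-series
#'
#' Implements the classical sine expansions (see
#' [brownian_eigenvalues()]) with independent standard-normal
#' coefficients.
#'
#' @param kind `"motion"` or `"bridge"`.
#' @param m_terms number of series terms.
#' @param grid evaluation points in \[0,1\].
#' @param n_paths number of realizations.
#' @param seed optional integer seed.
#' @return list of class `"kl_sample"` (paths, coefficients on the
#'   standard-normal scale, grid, lambda, seed).
#' @export
sample_brownian <- function(kind = c("motion", "bridge"), m_terms, grid,
                            n_paths = 1L, seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(m_terms >= 1, n_paths >= 1)
  if (any(grid < 0 | grid > 1)) stop("`grid` must lie in [0,1]")
  if (!is.null(seed)) set.seed(seed)
  j <- seq_len(m_terms)
  lam <- brownian_eigenvalues(kind, j)
  Phi <- if (kind == "motion")
    outer(grid, j, function(t, j) sqrt(2) * sin((2 * j - 1) * pi * t / 2))
  else
    outer(grid, j, function(t, j) sqrt(2) * sin(j * pi * t))
  a_std <- matrix(stats::rnorm(m_terms * n_paths), m_terms, n_paths)
  structure(list(paths = Phi %*% (sqrt(lam) * a_std),
                 coefficients = a_std, grid = grid, lambda = lam,
                 seed = seed),
            class = "kl_sample")
}

#' True functions of the simulation benchmarks
#'
#' Benchmark 1 is the Beta(2,5) probability density
#' \eqn{f(t) = 30\,t(1-t)^4}; benchmark 2 is the quasi-periodic
#' \eqn{f(t) = t\sin(10t)}. Both live on \[0,1\].
#'
#' @param sim 1 or 2.
#' @return a vectorized function of t.
#' @export
simulation_truth <- function(sim) {
  if (sim == 1) function(t) stats::dbeta(t, 2, 5)
  else if (sim == 2) function(t) t * sin(10 * t)
  else stop("`sim` must be 1 or 2")
}

#' Generate a synthetic regression benchmark
#'
#' Draws inputs on \[0,1\] (uniform at random by default, equispaced on
#' request), evaluates the benchmark truth ([simulation_truth()]), adds
#' i.i.d. Gaussian noise of variance `noise_var`, and splits into a
#' training and a disjoint test part. Defaults follow the benchmark
#' protocol: 140 observations, 40 for training, noise variance 0.1.
#'
#' @param sim benchmark id, 1 (Beta(2,5) density) or 2 (t sin(10t)).
#' @param n_total,n_train total and training sizes, `n_train < n_total`.
#' @param noise_var noise variance (0 gives noiseless responses).
#' @param seed optional integer seed.
#' @param design `"uniform"` (random uniform inputs) or `"equispaced"`.
#' @return list of class `"regression_dataset"`: `t_train`, `y_train`,
#'   `t_test`, `y_test`, `truth` (function), `sim`, `noise_var`, `seed`.
#' @export
simulate_dataset <- function(sim, n_total = 140L, n_train = 40L,
                             noise_var = 0.1, seed = NULL,
                             design = c("uniform", "equispaced")) {
  design <- match.arg(design)
  if (n_train >= n_total || n_train < 1)
    stop("need 1 <= n_train < n_total")
  if (noise_var < 0) stop("`noise_var` must be >= 0")
  f <- simulation_truth(sim)
  if (!is.null(seed)) set.seed(seed)
  t_all <- if (design == "uniform") stats::runif(n_total)
  else seq(0, 1, length.out = n_total)
  y_all <- f(t_all)
  if (noise_var > 0)
    y_all <- y_all + stats::rnorm(n_total, sd = sqrt(noise_var))
  idx <- sample.int(n_total, n_train)
  structure(
    list(t_train = t_all[idx], y_train = y_all[idx],
         t_test = t_all[-idx], y_test = y_all[-idx],
         truth = f, sim = sim, noise_var = noise_var, seed = seed),
    class = "regression_dataset")
}

#' @export
print.regression_dataset <- function(x, ...) {
  cat(sprintf("Regression dataset: %d train + %d test, noise_var = %g\n",
              length(x$t_train), length(x$t_test), x$noise_var))
  invisible(x)
}

#' Integrated squared error of a prediction against the truth
#'
#' The average squared difference between the predicted and the true
#' function over the evaluation points (default), or the trapezoid-rule
#' integral of the squared difference normalized by the grid span
#' (`method = "trapezoid"`, requires `grid`).
#'
#' @param pred predicted values.
#' @param truth true function values, same length.
#' @param method `"mean"` or `"trapezoid"`.
#' @param grid evaluation points, required (sorted) for the trapezoid rule.
#' @return nonnegative scalar.
#' @export
ise <- function(pred, truth, method = c("mean", "trapezoid"), grid = NULL) {
  method <- match.arg(method)
  if (length(pred) != length(truth))
    stop("`pred` and `truth` must have the same length")
  d2 <- (pred - truth)^2
  if (method == "mean") return(mean(d2))
  if (is.null(grid) || length(grid) != length(pred))
    stop("trapezoid ISE needs a `grid` of matching length")
  o <- order(grid)
  pracma::trapz(grid[o], d2[o]) / diff(range(grid))
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum(y - \hat y)^2 / \sum(y - \bar y)^2}. Values can be
#' negative when the predictor does worse than the observed mean.
#'
#' @param pred predicted values.
#' @param obs observed (or true) values, length >= 2, non-constant.
#' @return scalar <= 1.
#' @export
r_squared <- function(pred, obs) {
  if (length(pred) != length(obs))
    stop("`pred` and `obs` must have the same length")
  if (length(obs) < 2) stop("need at least two observations for R-squared")
  ss_tot <- sum((obs - mean(obs))^2)
  if (ss_tot == 0) stop("R-squared undefined: observations have zero variance")
  1 - sum((obs - pred)^2) / ss_tot
}
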