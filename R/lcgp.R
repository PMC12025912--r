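#' Fit a low-complexity (reduced-rank) GP regression
#'
#' Fits the model \eqn{y_i = f_m(t_i) + \tau_i}, \eqn{\tau_i \sim N(0,
#' \sigma_N^2)}, where \eqn{f_m} has the rank-m covariance of the supplied
#' eigenbasis. Only m x m quantities are ever stored: the design matrix is
#' streamed in row blocks to accumulate \eqn{\Phi^\top\Phi},
#' \eqn{\Phi^\top y} and \eqn{y^\top y}, so fitting costs O(N m^2) time and
#' O(m^2) memory.
#'
#' Numerically, the normal-equations matrix \eqn{M = \Phi^\top\Phi +
#' \sigma_N^2\Gamma^{-1}} is factored in whitened form \eqn{M' =
#' \Gamma^{1/2}\Phi^\top\Phi\,\Gamma^{1/2} + \sigma_N^2 I}, which avoids
#' forming \eqn{\Gamma^{-1}} when the spectrum decays fast; predictions and
#' the marginal likelihood are algebraically unchanged. If the Cholesky
#' factorization fails, a jitter of `1e-10 * mean(diag(M'))` is added once
#' (with a warning); a second failure is an error reporting the spectrum
#' ratio.
#'
#' @param basis an [eigen_basis()]. If its input map is unset (`NULL`) it
#'   is calibrated from `t` via [fit_input_map()] and stored in the fit.
#' @param t numeric vector of training inputs (data coordinates).
#' @param y numeric response vector, same length as `t`.
#' @param noise_var observation noise variance \eqn{\sigma_N^2}, > 0.
#' @param center subtract the training-response mean before fitting (and
#'   add it back in predictions)? The eigenbases exclude the constant mode
#'   (their eigenfunctions integrate to zero against the weight), so the
#'   prior is zero-mean in a strong sense; centering is recommended
#'   whenever the responses have a nonzero level. Off by default.
#' @param chunk_size rows per streaming block.
#' @return An object of class `"lcgp_fit"` with elements `basis` (map
#'   resolved), `noise_var`, `chol_w` (upper-triangular Cholesky factor of
#'   the whitened M'), `proj_data` (\eqn{\Phi^\top y}), `data_sq_norm`
#'   (\eqn{y^\top y}) and `n_train`.
#' @examples
#' b <- eigen_basis("matern", m = 1, sigma2 = 1, eps = 0, alpha = 1)
#' fit <- lcgp_fit(b, t = 0.5, y = 1, noise_var = 1)
#' predict(fit, 0.5)$mean      # 2 / (2 + pi^2)
#' log_marginal(fit)
#' @seealso [predict.lcgp_fit()], [log_marginal()], [lcgp_learn()]
#' @export
lcgp_fit <- function(basis, t, y, noise_var, center = FALSE,
                     chunk_size = 4096L) {
  stopifnot(inherits(basis, "eigen_basis"))
  n <- length(t)
  if (n < 1) stop("need at least one observation")
  if (length(y) != n) stop("`t` and `y` must have the same length")
  if (any(!is.finite(t)) || any(!is.finite(y)))
    stop("`t` and `y` must be finite")
  if (!is.numeric(noise_var) || length(noise_var) != 1L || noise_var <= 0)
    stop("`noise_var` must be a positive scalar")
  if (is.null(basis$map)) basis <- fit_input_map(basis, t)
  y_offset <- if (isTRUE(center)) mean(y) else 0
  y <- y - y_offset

  m <- basis$m
  lam <- basis_lambda(basis, seq_len(m))
  if (lam[1] / lam[m] > 1e12)
    warning(sprintf(
      "spectrum ratio lambda_1/lambda_m = %.3g > 1e12: system may be ill-conditioned",
      lam[1] / lam[m]))
  sl <- sqrt(lam)

  A <- matrix(0, m, m)       # Phi^T Phi
  b <- numeric(m)            # Phi^T y
  yty <- 0
  chunk_size <- max(1L, as.integer(chunk_size))
  for (start in seq(1L, n, by = chunk_size)) {
    idx <- start:min(start + chunk_size - 1L, n)
    P <- design_matrix(basis, t[idx])
    A <- A + crossprod(P)
    b <- b + drop(crossprod(P, y[idx]))
    yty <- yty + sum(y[idx]^2)
  }

  Mw <- (sl %o% sl) * A
  diag(Mw) <- diag(Mw) + noise_var
  R <- tryCatch(chol(Mw), error = function(e) NULL)
  if (is.null(R)) {
    warning("Cholesky failed; adding jitter 1e-10 * mean(diag(M'))")
    diag(Mw) <- diag(Mw) + 1e-10 * mean(diag(Mw))
    R <- tryCatch(chol(Mw), error = function(e)
      stop(sprintf(
        "Cholesky failed after jitter; spectrum ratio lambda_1/lambda_m = %.3g",
        lam[1] / lam[m])))
  }

  structure(
    list(basis = basis, noise_var = noise_var, chol_w = R,
         sqrt_lambda = sl, proj_data = b, data_sq_norm = yty,
         n_train = n, y_offset = y_offset),
    class = "lcgp_fit")
}

#' @export
print.lcgp_fit <- function(x, ...) {
  cat(sprintf(
    "Low-complexity GP fit: %s basis, m = %d, N = %d, noise_var = %g\n",
    x$basis$family, x$basis$m, x$n_train, x$noise_var))
  cat(sprintf("  log marginal likelihood: %.4f\n", log_marginal(x)))
  invisible(x)
}

#' Cholesky factor of M = Phi'Phi + sigma_N^2 Gamma^{-1}
#'
#' Recovers the lower-triangular factor of the unwhitened normal-equations
#' matrix from the stored whitened factor (\eqn{L = \Gamma^{-1/2} L'}).
#'
#' @param object an [lcgp_fit()] result.
#' @return lower-triangular m x m matrix `L` with `L %*% t(L) == M`.
#' @export
lcgp_chol <- function(object) {
  stopifnot(inherits(object, "lcgp_fit"))
  t(object$chol_w) / object$sqrt_lambda
}

#' Predictive mean and variance of a reduced-rank GP fit
#'
#' Computes \eqn{\bar f_\star = \phi_\star^\top M^{-1}\Phi^\top y} and
#' \eqn{v(f_\star) = \sigma_N^2\,\phi_\star^\top M^{-1}\phi_\star} via
#' triangular solves with the stored m x m factor; O(m^2) per test point.
#' By default the variance is the latent-function variance; set
#' `include_noise = TRUE` to add \eqn{\sigma_N^2} for predictive intervals
#' on new noisy observations.
#'
#' @param object an [lcgp_fit()] result.
#' @param t_star numeric vector of test inputs (data coordinates).
#' @param include_noise add the noise variance to the predictive variance?
#' @param ... unused.
#' @return list of class `"gp_prediction"` with `mean`, `variance`
#'   (both length `length(t_star)`) and `include_noise`.
#' @export
predict.lcgp_fit <- function(object, t_star, include_noise = FALSE, ...) {
  if (missing(t_star)) stop("`t_star` is required")
  Pw <- design_matrix(object$basis, t_star)
  Pw <- sweep(Pw, 2, object$sqrt_lambda, "*")       # whitened phi_star rows
  R <- object$chol_w
  qw <- object$sqrt_lambda * object$proj_data
  w <- backsolve(R, backsolve(R, qw, transpose = TRUE))
  Z <- backsolve(R, t(Pw), transpose = TRUE)        # m x N*
  variance <- object$noise_var * colSums(Z^2)
  if (include_noise) variance <- variance + object$noise_var
  structure(list(mean = drop(Pw %*% w) + object$y_offset,
                 variance = variance,
                 include_noise = include_noise),
            class = "gp_prediction")
}

#' @export
print.gp_prediction <- function(x, ...) {
  df <- data.frame(mean = x$mean, variance = x$variance)
  cat(sprintf("GP prediction (%d points, %s noise):\n", nrow(df),
              if (x$include_noise) "with" else "without"))
  print(utils::head(df, 10), ...)
  if (nrow(df) > 10) cat(sprintf("  ... %d more rows\n", nrow(df) - 10))
  invisible(x)
}

#' Log marginal likelihood
#'
#' Generic for the log evidence \eqn{\log P(y \mid t, \theta)} of a fitted
#' GP. For reduced-rank fits the determinant-lemma form is used,
#' \deqn{l(\theta) = -\tfrac12 (N - m)\log\sigma_N^2 - \tfrac12\log|M'| -
#' \tfrac{1}{2\sigma_N^2}\bigl(y^\top y - q^\top M'^{-1} q\bigr) -
#' \tfrac{N}{2}\log 2\pi,}
#' with \eqn{q = \Gamma^{1/2}\Phi^\top y}, evaluated from the stored m x m
#' Cholesky factor only (\eqn{\log|M'| = 2\sum_j \log L'_{jj}}), so the cost
#' is O(m^3) after fitting. For exact fits it is the classical
#' \eqn{-\tfrac12\log|K + \sigma_N^2 I| - \tfrac12 y^\top (K +
#' \sigma_N^2 I)^{-1} y - \tfrac{N}{2}\log 2\pi}.
#'
#' @param object a fitted model ([lcgp_fit()] or [cgp_fit()]).
#' @param ... unused.
#' @return scalar log marginal likelihood.
#' @export
log_marginal <- function(object, ...) UseMethod("log_marginal")

#' @export
log_marginal.lcgp_fit <- function(object, ...) {
  R <- object$chol_w
  n <- object$n_train
  m <- object$basis$m
  s2 <- object$noise_var
  qw <- object$sqrt_lambda * object$proj_data
  z <- backsolve(R, qw, transpose = TRUE)
  quad <- object$data_sq_norm - sum(z^2)
  -0.5 * (n - m) * log(s2) - sum(log(diag(R))) - quad / (2 * s2) -
    n / 2 * log(2 * pi)
}
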