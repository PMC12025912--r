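#' Exact (canonical) GP regression
#'
#' The O(N^3) reference implementation: Cholesky-factor
#' \eqn{K + \sigma_N^2 I} and solve for the weights
#' \eqn{(K + \sigma_N^2 I)^{-1} y}. It is the correctness oracle for the
#' reduced-rank path (on the rank-m kernel both must agree to rounding by
#' the matrix-inversion lemma) and the `std-gp` baseline for small N.
#'
#' A hard cap on N (default 2000) guards against accidental cubic blowups;
#' pass `force = TRUE` to override.
#'
#' @param kernel a [canonical_kernel()] or [truncated_kernel()].
#' @param t,y training inputs and responses.
#' @param noise_var noise variance, > 0.
#' @param center subtract the training-response mean before fitting (added
#'   back in predictions)? See [lcgp_fit()].
#' @param max_n size cap.
#' @param force override the cap.
#' @return object of class `"cgp_fit"`.
#' @export
cgp_fit <- function(kernel, t, y, noise_var, center = FALSE,
                    max_n = 2000L, force = FALSE) {
  n <- length(t)
  if (n < 1) stop("need at least one observation")
  if (length(y) != n) stop("`t` and `y` must have the same length")
  if (!is.numeric(noise_var) || noise_var <= 0)
    stop("`noise_var` must be a positive scalar")
  if (n > max_n && !force)
    stop(sprintf(
      "N = %d exceeds the canonical-GP cap (%d); cost is O(N^3). Use force = TRUE or lcgp_fit().",
      n, max_n))
  if (inherits(kernel, "truncated_kernel") && is.null(kernel$basis$map))
    kernel$basis <- fit_input_map(kernel$basis, t)
  y_offset <- if (isTRUE(center)) mean(y) else 0
  y <- y - y_offset
  K <- kernel_gram(kernel, t)
  Kn <- K + diag(noise_var, n)
  R <- chol(Kn)
  weights <- backsolve(R, backsolve(R, y, transpose = TRUE))
  structure(list(kernel = kernel, t = t, y = y, noise_var = noise_var,
                 chol = R, weights = weights, n_train = n,
                 y_offset = y_offset),
            class = "cgp_fit")
}

#' Predictive distribution of an exact GP fit
#'
#' Mean \eqn{k_\star^\top (K + \sigma_N^2 I)^{-1} y} and variance
#' \eqn{k(t_\star,t_\star) - k_\star^\top (K + \sigma_N^2 I)^{-1}
#' k_\star}. Round-off can push the variance marginally negative; values
#' above -1e-8 are clipped silently to 0, anything lower is clipped with a
#' warning.
#'
#' @param object a [cgp_fit()] result.
#' @param t_star test inputs.
#' @param include_noise add the noise variance?
#' @param ... unused.
#' @return list of class `"gp_prediction"` (see [predict.lcgp_fit()]).
#' @export
predict.cgp_fit <- function(object, t_star, include_noise = FALSE, ...) {
  if (missing(t_star)) stop("`t_star` is required")
  ks <- kernel_gram(object$kernel, object$t, t_star)   # N x N*
  mean <- drop(crossprod(ks, object$weights)) + object$y_offset
  V <- backsolve(object$chol, ks, transpose = TRUE)
  variance <- kernel_diag(object$kernel, t_star) - colSums(V^2)
  if (any(variance < -1e-8))
    warning(sprintf("predictive variance clipped from %.3g to 0",
                    min(variance)))
  variance <- pmax(variance, 0)
  if (include_noise) variance <- variance + object$noise_var
  structure(list(mean = mean, variance = variance,
                 include_noise = include_noise),
            class = "gp_prediction")
}

#' @export
log_marginal.cgp_fit <- function(object, ...) {
  z <- backsolve(object$chol, object$y, transpose = TRUE)
  -sum(log(diag(object$chol))) - 0.5 * sum(z^2) -
    object$n_train / 2 * log(2 * pi)
}

#' @export
print.cgp_fit <- function(x, ...) {
  kind <- if (inherits(x$kernel, "truncated_kernel"))
    sprintf("truncated %s (m = %d)", x$kernel$basis$family, x$kernel$basis$m)
  else x$kernel$kind
  cat(sprintf("Canonical GP fit: %s kernel, N = %d, noise_var = %g\n",
              kind, x$n_train, x$noise_var))
  invisible(x)
}
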