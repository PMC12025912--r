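# Hyperparameter learning: gradient ascent on the approximate log marginal
# likelihood, with parameters handled on the log scale so positivity is
# automatic.

# Names of the tunable kernel parameters for a basis family.
tunable_params <- function(basis, learn_noise = TRUE) {
  nm <- switch(basis$family,
               matern = c("sigma2", "eps"),
               if (basis$amplitude) "sigma2" else character())
  if (learn_noise) nm <- c(nm, "noise_var")
  nm
}

# Rebuild the basis / noise from a named log-parameter vector.
apply_theta <- function(basis, noise_var, theta_log) {
  th <- exp(theta_log)
  for (nm in names(th)) {
    if (nm == "noise_var") noise_var <- th[[nm]]
    else basis[[nm]] <- th[[nm]]
  }
  list(basis = basis, noise_var = noise_var)
}

lml_objective <- function(basis, t, y, noise_var) {
  function(theta_log) {
    st <- apply_theta(basis, noise_var, theta_log)
    log_marginal(lcgp_fit(st$basis, t, y, st$noise_var))
  }
}

#' Gradient of the approximate log marginal likelihood
#'
#' Central finite differences of the reduced-rank log marginal likelihood
#' with respect to each log-parameter, step
#' `fd_step * (1 + |log theta_j|)` per coordinate. Each evaluation rebuilds
#' the m x m system, so a full gradient costs O(p (N m^2 + m^3)) for p
#' parameters. If the likelihood is non-finite at a perturbed point the
#' step is halved up to 20 times before erroring.
#'
#' @param basis an [eigen_basis()]; its input map should already be
#'   calibrated (it is held fixed during differentiation).
#' @param t,y training data.
#' @param noise_var current noise variance.
#' @param params which parameters to differentiate; defaults to the
#'   family's tunable set plus the noise variance.
#' @param fd_step base relative step of the central difference.
#' @return named gradient vector in log-parameter space.
#' @export
lcgp_lml_gradient <- function(basis, t, y, noise_var,
                              params = tunable_params(basis),
                              fd_step = 1e-4) {
  if (is.null(basis$map)) basis <- fit_input_map(basis, t)
  theta_log <- current_theta_log(basis, noise_var, params)
  obj <- lml_objective(basis, t, y, noise_var)
  fd_gradient(obj, theta_log, fd_step)
}

current_theta_log <- function(basis, noise_var, params) {
  vals <- vapply(params, function(nm)
    if (nm == "noise_var") noise_var else basis[[nm]], numeric(1))
  if (any(vals <= 0))
    stop("all tunable parameters must be strictly positive")
  stats::setNames(log(vals), params)
}

fd_gradient <- function(obj, theta_log, fd_step) {
  g <- numeric(length(theta_log))
  names(g) <- names(theta_log)
  if (length(theta_log) == 0) return(g)
  for (i in seq_along(theta_log)) {
    h <- fd_step * (1 + abs(theta_log[i]))
    for (try in 1:20) {
      up <- theta_log; up[i] <- up[i] + h
      dn <- theta_log; dn[i] <- dn[i] - h
      lu <- obj(up); ld <- obj(dn)
      if (is.finite(lu) && is.finite(ld)) {
        g[i] <- (lu - ld) / (2 * h)
        break
      }
      h <- h / 2
      if (try == 20)
        stop("non-finite likelihood at perturbed parameters; cannot form gradient")
    }
  }
  g
}

#' Learn hyperparameters by gradient ascent on the marginal likelihood
#'
#' Ascends the reduced-rank log marginal likelihood in log-parameter space,
#' \eqn{\theta_j \leftarrow \theta_j + \eta g_j}, with backtracking halving
#' of the step whenever a proposal would decrease the objective, so the
#' returned likelihood trace is non-decreasing. Iteration stops when the
#' gradient norm drops below `tol`, when no halved step improves, or after
#' `max_iters` iterations.
#'
#' The tunable set depends on the family: `(sigma2, eps)` for the Matern
#' basis, the global amplitude `sigma2` for polynomial families (when the
#' basis carries one), plus the noise variance unless
#' `learn_noise = FALSE`. The truncation order m and the Matern smoothness
#' alpha are integers and are never optimized; compare fits at different
#' values via [log_marginal()]. Individual parameters can be frozen with
#' `fix`.
#'
#' @param basis starting [eigen_basis()] (its parameter values are the
#'   initialization). The input map is calibrated once from `t` and held
#'   fixed.
#' @param t,y training data.
#' @param noise_var initial noise variance.
#' @param learn_noise include the noise variance in the optimization?
#' @param center subtract the training-response mean before fitting? See
#'   [lcgp_fit()]; the returned fit carries the offset.
#' @param inits optional list of named numeric vectors of starting values
#'   (on the natural, not log, scale), e.g.
#'   `list(c(sigma2 = 1), c(sigma2 = 5))`. The ascent is run from each
#'   start (the basis values fill in unnamed parameters) and the result
#'   with the highest final likelihood is returned. The marginal
#'   likelihood is multimodal in the kernel parameters; a small
#'   deterministic ladder of starts, e.g. from [lcgp_default_inits()],
#'   is cheap insurance.
#' @param fix character vector of parameter names to freeze.
#' @param eta initial learning rate.
#' @param tol stop when the gradient norm falls below this.
#' @param max_iters iteration cap.
#' @param fd_step finite-difference step, see [lcgp_lml_gradient()].
#' @return list of class `"lcgp_learn"`: `basis` and `noise_var` at the
#'   optimum, `theta` (named optimized values), `trace` (log marginal
#'   likelihood per accepted iterate, non-decreasing), `iterations`,
#'   `converged`, and `fit` (the [lcgp_fit()] at the optimum).
#' @examples
#' set.seed(7)
#' d <- simulate_dataset(1, seed = 7)
#' b <- eigen_basis("matern", m = 25, sigma2 = 1, eps = 1, alpha = 1)
#' opt <- lcgp_learn(b, d$t_train, d$y_train, noise_var = 0.1,
#'                   max_iters = 50)
#' opt$theta
#' @export
lcgp_learn <- function(basis, t, y, noise_var = 0.1, learn_noise = TRUE,
                       center = FALSE, inits = NULL, fix = character(),
                       eta = 0.1, tol = 1e-5, max_iters = 500L,
                       fd_step = 1e-4) {
  stopifnot(inherits(basis, "eigen_basis"))
  if (eta <= 0) stop("`eta` must be > 0")
  if (tol <= 0) stop("`tol` must be > 0")
  if (max_iters < 1) stop("`max_iters` must be >= 1")
  if (any(!is.finite(t)) || any(!is.finite(y)))
    stop("`t` and `y` must be finite")
  if (is.null(basis$map)) basis <- fit_input_map(basis, t)
  y_offset <- if (isTRUE(center)) mean(y) else 0
  y <- y - y_offset

  if (!is.null(inits)) {
    runs <- lapply(inits, function(init) {
      b <- basis
      for (nm in names(init)) {
        if (nm == "noise_var") noise_var <- init[[nm]]
        else b[[nm]] <- init[[nm]]
      }
      lcgp_learn(b, t, y, noise_var = noise_var,
                 learn_noise = learn_noise, center = FALSE, fix = fix,
                 eta = eta, tol = tol, max_iters = max_iters,
                 fd_step = fd_step)
    })
    best <- runs[[which.max(vapply(runs, function(r)
      utils::tail(r$trace, 1), numeric(1)))]]
    best$fit$y_offset <- y_offset
    return(best)
  }

  params <- setdiff(tunable_params(basis, learn_noise), fix)
  obj <- lml_objective(basis, t, y, noise_var)
  theta_log <- current_theta_log(basis, noise_var, params)
  l_cur <- obj(theta_log)
  if (!is.finite(l_cur)) stop("non-finite likelihood at the initial parameters")
  trace <- l_cur
  converged <- length(params) == 0L
  iter <- 0L

  while (!converged && iter < max_iters) {
    iter <- iter + 1L
    g <- fd_gradient(obj, theta_log, fd_step)
    if (sqrt(sum(g^2)) < tol) {
      converged <- TRUE
      break
    }
    step <- eta
    accepted <- FALSE
    for (half in 1:30) {
      cand <- theta_log + step * g
      l_new <- obj(cand)
      if (is.finite(l_new) && l_new >= l_cur) {
        theta_log <- cand
        l_cur <- l_new
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break          # no ascent direction at this resolution
    trace <- c(trace, l_cur)
  }

  st <- apply_theta(basis, noise_var, theta_log)
  fit <- lcgp_fit(st$basis, t, y, st$noise_var)
  fit$y_offset <- y_offset
  structure(
    list(basis = st$basis, noise_var = st$noise_var,
         theta = exp(theta_log), trace = trace, iterations = iter,
         converged = converged, fit = fit),
    class = "lcgp_learn")
}

#' Default multi-start initializations for hyperparameter learning
#'
#' A small deterministic ladder of starting values: the basis amplitude at
#' 1 and at a moment-matched value (three times the response variance,
#' since the prior marginal variance of these bases is a modest fraction
#' of the amplitude), and for the Matern family shape values spanning
#' smooth (`eps = 1`) to rough (`eps = 100`) regimes.
#'
#' @param basis an [eigen_basis()].
#' @param y training responses (after any centering).
#' @return list of named numeric vectors suitable for
#'   [lcgp_learn()]'s `inits`.
#' @export
lcgp_default_inits <- function(basis, y) {
  v <- max(stats::var(y), 1e-8)
  if (basis$family == "matern")
    list(c(sigma2 = 1, eps = 1), c(sigma2 = 3 * v, eps = 1),
         c(sigma2 = 3 * v, eps = 100))
  else
    list(c(sigma2 = 1), c(sigma2 = 3 * v))
}

#' @export
print.lcgp_learn <- function(x, ...) {
  cat(sprintf(
    "Hyperparameter learning: %d iteration(s), %sconverged\n",
    x$iterations, if (x$converged) "" else "not "))
  cat("  theta* =", paste(sprintf("%s = %.4g", names(x$theta), x$theta),
                          collapse = ", "), "\n")
  cat(sprintf("  log marginal likelihood: %.4f\n", utils::tail(x$trace, 1)))
  invisible(x)
}
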