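# Dataset I/O and the fit-predict-report pipeline.
#
# Errors are classed so the command-line front-end can map them to stable
# exit codes: lcgp_input_error (bad data), lcgp_numerical_error,
# lcgp_config_error.

lcgp_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "lcgp_error")))
}

#' Read a regression dataset from CSV
#'
#' Expects a header row and numeric `t` and `y` columns; an optional
#' `split` column with values `"train"`/`"test"` and an optional numeric
#' `truth` column are honoured. Rows containing non-finite values in the
#' used columns are dropped with a warning naming them.
#'
#' @param path CSV file path (comma-separated, `.` decimal, UTF-8).
#' @param t_col,y_col column names for inputs and responses.
#' @param split_col,truth_col optional column names.
#' @return list of class `"regression_dataset"` (see
#'   [simulate_dataset()]); without a split column all rows are training
#'   data. Truth values, when present, are stored as `truth_train` /
#'   `truth_test` vectors.
#' @export
read_regression_csv <- function(path, t_col = "t", y_col = "y",
                                split_col = "split", truth_col = "truth") {
  if (!file.exists(path))
    lcgp_stop(paste0("file not found: ", path), "lcgp_input_error")
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   lcgp_stop(paste0("cannot parse CSV: ", conditionMessage(e)),
                             "lcgp_input_error"))
  if (nrow(df) == 0)
    lcgp_stop("empty dataset", "lcgp_input_error")
  for (col in c(t_col, y_col))
    if (!col %in% names(df))
      lcgp_stop(paste0("missing required column `", col, "`"),
                "lcgp_input_error")
  t <- suppressWarnings(as.numeric(df[[t_col]]))
  y <- suppressWarnings(as.numeric(df[[y_col]]))
  has_truth <- truth_col %in% names(df)
  tr <- if (has_truth) suppressWarnings(as.numeric(df[[truth_col]])) else NULL
  ok <- is.finite(t) & is.finite(y)
  if (has_truth) ok <- ok & is.finite(tr)
  if (!all(ok)) {
    warning(sprintf("dropping %d row(s) with non-finite values: %s",
                    sum(!ok),
                    paste(utils::head(which(!ok), 10L), collapse = ", ")))
    t <- t[ok]; y <- y[ok]
    if (has_truth) tr <- tr[ok]
  }
  if (length(t) == 0)
    lcgp_stop("no usable rows after filtering", "lcgp_input_error")
  is_test <- if (split_col %in% names(df))
    df[[split_col]][ok] == "test" else rep(FALSE, length(t))
  out <- structure(
    list(t_train = t[!is_test], y_train = y[!is_test],
         t_test = t[is_test], y_test = y[is_test],
         truth = NULL, noise_var = NA_real_, seed = NULL),
    class = "regression_dataset")
  if (has_truth) {
    out$truth_train <- tr[!is_test]
    out$truth_test <- tr[is_test]
  }
  out
}

#' Write a dataset to CSV
#'
#' Columns `t`, `y`, `split` and, when the truth function or stored truth
#' values are available, `truth`.
#'
#' @param dataset a `"regression_dataset"`.
#' @param path output CSV path.
#' @export
write_regression_csv <- function(dataset, path) {
  t <- c(dataset$t_train, dataset$t_test)
  y <- c(dataset$y_train, dataset$y_test)
  split <- c(rep("train", length(dataset$t_train)),
             rep("test", length(dataset$t_test)))
  df <- data.frame(t = t, y = y, split = split)
  if (is.function(dataset$truth)) df$truth <- dataset$truth(t)
  else if (!is.null(dataset$truth_train))
    df$truth <- c(dataset$truth_train, dataset$truth_test)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Resolve a user config (defaults + validation). Returns the full config.
resolve_config <- function(config) {
  defaults <- list(
    family = "matern", m = 25L, sigma2 = 1, eps = 1, alpha_smooth = 1L,
    alpha_jac = -0.5, beta_jac = -0.3, amplitude = TRUE,
    method = "lcgp", noise_var = 0.1, learn = FALSE, center = TRUE,
    learn_noise = TRUE, multistart = TRUE,
    eta = 0.1, tol = 1e-5, max_iters = 500L,
    fix = character(), include_noise = FALSE, seed = NULL,
    t_col = "t", y_col = "y",
    data = NULL, predictions_out = NULL, report_out = NULL)
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown) > 0)
    lcgp_stop(paste0("unknown config key(s): ",
                     paste(unknown, collapse = ", ")), "lcgp_config_error")
  cfg <- utils::modifyList(defaults, config)
  if (!cfg$method %in% c("lcgp", "std-gp"))
    lcgp_stop("`method` must be \"lcgp\" or \"std-gp\"", "lcgp_config_error")
  if (!cfg$family %in% c("matern", "legendre", "laguerre", "hermite",
                         "chebyshev", "jacobi"))
    lcgp_stop(paste0("unknown family: ", cfg$family), "lcgp_config_error")
  cfg
}

config_basis <- function(cfg) {
  eigen_basis(cfg$family, m = cfg$m, sigma2 = cfg$sigma2, eps = cfg$eps,
              alpha = cfg$alpha_smooth, alpha_jac = cfg$alpha_jac,
              beta_jac = cfg$beta_jac, amplitude = cfg$amplitude)
}

# Pull inputs that fall (marginally) outside the invertible preimage of
# the natural domain back to its edge, so the tool can always predict at
# every requested point; the library-level design_matrix() stays strict.
clamp_to_domain <- function(basis, t) {
  if (is.null(basis$map)) return(t)
  dom <- basis_domain(basis)
  a <- basis$map$scale; b <- basis$map$offset
  bounds <- sort((dom - b) / a)
  # nudge inward so the forward map cannot overshoot the boundary by a ulp
  nudge <- 1e-12 * pmax(1, abs(bounds))
  bounds <- bounds + c(nudge[1], -nudge[2])
  out <- pmin(pmax(t, bounds[1]), bounds[2])
  n_cl <- sum(out != t)
  if (n_cl > 0)
    warning(sprintf(
      "%d prediction input(s) outside the mapped domain were clamped to its edge",
      n_cl))
  out
}

#' Fit, predict and report in one call
#'
#' The orchestration behind the command-line `fit` command: resolve the
#' configuration, load (or accept) a dataset, optionally learn
#' hyperparameters ([lcgp_learn()]), fit with the requested method
#' (`"lcgp"` reduced-rank, or `"std-gp"` exact GP on the same rank-m
#' kernel), predict at the test inputs (training inputs when no test split
#' exists) with 95 percent Gaussian intervals, and assemble a report with
#' the resolved configuration, optimized parameters, log marginal
#' likelihood, and ISE / R-squared metrics when a test split or truth
#' values are available.
#'
#' @param config named list; see the package vignette for keys. Minimal:
#'   `data` (CSV path) or `dataset` passed separately, `family`, `m`.
#' @param dataset optional `"regression_dataset"` overriding `config$data`.
#' @return list with `predictions` (data.frame `t, mean, variance,
#'   lower95, upper95`), `report` (list), `model`. Files are written when
#'   `config$predictions_out` / `config$report_out` are set.
#' @export
run_fit_predict <- function(config = list(), dataset = NULL) {
  t0 <- proc.time()[["elapsed"]]
  cfg <- resolve_config(config)
  if (is.null(dataset)) {
    if (is.null(cfg$data))
      lcgp_stop("no dataset: set config$data or pass `dataset`",
                "lcgp_config_error")
    dataset <- read_regression_csv(cfg$data, cfg$t_col, cfg$y_col)
  }
  if (!is.null(cfg$seed)) set.seed(cfg$seed)

  basis <- config_basis(cfg)
  basis <- fit_input_map(basis, dataset$t_train)
  noise_var <- cfg$noise_var
  theta <- NULL
  if (isTRUE(cfg$learn)) {
    yc <- dataset$y_train -
      if (isTRUE(cfg$center)) mean(dataset$y_train) else 0
    opt <- lcgp_learn(basis, dataset$t_train, dataset$y_train,
                      noise_var = noise_var,
                      learn_noise = isTRUE(cfg$learn_noise),
                      center = isTRUE(cfg$center),
                      inits = if (isTRUE(cfg$multistart))
                        lcgp_default_inits(basis, yc),
                      fix = cfg$fix, eta = cfg$eta, tol = cfg$tol,
                      max_iters = cfg$max_iters)
    basis <- opt$basis
    noise_var <- opt$noise_var
    theta <- as.list(opt$theta)
  }

  model <- tryCatch(
    if (cfg$method == "lcgp")
      lcgp_fit(basis, dataset$t_train, dataset$y_train, noise_var,
               center = isTRUE(cfg$center))
    else
      cgp_fit(truncated_kernel(basis), dataset$t_train, dataset$y_train,
              noise_var, center = isTRUE(cfg$center)),
    error = function(e)
      lcgp_stop(paste0("model fitting failed: ", conditionMessage(e)),
                "lcgp_numerical_error"))

  has_test <- length(dataset$t_test) > 0
  t_out <- if (has_test) dataset$t_test else dataset$t_train
  t_eval <- clamp_to_domain(basis, t_out)
  pr <- predict(model, t_eval, include_noise = isTRUE(cfg$include_noise))
  predictions <- data.frame(
    t = t_out, mean = pr$mean, variance = pr$variance,
    lower95 = pr$mean - 1.96 * sqrt(pr$variance),
    upper95 = pr$mean + 1.96 * sqrt(pr$variance))

  metrics <- list()
  if (has_test) {
    metrics$r_squared_test <- r_squared(pr$mean, dataset$y_test)
    truth_test <- if (is.function(dataset$truth)) dataset$truth(t_out)
    else dataset$truth_test
    if (!is.null(truth_test)) {
      metrics$ise_truth <- ise(pr$mean, truth_test)
      metrics$r_squared_truth <- r_squared(pr$mean, truth_test)
    }
  }

  report <- list(
    package_version = as.character(utils::packageVersion("lcgp")),
    config = cfg[setdiff(names(cfg), c("data", "predictions_out",
                                       "report_out"))],
    family = cfg$family, m = cfg$m, method = cfg$method,
    theta = theta,
    noise_var = noise_var,
    log_marginal = log_marginal(model),
    metrics = metrics,
    n_train = length(dataset$t_train), n_test = length(dataset$t_test),
    seed = cfg$seed,
    timing_sec = proc.time()[["elapsed"]] - t0)

  if (!is.null(cfg$predictions_out))
    utils::write.csv(predictions, cfg$predictions_out, row.names = FALSE)
  if (!is.null(cfg$report_out))
    jsonlite::write_json(report, cfg$report_out, auto_unbox = TRUE,
                         digits = NA, null = "null", pretty = TRUE)

  list(predictions = predictions, report = report, model = model)
}
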