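## Hyperparameter selection and model-fit serialization.

#' Select a regularization strength by inner cross-validation
#'
#' Splits the *training* rows into `n_folds` folds, fits `trainer` at every
#' grid value and picks the one minimizing mean validation RMSE.  Ties break
#' toward the larger (sparser) value.
#'
#' @param trainer function `(X, Y, alpha) -> fit`, where the fit has a
#'   `predict` method returning predictions shaped like `Y`.
#' @param X training feature matrix.
#' @param Y training responses (vector or matrix).
#' @param grid candidate values (non-empty).
#' @param n_folds inner folds (default 3).
#' @param seed fold-assignment seed.
#' @return list with `alpha` (chosen value) and `cv_rmse` (named mean RMSE
#'   per grid value).
#' @export
select_alpha <- function(trainer, X, Y, grid, n_folds = 3L, seed = 1L) {
  if (length(grid) == 0L) stop("`grid` must be non-empty", call. = FALSE)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  n <- nrow(X)
  if (length(grid) == 1L) {
    return(list(alpha = grid, cv_rmse = stats::setNames(NA_real_, grid)))
  }
  n_folds <- min(n_folds, n)
  folds <- with_seed(seed, sample(rep_len(seq_len(n_folds), n)))
  err <- matrix(NA_real_, nrow = n_folds, ncol = length(grid))
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    if (sum(tr) < 2L || sum(!tr) < 1L) next
    for (g in seq_along(grid)) {
      fit <- trainer(X[tr, , drop = FALSE], Y[tr, , drop = FALSE], grid[g])
      pred <- stats::predict(fit, X[!tr, , drop = FALSE])
      err[f, g] <- rmse(as.numeric(pred), as.numeric(Y[!tr, , drop = FALSE]))
    }
  }
  mean_rmse <- colMeans(err, na.rm = TRUE)
  ord <- order(grid, decreasing = TRUE)   # prefer sparser on ties
  best <- ord[which.min(mean_rmse[ord])]
  list(alpha = grid[best],
       cv_rmse = stats::setNames(mean_rmse, grid))
}

#' Serialize a model fit to JSON
#'
#' Writes weights keyed by feature name together with the fit configuration
#' and solver diagnostics, so downstream interpretation can consume fits
#' without R.
#'
#' @param fit an `stl_fit`, `mtl_fit` or `msvr_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path) {
  obj <- if (inherits(fit, "stl_fit")) {
    list(type = "stl", alpha = fit$alpha, intercept = fit$intercept,
         weights = as.list(fit$weights[fit$weights != 0]),
         diagnostics = fit$diagnostics[c("solver", "objective")])
  } else if (inherits(fit, "mtl_fit")) {
    nz <- rowSums(abs(fit$W)) > 0
    list(type = "mtl", layout = fit$layout, alpha = fit$alpha,
         tasks = fit$task_names,
         intercepts = as.list(fit$intercepts),
         weights = apply(fit$W[nz, , drop = FALSE], 1L, as.list),
         diagnostics = fit$diagnostics[c("iterations", "objective",
                                         "converged")])
  } else if (inherits(fit, "msvr_fit")) {
    list(type = "msvr", kernel = fit$kernel, C = fit$C,
         lambda = fit$lambda, sigma = fit$sigma,
         tasks = fit$task_names, biases = as.list(fit$b),
         n_support = nrow(fit$X_support), jittered = fit$jittered)
  } else {
    stop("unsupported fit class", call. = FALSE)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
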