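## Single-task LASSO (personalized, or generalized by row-concatenating
## patients).  Objective, in glmnet's convention:
##   (1/(2n)) ||y - Xw||^2 + alpha |w|_1
## Features are z-scored and the label centered before fitting; the intercept
## is unpenalized (it is the label mean on the centered problem).  Weights
## are reported on the standardized feature scale, which is also the scale
## the interpretation layer compares weights on.

#' Fit a single-task LASSO model
#'
#' @param X numeric matrix (rows = EMA entries, named feature columns).
#' @param y numeric response vector.
#' @param alpha sparsity penalty (>= 0); `alpha = 0` is ordinary least
#'   squares (minimum-norm when rank-deficient).
#' @param standardize z-score columns first (default `TRUE`).  Zero-variance
#'   columns are left centered at zero and receive zero weight.
#' @return an object of class `stl_fit` with elements `weights` (named, on
#'   the standardized scale), `intercept`, `alpha`, the scaling used, and
#'   solver diagnostics.
#' @export
fit_lasso_stl <- function(X, y, alpha, standardize = TRUE) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)", call. = FALSE)
  if (nrow(X) < 2L) stop("need at least 2 rows", call. = FALSE)
  stopifnot_scalar(alpha, "alpha")
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)

  sc <- standardize_columns(X, standardize)
  Xs <- sc$X
  y_center <- mean(y)
  yc <- y - y_center

  if (alpha == 0) {
    fit <- stats::lm.fit(Xs, yc)
    w <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
    diag <- list(solver = "qr", iterations = NA_integer_,
                 objective = mean((yc - Xs %*% w)^2) / 2)
  } else {
    gfit <- glmnet::glmnet(Xs, yc, alpha = 1, standardize = FALSE,
                           intercept = FALSE, thresh = 1e-12, maxit = 1e6)
    w <- as.numeric(glmnet::coef.glmnet(
      gfit, s = alpha, exact = TRUE, x = Xs, y = yc,
      alpha = 1, standardize = FALSE, intercept = FALSE,
      thresh = 1e-12, maxit = 1e6
    ))[-1L]
    diag <- list(
      solver = "glmnet",
      iterations = NA_integer_,
      objective = mean((yc - Xs %*% w)^2) / 2 + alpha * sum(abs(w))
    )
  }
  names(w) <- colnames(X)
  structure(list(
    weights = w, intercept = y_center, alpha = alpha,
    center = sc$center, scale = sc$scale, diagnostics = diag
  ), class = "stl_fit")
}

standardize_columns <- function(X, standardize = TRUE) {
  if (!standardize) {
    return(list(X = X, center = rep(0, ncol(X)), scale = rep(1, ncol(X))))
  }
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[!is.finite(scale) | scale < 1e-12] <- 1
  list(X = sweep(sweep(X, 2L, center), 2L, scale, "/"),
       center = center, scale = scale)
}

apply_scaling <- function(X, fit) {
  sweep(sweep(as.matrix(X), 2L, fit$center), 2L, fit$scale, "/")
}

check_columns <- function(X, fit) {
  need <- names(fit$weights) %||% rownames(fit$W)
  if (is.null(colnames(X)) || !identical(colnames(X), need)) {
    if (!is.null(colnames(X)) && setequal(colnames(X), need)) {
      return(X[, need, drop = FALSE])
    }
    stop("prediction columns do not match training columns", call. = FALSE)
  }
  X
}

#' Predict from a single-task LASSO fit
#'
#' Linear predictions (inner product of feature weights and feature values
#' plus intercept).  Predictions are not clipped to the 0-3 EMA scale unless
#' `clip = TRUE`.
#'
#' @param object an `stl_fit`.
#' @param newdata feature matrix with the training columns.
#' @param clip clip predictions to `[0, 3]` (default `FALSE`).
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.stl_fit <- function(object, newdata, clip = FALSE, ...) {
  X <- check_columns(as.matrix(newdata), object)
  out <- as.numeric(apply_scaling(X, object) %*% object$weights) +
    object$intercept
  if (clip) out <- pmin(pmax(out, 0), 3)
  out
}
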