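## Multi-output least-squares support vector regression.  Each task's
## regressor decomposes as a mean regressor plus a small per-task
## adjustment, w_0 + v_t, with objective
##
##   min  1/2 ||w0||^2 + lambda/(2T) sum_t ||v_t||^2 + C/2 sum_{t,i} e_ti^2
##   s.t. y_ti = (w0 + v_t)' phi(x_i) + b_t + e_ti
##
## (equality-constrained squared-error loss, the least-squares SVR variant).
## The KKT conditions give a single linear system in the dual variables
## A (n x T) and the per-task biases:
##
##   K (A 1_T) + (T/lambda) K a_t + b_t 1 + a_t / C = y_t ,   1' a_t = 0 .
##
## Predictions: f_t(x) = k(x, X) (A 1_T + (T/lambda) a_t) + b_t.

#' Fit a multi-output least-squares SVR
#'
#' @param X feature matrix (rows = samples, named columns).
#' @param Y matrix of task responses (rows x tasks); a vector is treated as
#'   a single task.
#' @param kernel `"linear"` or `"rbf"`.
#' @param C cost of squared training error (> 0).
#' @param lambda coupling strength (> 0): large values shrink the per-task
#'   adjustments toward the shared mean regressor.
#' @param sigma RBF bandwidth; default is the median pairwise distance
#'   heuristic on the standardized features.
#' @param standardize z-score the features before the kernel (default TRUE).
#' @return an object of class `msvr_fit` (dual coefficients, biases, kernel
#'   spec, retained support data, and a `jittered` flag when the KKT system
#'   needed a ridge of 1e-10).
#' @export
fit_msvr <- function(X, Y, kernel = c("linear", "rbf"), C = 1, lambda = 1,
                     sigma = NULL, standardize = TRUE) {
  kernel <- match.arg(kernel)
  X <- as.matrix(X)
  Y <- as.matrix(Y)
  if (nrow(X) != nrow(Y)) stop("X and Y row mismatch", call. = FALSE)
  if (nrow(X) < 2L) stop("need at least 2 samples", call. = FALSE)
  stopifnot_scalar(C, "C"); stopifnot_scalar(lambda, "lambda")
  if (C <= 0) stop("`C` must be > 0", call. = FALSE)
  if (lambda <= 0) {
    stop("`lambda` must be > 0 (the per-task adjustments are unpenalized in the limit)",
         call. = FALSE)
  }

  sc <- standardize_columns(X, standardize)
  Xs <- sc$X
  n <- nrow(Xs)
  T_ <- ncol(Y)
  task_names <- colnames(Y) %||% paste0("task", seq_len(T_))

  if (kernel == "rbf" && is.null(sigma)) {
    sigma <- median_pairwise_distance(Xs)
    if (!is.finite(sigma) || sigma <= 0) sigma <- 1
  }
  K <- kernel_matrix(Xs, Xs, kernel, sigma)

  ## big system: [ 1_T1_T' (x) K + (T/lambda) I (x) K + I/C ,  I (x) 1 ]
  ##             [ I (x) 1'                                 ,  0       ]
  ones_T <- matrix(1, T_, T_)
  M <- kronecker(ones_T, K) + kronecker(diag(T_), (T_ / lambda) * K) +
    diag(1 / C, n * T_)
  B <- kronecker(diag(T_), matrix(1, n, 1))
  sys <- rbind(cbind(M, B), cbind(t(B), matrix(0, T_, T_)))
  rhs <- c(as.numeric(Y), rep(0, T_))
  sol <- tryCatch(solve(sys, rhs), error = function(e) NULL)
  jittered <- FALSE
  if (is.null(sol)) {
    jittered <- TRUE
    sol <- solve(sys + diag(1e-10, nrow(sys)), rhs)
  }
  A <- matrix(sol[seq_len(n * T_)], nrow = n, ncol = T_,
              dimnames = list(NULL, task_names))
  b <- stats::setNames(sol[n * T_ + seq_len(T_)], task_names)

  structure(list(
    A = A, b = b, kernel = kernel, sigma = sigma, C = C, lambda = lambda,
    X_support = Xs, center = sc$center, scale = sc$scale,
    feature_names = colnames(X), task_names = task_names,
    jittered = jittered
  ), class = "msvr_fit")
}

median_pairwise_distance <- function(X) {
  n <- nrow(X)
  if (n > 200L) X <- X[seq(1L, n, length.out = 200L), , drop = FALSE]
  stats::median(stats::dist(X))
}

kernel_matrix <- function(A, B, kernel, sigma = NULL) {
  if (kernel == "linear") {
    A %*% t(B)
  } else {
    an <- rowSums(A * A)
    bn <- rowSums(B * B)
    d2 <- outer(an, bn, "+") - 2 * A %*% t(B)
    exp(-pmax(d2, 0) / (2 * sigma^2))
  }
}

#' Predict from a multi-output LS-SVR fit
#'
#' @param object an `msvr_fit`.
#' @param newdata feature matrix with the training columns.
#' @param clip clip predictions to `[0, 3]` (default `FALSE`).
#' @param ... unused.
#' @return matrix of predictions (rows x tasks).
#' @export
predict.msvr_fit <- function(object, newdata, clip = FALSE, ...) {
  X <- as.matrix(newdata)
  if (!is.null(colnames(X)) && !is.null(object$feature_names) &&
      !identical(colnames(X), object$feature_names)) {
    if (!setequal(colnames(X), object$feature_names)) {
      stop("prediction columns do not match training columns", call. = FALSE)
    }
    X <- X[, object$feature_names, drop = FALSE]
  }
  Xs <- sweep(sweep(X, 2L, object$center), 2L, object$scale, "/")
  Kn <- kernel_matrix(Xs, object$X_support, object$kernel, object$sigma)
  T_ <- length(object$b)
  shared <- rowSums(object$A)
  out <- sapply(seq_len(T_), function(t) {
    as.numeric(Kn %*% (shared + (T_ / object$lambda) * object$A[, t])) +
      object$b[t]
  })
  out <- matrix(out, nrow = nrow(X),
                dimnames = list(rownames(X), object$task_names))
  if (clip) out <- pmin(pmax(out, 0), 3)
  out
}
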