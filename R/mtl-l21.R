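## l2,1-regularized multi-task regression, solved by proximal gradient
## (ISTA) with backtracking line search.  Two layouts:
##
##   * "symptoms": one shared design X and k label columns (couple one
##     patient's symptom models);
##   * "patients": per-patient (X_u, y_u) blocks sharing the feature space
##     (couple all patients' models for one symptom).
##
## Objective:  sum_t c_t ||y_t - X_t w_t||^2  +  alpha ||W||_{2,1},
## where ||W||_{2,1} = sum_rows ||W[i, ]||_2 enforces a jointly shared row
## support, and c_t = 1/n_t when per-task loss normalization is on (the
## default for the patients layout, where task sample sizes differ).

#' Fit an l2,1-norm multi-task regression model
#'
#' @param X_blocks either a single matrix (layout `"symptoms"`: all tasks
#'   share the design) or a list of per-task matrices with identical column
#'   names (layout `"patients"`).
#' @param Y_blocks a matrix with one column per task (shared design) or a
#'   list of per-task response vectors.
#' @param alpha the l2,1 penalty (>= 0).
#' @param layout `"symptoms"` or `"patients"`.
#' @param normalize_loss divide each task's squared-error loss by its sample
#'   size; defaults to `TRUE` for the patients layout, `FALSE` otherwise.
#' @param standardize z-score each task's design and center its labels.
#' @param tol relative objective-change convergence tolerance (default 1e-8).
#' @param max_iter iteration cap (default 5000).
#' @return an object of class `mtl_fit`: the weight matrix `W` (features x
#'   tasks, standardized scale), per-task intercepts and scalings, and solver
#'   diagnostics (`iterations`, `objective`, `objective_trace`, `converged`).
#' @export
fit_mtl_l21 <- function(X_blocks, Y_blocks, alpha,
                        layout = c("symptoms", "patients"),
                        normalize_loss = NULL,
                        standardize = TRUE,
                        tol = 1e-8, max_iter = 5000L) {
  layout <- match.arg(layout)
  stopifnot_scalar(alpha, "alpha")
  if (alpha < 0) stop("`alpha` must be >= 0", call. = FALSE)
  if (is.null(normalize_loss)) normalize_loss <- layout == "patients"

  if (is.matrix(X_blocks) || is.data.frame(X_blocks)) {
    X <- as.matrix(X_blocks)
    Y <- as.matrix(Y_blocks)
    if (nrow(Y) != nrow(X)) stop("Y rows must match X rows", call. = FALSE)
    Xs <- replicate(ncol(Y), X, simplify = FALSE)
    ys <- lapply(seq_len(ncol(Y)), function(j) Y[, j])
    task_names <- colnames(Y) %||% paste0("task", seq_len(ncol(Y)))
  } else {
    Xs <- lapply(X_blocks, as.matrix)
    ys <- lapply(Y_blocks, as.numeric)
    if (length(Xs) != length(ys)) {
      stop("X_blocks and Y_blocks must have the same length", call. = FALSE)
    }
    cn <- colnames(Xs[[1L]])
    for (t in seq_along(Xs)) {
      if (!identical(colnames(Xs[[t]]), cn)) {
        stop("all task blocks must share the same column space", call. = FALSE)
      }
      if (nrow(Xs[[t]]) != length(ys[[t]])) {
        stop("task block row/label mismatch", call. = FALSE)
      }
    }
    task_names <- names(Xs) %||% paste0("task", seq_along(Xs))
  }

  T_ <- length(Xs)
  d <- ncol(Xs[[1L]])
  feat_names <- colnames(Xs[[1L]]) %||% paste0("f", seq_len(d))

  scalings <- vector("list", T_)
  y_center <- numeric(T_)
  shared_design <- is.matrix(X_blocks) || is.data.frame(X_blocks)
  if (shared_design) {
    sc <- standardize_columns(Xs[[1L]], standardize)
    for (t in seq_len(T_)) scalings[[t]] <- sc
    Xs <- replicate(T_, sc$X, simplify = FALSE)
  } else {
    for (t in seq_len(T_)) {
      scalings[[t]] <- standardize_columns(Xs[[t]], standardize)
      Xs[[t]] <- scalings[[t]]$X
    }
  }
  for (t in seq_len(T_)) {
    y_center[t] <- mean(ys[[t]])
    ys[[t]] <- ys[[t]] - y_center[t]
  }
  cs <- if (normalize_loss) {
    vapply(Xs, function(x) 1 / nrow(x), numeric(1))
  } else {
    rep(1, T_)
  }

  ## smooth part, gradient, and penalty (fast path when the design is
  ## shared across tasks)
  if (shared_design) {
    X1 <- Xs[[1L]]
    Ym <- do.call(cbind, ys)
    loss <- function(W) cs[1L] * sum((Ym - X1 %*% W)^2)
    gradient <- function(W) -2 * cs[1L] * crossprod(X1, Ym - X1 %*% W)
  } else {
    loss <- function(W) {
      s <- 0
      for (t in seq_len(T_)) {
        r <- ys[[t]] - Xs[[t]] %*% W[, t]
        s <- s + cs[t] * sum(r * r)
      }
      s
    }
    gradient <- function(W) {
      G <- matrix(0, d, T_)
      for (t in seq_len(T_)) {
        r <- ys[[t]] - Xs[[t]] %*% W[, t]
        G[, t] <- -2 * cs[t] * crossprod(Xs[[t]], r)
      }
      G
    }
  }
  row_norms <- function(W) sqrt(rowSums(W * W))
  penalty <- function(W) alpha * sum(row_norms(W))
  prox <- function(W, thr) {
    rn <- row_norms(W)
    shrink <- pmax(0, 1 - thr / pmax(rn, 1e-300))
    W * shrink
  }

  ## Lipschitz estimate: 2 * max_t c_t * lambda_max(X_t' X_t) via a few
  ## deterministic power iterations per task
  L <- 0
  for (t in seq_len(T_)) {
    v <- rep(1 / sqrt(d), d)
    for (it in 1:8) {
      v <- crossprod(Xs[[t]], Xs[[t]] %*% v)
      nv <- sqrt(sum(v * v))
      if (nv < 1e-30) break
      v <- v / nv
    }
    lam <- sum((Xs[[t]] %*% v)^2)
    L <- max(L, 2 * cs[t] * lam)
  }
  step <- if (L > 0) 1 / L else 1

  ## Monotone accelerated proximal gradient: the candidate step is taken
  ## from the momentum point (FISTA); whenever it fails to decrease the
  ## objective, fall back to a plain proximal step from the current iterate
  ## and reset the momentum, so the objective is non-increasing by
  ## construction.
  W <- matrix(0, d, T_)
  V <- W                  # momentum point
  theta <- 1
  obj <- loss(W) + penalty(W)
  trace <- obj
  converged <- FALSE
  iter <- 0L
  prox_step <- function(P, f_p, G) {
    ## backtracking proximal step from point P
    repeat {
      Q <- prox(P - step * G, step * alpha)
      D <- Q - P
      f_q <- loss(Q)
      if (f_q <= f_p + sum(G * D) + sum(D * D) / (2 * step) + 1e-12) {
        return(Q)
      }
      step <<- step / 2
      if (step < 1e-18) return(Q)
    }
  }
  while (iter < max_iter) {
    iter <- iter + 1L
    W_acc <- prox_step(V, loss(V), gradient(V))
    obj_acc <- loss(W_acc) + penalty(W_acc)
    if (obj_acc <= obj + 1e-15) {
      W_new <- W_acc
      obj_new <- obj_acc
    } else {
      W_new <- prox_step(W, loss(W), gradient(W))
      obj_new <- loss(W_new) + penalty(W_new)
      if (obj_new > obj) {        # numerically stuck: keep current iterate
        W_new <- W
        obj_new <- obj
      }
      theta <- 1                  # restart momentum
    }
    theta_new <- (1 + sqrt(1 + 4 * theta^2)) / 2
    V <- W_new + ((theta - 1) / theta_new) * (W_new - W)
    theta <- theta_new
    W <- W_new
    trace <- c(trace, obj_new)
    if (abs(obj - obj_new) <= tol * max(1, abs(obj))) {
      obj <- obj_new
      converged <- TRUE
      break
    }
    obj <- obj_new
    step <- step * 1.05
  }

  dimnames(W) <- list(feat_names, task_names)
  structure(list(
    W = W, intercepts = stats::setNames(y_center, task_names),
    alpha = alpha, layout = layout, normalize_loss = normalize_loss,
    scalings = scalings, task_names = task_names,
    diagnostics = list(iterations = iter, objective = obj,
                       objective_trace = trace, converged = converged)
  ), class = "mtl_fit")
}

#' Predict from an l2,1 multi-task fit
#'
#' @param object an `mtl_fit`.
#' @param newdata feature matrix with the training columns.
#' @param task task name or index (required for the patients layout, where
#'   each task has its own standardization; defaults to all tasks for a
#'   shared design).
#' @param clip clip predictions to `[0, 3]` (default `FALSE`).
#' @param ... unused.
#' @return matrix of predictions (rows x tasks), or a vector when a single
#'   task is requested.
#' @export
predict.mtl_fit <- function(object, newdata, task = NULL, clip = FALSE, ...) {
  X <- as.matrix(newdata)
  need <- rownames(object$W)
  if (!is.null(colnames(X)) && !identical(colnames(X), need)) {
    if (!setequal(colnames(X), need)) {
      stop("prediction columns do not match training columns", call. = FALSE)
    }
    X <- X[, need, drop = FALSE]
  }
  tasks <- if (is.null(task)) seq_along(object$task_names) else task
  if (is.character(tasks)) tasks <- match(tasks, object$task_names)
  out <- sapply(tasks, function(t) {
    sc <- object$scalings[[t]]
    Xs <- sweep(sweep(X, 2L, sc$center), 2L, sc$scale, "/")
    as.numeric(Xs %*% object$W[, t]) + object$intercepts[t]
  })
  out <- matrix(out, nrow = nrow(X),
                dimnames = list(rownames(X), object$task_names[tasks]))
  if (clip) out <- pmin(pmax(out, 0), 3)
  if (length(tasks) == 1L) as.numeric(out) else out
}
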