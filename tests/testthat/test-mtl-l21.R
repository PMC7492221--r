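random_mtl_instance <- function(seed, n = 40, d = 30, T_ = 4, s = 5,
                                noise = 0.1) {
  set.seed(seed)
  X <- matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("f", 1:d)))
  rows <- sample(d, s)
  W <- matrix(0, d, T_)
  W[rows, ] <- matrix(rnorm(s * T_), s, T_)
  Y <- X %*% W + matrix(rnorm(n * T_, sd = noise), n, T_)
  colnames(Y) <- paste0("t", 1:T_)
  list(X = X, Y = Y, rows = sort(rows))
}

row_support <- function(fit, tol = 1e-8) {
  unname(which(sqrt(rowSums(fit$W^2)) > tol))
}

test_that("objective is monotonically non-increasing on random instances", {
  for (seed in 1:20) {
    inst <- random_mtl_instance(seed, n = 25, d = 15, T_ = 3)
    fit <- fit_mtl_l21(inst$X, inst$Y, alpha = runif(1, 0.01, 2),
                       layout = "symptoms")
    tr <- fit$diagnostics$objective_trace
    expect_true(all(diff(tr) <= 1e-9 * pmax(1, abs(tr[-length(tr)]))))
  }
})

test_that("large alpha zeroes the whole weight matrix exactly", {
  inst <- random_mtl_instance(1)
  fit <- fit_mtl_l21(inst$X, inst$Y, alpha = 1e6, layout = "symptoms")
  expect_true(all(fit$W == 0))
  ## intercept-only predictions equal the task means
  P <- predict(fit, inst$X)
  expect_equal(P[1, ], colMeans(inst$Y), tolerance = 1e-12)
})

test_that("alpha = 0 recovers the per-task least-squares solutions", {
  set.seed(31)
  X <- matrix(rnorm(60 * 8), 60, 8, dimnames = list(NULL, paste0("f", 1:8)))
  Y <- matrix(rnorm(60 * 3), 60, 3, dimnames = list(NULL, paste0("t", 1:3)))
  fit <- fit_mtl_l21(X, Y, alpha = 0, layout = "symptoms", tol = 1e-14)
  P <- predict(fit, X)
  for (j in 1:3) {
    expect_equal(P[, j], unname(fitted(stats::lm(Y[, j] ~ X))),
                 tolerance = 1e-5)
  }
})

test_that("row support is shared across tasks (joint group sparsity)", {
  inst <- random_mtl_instance(2, n = 60, d = 40, T_ = 5, s = 6, noise = 0.05)
  fit <- fit_mtl_l21(inst$X, inst$Y, alpha = 0.5, layout = "symptoms")
  nz_rows <- row_support(fit)
  expect_gt(length(nz_rows), 0)
  ## within a nonzero row, every task is (generically) nonzero
  frac_full <- mean(apply(fit$W[nz_rows, , drop = FALSE], 1,
                          function(r) all(abs(r) > 0)))
  expect_gt(frac_full, 0.95)
})

test_that("noiseless planted rows are recovered at small alpha", {
  inst <- random_mtl_instance(3, n = 80, d = 60, T_ = 5, s = 6, noise = 0)
  fit <- fit_mtl_l21(inst$X, inst$Y, alpha = 0.3, layout = "symptoms")
  expect_identical(row_support(fit, tol = 1e-6), inst$rows)
})

test_that("patients layout solves per-task blocks over a shared column space", {
  set.seed(32)
  d <- 20
  Xs <- lapply(c(30, 45, 25), function(n) {
    matrix(rnorm(n * d), n, d, dimnames = list(NULL, paste0("f", 1:d)))
  })
  names(Xs) <- paste0("P", 1:3)
  w <- c(rep(1.2, 3), rep(0, d - 3))
  ys <- lapply(Xs, function(X) as.numeric(X %*% w) + rnorm(nrow(X), sd = 0.05))
  fit <- fit_mtl_l21(Xs, ys, alpha = 0.2, layout = "patients")
  expect_equal(fit$task_names, names(Xs))
  sup <- row_support(fit)
  expect_true(all(1:3 %in% sup))
  expect_lt(length(sup), 10)
  ## per-task prediction uses that task's standardization
  p <- predict(fit, Xs[[2]], task = "P2")
  expect_lt(rmse(p, ys[[2]]), 0.2)
  ## mismatched column spaces are rejected
  Xbad <- Xs
  colnames(Xbad[[2]]) <- paste0("g", 1:d)
  expect_error(fit_mtl_l21(Xbad, ys, 0.1, layout = "patients"),
               "column space")
})

test_that("final objective matches a long-run reference on small instances", {
  for (seed in 4:6) {
    inst <- random_mtl_instance(seed, n = 30, d = 12, T_ = 3)
    quick <- fit_mtl_l21(inst$X, inst$Y, alpha = 0.4, layout = "symptoms")
    long <- fit_mtl_l21(inst$X, inst$Y, alpha = 0.4, layout = "symptoms",
                        tol = 0, max_iter = 50000L)
    expect_lt(abs(quick$diagnostics$objective - long$diagnostics$objective) /
                max(1, abs(long$diagnostics$objective)), 1e-6)
  }
})
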