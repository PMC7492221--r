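## Independent oracles used across the suite.  These deliberately re-derive
## quantities with the most naive possible algorithm (double loops, direct
## linear solves) so they stay independent of the implementation paths they
## check.

## O(n^2) brute-force sample entropy: count all template pairs explicitly.
sampen_bruteforce <- function(x, m, r) {
  n <- length(x)
  N <- n - m
  if (N < 2) return(NA_real_)
  A <- 0; B <- 0
  for (i in 1:(N - 1)) {
    for (j in (i + 1):N) {
      dm <- max(abs(x[i:(i + m - 1)] - x[j:(j + m - 1)]))
      if (dm <= r) {
        B <- B + 1
        dm1 <- max(abs(x[i:(i + m)] - x[j:(j + m)]))
        if (dm1 <= r) A <- A + 1
      }
    }
  }
  if (A == 0 || B == 0) return(NA_real_)
  -log(A / B)
}

## brute-force silhouette: direct definition, explicit loops
silhouette_bruteforce <- function(X, labels) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in 1:n) {
    own <- setdiff(which(labels == labels[i]), i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(sapply(own, function(j) d(i, j)))
    bs <- sapply(setdiff(unique(labels), labels[i]), function(k) {
      mean(sapply(which(labels == k), function(j) d(i, j)))
    })
    b <- min(bs)
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

## soft-threshold operator (closed-form LASSO for orthonormal designs)
soft_threshold <- function(z, t) sign(z) * pmax(abs(z) - t, 0)

## direct single-output LS-SVR: (K + I/C) a + b = y, 1'a = 0
ls_svr_oracle_predict <- function(K, y, C) {
  n <- length(y)
  sys <- rbind(cbind(K + diag(1 / C, n), rep(1, n)), c(rep(1, n), 0))
  sol <- solve(sys, c(y, 0))
  as.numeric(K %*% sol[1:n] + sol[n + 1])
}

## adjusted Rand index between two labelings
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  si <- sum(choose(rowSums(tab), 2))
  sj <- sum(choose(colSums(tab), 2))
  sij <- sum(choose(tab, 2))
  e <- si * sj / choose(n, 2)
  (sij - e) / ((si + sj) / 2 - e)
}

## F1 of a selected feature set against a reference set
support_f1 <- function(selected, truth) {
  tp <- length(intersect(selected, truth))
  if (tp == 0) return(0)
  p <- tp / length(selected)
  r <- tp / length(truth)
  2 * p * r / (p + r)
}

## small synthetic cohort configuration shared by pipeline-level tests:
## 4 modalities, 2-and-4-day windows, planted periods that fit the windows
small_cohort_config <- function(seed, n_patients = 6, n_days = 60, ...) {
  cohort_config(
    n_patients = n_patients, n_days = n_days,
    modalities = c("light", "sound", "screen_on_time", "sms_sent"),
    windows = c(2, 4), infradian_pool = c(64, 72),
    seed = seed, ...
  )
}

## features + labels for run_protocol from a cohort
cohort_model_data <- function(cohort, windows = cohort$config$windows) {
  feats <- cohort_features(cohort, windows = windows)
  list(
    feats = feats,
    data = lapply(feats, function(f) list(X = f$X, Y = f$Y)),
    ema_table = do.call(rbind, lapply(names(feats), function(pt) {
      data.frame(patient = pt, date = as.character(feats[[pt]]$dates),
                 stringsAsFactors = FALSE)
    }))
  )
}
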