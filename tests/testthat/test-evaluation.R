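toy_ema_table <- function(n_patients = 2, n_rows = 10) {
  do.call(rbind, lapply(seq_len(n_patients), function(p) {
    data.frame(patient = sprintf("P%02d", p),
               date = as.character(as.Date("2020-02-01") + seq_len(n_rows)),
               stringsAsFactors = FALSE)
  }))
}

test_that("cv plans partition rows exactly once per scheme", {
  tab <- toy_ema_table(3, 10)
  for (scheme in c("fivefold", "semi_loso", "loso")) {
    plan <- make_cv_plan(tab, scheme, seed = 5)
    expect_equal(nrow(plan$table), nrow(tab))
    expect_false(anyNA(plan$table$fold))
    if (scheme != "loso") {
      per <- table(plan$table$patient, plan$table$fold)
      expect_true(all(rowSums(per) == 10))
      expect_true(all(per == 2))   # 10 rows over 5 folds
    }
  }
})

test_that("chronological plan holds out the latest 20% per patient", {
  plan <- make_cv_plan(toy_ema_table(1, 10), "chronological")
  tab <- plan$table
  expect_equal(sum(tab$fold == "train"), 8L)
  expect_equal(sum(tab$fold == "test"), 2L)
  expect_true(all(as.Date(tab$date[tab$fold == "test"]) >
                  max(as.Date(tab$date[tab$fold == "train"]))))
})

test_that("fivefold plans reject patients with too few rows and fix seeds", {
  expect_error(make_cv_plan(toy_ema_table(2, 4), "fivefold"), "fewer than 5")
  p1 <- make_cv_plan(toy_ema_table(2, 10), "fivefold", seed = 9)
  p2 <- make_cv_plan(toy_ema_table(2, 10), "fivefold", seed = 9)
  expect_identical(p1, p2)
})

test_that("rmse and its percent-of-scale form behave", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 2) + 0.5, c(1, 2)), 0.5)
  expect_equal(rmse_pct(0.309), 10.3, tolerance = 1e-3)
  expect_error(rmse(1:3, 1:2), "equal-length")
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
})

test_that("every EMA row gets exactly one out-of-fold prediction", {
  set.seed(51)
  d <- 6
  data <- lapply(1:2, function(p) {
    X <- matrix(rnorm(10 * d), 10, d, dimnames = list(NULL, paste0("f", 1:d)))
    Y <- matrix(sample(0:3, 20, TRUE), 10, 2,
                dimnames = list(NULL, c("depressed", "calm")))
    list(X = X, Y = Y)
  })
  names(data) <- c("P01", "P02")
  tab <- toy_ema_table(2, 10)
  for (alg in c("stl", "mtl_symptoms")) {
    plan <- make_cv_plan(tab, "fivefold", seed = 1)
    pr <- run_protocol(alg, data, plan, alpha = 0.1)
    expect_equal(nrow(pr), 2 * 10 * 2)  # sum_u e_u x symptoms
    expect_equal(unname(table(pr$patient, pr$symptom)), matrix(10, 2, 2))
    pr2 <- run_protocol(alg, data, plan, alpha = 0.1)
    expect_identical(pr, pr2)           # deterministic rerun
  }
  ## generalized models under LOSO
  plan_l <- make_cv_plan(tab, "loso")
  pr <- run_protocol("stl_gen", data, plan_l, alpha = 0.1)
  expect_equal(nrow(pr), 40L)
  ## m-SVR under fivefold
  plan_f <- make_cv_plan(tab, "fivefold", seed = 2)
  pr_m <- run_protocol("msvr_rbf", data, plan_f)
  expect_equal(nrow(pr_m), 40L)
  ## semi-LOSO: training sets combine held-in folds with other patients
  plan_s <- make_cv_plan(tab, "semi_loso", seed = 3)
  pr_s <- run_protocol("mtl_patients", data, plan_s, alpha = 0.1,
                       symptoms = "depressed")
  expect_equal(nrow(pr_s), 20L)
  expect_false(any(duplicated(pr_s[, c("patient", "row")])))
})

test_that("scheme/protocol mismatches are rejected", {
  tab <- toy_ema_table(2, 10)
  plan <- make_cv_plan(tab, "loso")
  expect_error(run_protocol("stl", list(), plan), "requires scheme")
  plan_f <- make_cv_plan(tab, "fivefold")
  expect_error(run_protocol("mtl_patients", list(), plan_f), "requires scheme")
})

test_that("signed-rank test: exact small-sample null and symmetries", {
  ## 6 pairs, all positive differences: two-sided exact p = 2/64
  a <- c(1.2, 2.1, 0.7, 3.3, 1.9, 2.5)
  b <- a - c(0.11, 0.23, 0.31, 0.17, 0.41, 0.13)
  res <- paired_signed_rank(a, b)
  expect_equal(res$method, "exact")
  expect_equal(res$p.value, 2 / 64)
  swapped <- paired_signed_rank(b, a)
  expect_equal(swapped$p.value, res$p.value)
  expect_equal(swapped$statistic, -res$statistic)
  tied <- paired_signed_rank(a, a)
  expect_true(tied$undefined)
  expect_true(is.na(tied$p.value))
})

test_that("signed-rank test agrees with the reference implementation", {
  set.seed(52)
  for (i in 1:20) {
    n <- sample(c(8, 15, 30, 60), 1)
    a <- rnorm(n)
    b <- rnorm(n)
    res <- paired_signed_rank(a, b)
    ref <- stats::wilcox.test(a, b, paired = TRUE, exact = n <= 25,
                              correct = TRUE)
    expect_equal(res$V, unname(ref$statistic))
    expect_equal(res$p.value, ref$p.value, tolerance = 1e-10)
  }
})

test_that("Holm-Bonferroni matches hand-computed step-down values", {
  expect_equal(holm_bonferroni(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_bonferroni(0.2), 0.2)
  expect_equal(holm_bonferroni(c(0.03, 0.02, 0.5)), c(0.06, 0.06, 0.5))
  set.seed(53)
  p <- runif(12)
  expect_equal(holm_bonferroni(p), stats::p.adjust(p, "holm"))
  expect_error(holm_bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("evaluation_report aggregates cells and bootstraps CIs", {
  set.seed(54)
  pr <- data.frame(
    algorithm = rep(c("stl", "mtl_patients"), each = 40),
    patient = rep(rep(c("P1", "P2"), each = 20), 2),
    symptom = rep(rep(c("depressed", "calm"), each = 10), 4),
    y_true = sample(0:3, 80, TRUE),
    y_pred = runif(80, 0, 3)
  )
  rep_ <- evaluation_report(pr, bootstrap_n = 200, seed = 2)
  expect_equal(nrow(rep_$cells), 8L)   # 2 algs x 2 patients x 2 symptoms
  expect_true(all(rep_$cells$rmse >= 0))
  expect_true(all(rep_$algorithms$ci_lo <= rep_$algorithms$mean_rmse &
                  rep_$algorithms$mean_rmse <= rep_$algorithms$ci_hi))
})
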