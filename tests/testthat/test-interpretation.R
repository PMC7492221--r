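toy_weights <- function() {
  nms <- c(feature_name("light", "amplitude", 2),
           feature_name("light", "4-hour_PSD", 4),
           feature_name("sound", "M10", 2),
           feature_name("sound", "72-hour_PSD", 6),
           feature_name("sms_sent", "2-hour_MSE", 2),
           feature_name("sms_sent", "median_deviation", 4))
  stats::setNames(c(0.5, -0.3, 0.2, 0, -0.1, 0.4), nms)
}

test_that("rank_features orders by |weight| with lexicographic ties", {
  w <- c(a = 0.2, b = -0.5)
  rf <- rank_features(w, n = 1)
  expect_equal(rf$name, "b")
  z <- rank_features(c(a = 0, b = 0))
  expect_equal(nrow(z), 0L)
  expect_true(attr(z, "all_zero"))
  tied <- rank_features(c(z2 = 0.3, a1 = -0.3))
  expect_equal(tied$name, c("a1", "z2"))
})

test_that("factor contributions equal direct hand computation", {
  w <- toy_weights()
  fc <- factor_contribution(w, "modality")
  ## c_light = mean(|0.5|, |-0.3|) = 0.4, etc.
  expect_equal(fc$c_p[fc$factor == "light"], 0.4)
  expect_equal(fc$c_p[fc$factor == "sound"], 0.1)
  expect_equal(fc$c_p[fc$factor == "sms_sent"], 0.25)
  ## positive / negative means are reported separately
  light <- fc[fc$factor == "light", ]
  expect_equal(light$mean_positive, 0.5)
  expect_equal(light$mean_negative, 0.3)
  ## periodicity grouping collapses metrics to the three classes
  fp <- factor_contribution(w, "periodicity")
  expect_setequal(fp$factor, c("ultradian", "circadian", "infradian"))
  expect_equal(fp$c_p[fp$factor == "ultradian"], mean(c(0.3, 0.1)))
  expect_equal(fp$c_p[fp$factor == "infradian"], 0)
  fw <- factor_contribution(w, "window")
  expect_equal(fw$c_p[fw$factor == "2-day_window"], mean(c(0.5, 0.2, 0.1)))
})

test_that("contribution is permutation-invariant and scales linearly", {
  w <- toy_weights()
  set.seed(61)
  perm <- sample(length(w))
  f1 <- factor_contribution(w, "modality")
  f2 <- factor_contribution(w[perm], "modality")
  expect_equal(f1, f2)
  f3 <- factor_contribution(w * 2.5, "modality")
  expect_equal(f3$c_p, f1$c_p * 2.5)
  expect_error(factor_contribution(c(bad_name = 1), "modality"),
               "unparseable")
})

test_that("silhouette matches the brute-force oracle on random labelings", {
  set.seed(62)
  for (i in 1:15) {
    n <- sample(8:20, 1)
    X <- matrix(rnorm(n * 3), n, 3)
    k <- sample(2:4, 1)
    labels <- sample(k, n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    expect_lt(abs(silhouette_score(X, labels) -
                  silhouette_bruteforce(X, labels)), 1e-10)
  }
})

test_that("find_subtypes recovers two well-separated weight templates", {
  set.seed(63)
  d <- 30
  t1 <- c(rep(1, 5), rep(0, d - 5))
  t2 <- c(rep(0, d - 5), rep(1, 5))
  W <- rbind(
    t(replicate(12, t1 * runif(d, 0.8, 1.2))),
    t(replicate(12, t2 * runif(d, 0.8, 1.2)))
  ) + matrix(rnorm(24 * d, sd = 0.02), 24, d)
  truth <- rep(1:2, each = 12)
  res <- find_subtypes(W, k_range = 2:10, seed = 7)
  expect_equal(res$k, 2L)
  expect_gt(max(res$silhouette, na.rm = TRUE), 0.5)
  expect_gte(adjusted_rand_index(res$labels, truth), 0.99)
})

test_that("degenerate clustering inputs are flagged, not crashed", {
  W <- matrix(1, nrow = 12, ncol = 5)   # identical patients
  res <- find_subtypes(W, k_range = 2:10, seed = 1)
  expect_true(is.na(res$k))
  expect_null(res$labels)
  expect_gt(length(res$flags), 0)
  expect_error(find_subtypes(matrix(rnorm(20), 4, 5), k_range = 2:10),
               "patients")
})

test_that("compare_subtypes summarizes clusters against ground structure", {
  set.seed(64)
  nms <- feature_catalog(c("light", "screen_on_time"), c(2, 4))$name
  d <- length(nms)
  light_idx <- grep("^light", nms)
  phone_idx <- grep("^screen_on_time", nms)
  W <- matrix(0, 14, d, dimnames = list(sprintf("P%02d", 1:14), nms))
  W[1:7, light_idx[1:4]] <- matrix(runif(28, 0.3, 0.6), 7)
  W[8:14, phone_idx[1:4]] <- matrix(runif(28, 0.3, 0.6), 7)
  res <- find_subtypes(W, k_range = 2:10, seed = 2)
  expect_equal(res$k, 2L)
  ema_means <- matrix(runif(28, 0, 3), 14, 2,
                      dimnames = list(rownames(W), c("depressed", "calm")))
  cs <- compare_subtypes(res, W, ema_means, top_n = 5)
  expect_length(cs, 2L)
  mods <- vapply(cs, function(s) {
    parse_feature_name(s$top_features$name[1])$modality
  }, character(1))
  expect_setequal(mods, c("light", "screen_on_time"))
  for (s in cs) {
    expect_equal(length(s$mean_ema), 2L)
    expect_false(s$small_cluster)
    expect_equal(nrow(s$top_features), 4L)  # only nonzero weights are ranked
  }
})
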