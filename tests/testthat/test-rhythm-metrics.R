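test_that("periodogram satisfies Parseval under the chosen normalization", {
  set.seed(5)
  for (n in c(48, 100, 336)) {
    x <- rnorm(n) + sin(2 * pi * seq_len(n) / 24)
    pg <- periodogram(x)
    z <- stats::residuals(stats::lm(x ~ seq_len(n)))
    expect_lt(abs(sum(pg$power) - mean(z^2)), 1e-8)
  }
})

test_that("band power localizes a pure 24-h cosine in the circadian bands", {
  t <- 0:(14 * 24 - 1)
  x <- cos(2 * pi * t / 24)
  bp <- psd_band_power(x)
  feasible <- bp[!is.na(bp)]
  circ <- feasible[c("22-hour_PSD", "27-hour_PSD", "28-hour_PSD")]
  expect_gt(sum(circ, na.rm = TRUE) / sum(feasible), 0.95)
})

test_that("band-power ratio of two planted cosines follows amplitude^2", {
  t <- 0:(14 * 24 - 1)
  a <- 1.7; b <- 0.6
  x <- a * cos(2 * pi * t / 24) + b * cos(2 * pi * t / 8)
  bp <- psd_band_power(x)
  ## the 24-h line sits near the 22/27-h band edge, so compare the summed
  ## circadian bands (which capture the whole line) with the 8-h band
  circ <- sum(bp[c("20-hour_PSD", "22-hour_PSD", "27-hour_PSD",
                   "28-hour_PSD")])
  ratio <- circ / bp[["8-hour_PSD"]]
  expect_lt(abs(ratio - a^2 / b^2) / (a^2 / b^2), 0.05)
})

test_that("constant series has zero band power; long periods are missing", {
  bp <- psd_band_power(rep(3, 96))   # 4-day window
  feasible <- as.numeric(sub("-hour_PSD", "", names(bp))) <= 96
  expect_true(all(bp[feasible] == 0))
  expect_true(all(is.na(bp[!feasible])))
})

test_that("M10/L5 equal an exhaustive circular-start oracle", {
  set.seed(9)
  for (i in 1:20) {
    x <- rep(runif(24, 0, 5), 4)  # 4 identical days
    ml <- m10_l5(x)
    prof <- x[1:24]
    ext <- c(prof, prof)
    m10s <- sapply(1:24, function(s) mean(ext[s:(s + 9)]))
    l5s <- sapply(1:24, function(s) mean(ext[s:(s + 4)]))
    expect_equal(unname(ml["M10"]), max(m10s))
    expect_equal(unname(ml["L5"]), min(l5s))
  }
})

test_that("M10/L5 examples: square profile and constant", {
  prof <- rep(0, 24); prof[9:18] <- 1   # active hours 8-17
  x <- rep(prof, 2)
  ml <- m10_l5(x)
  expect_equal(unname(ml["M10"]), 1)
  expect_equal(unname(ml["L5"]), 0)
  mlc <- m10_l5(rep(4.2, 48))
  expect_equal(unname(mlc["M10"]), 4.2)
  expect_equal(unname(mlc["L5"]), 4.2)
})

test_that("relative amplitude follows its closed form and range", {
  expect_equal(relative_amplitude(1, 0), 1)
  expect_equal(relative_amplitude(2, 2), 0)
  expect_equal(relative_amplitude(3, 1), 0.5)
  expect_true(is.na(relative_amplitude(0, 0)))
  set.seed(2)
  for (i in 1:200) {
    v <- sort(runif(2, 0, 10))
    ra <- relative_amplitude(v[2], v[1])
    expect_gte(ra, 0); expect_lte(ra, 1)
  }
})

test_that("template deviation: identical days give zero, oracle on a toy", {
  day <- runif(24)
  x <- rep(day, 3)
  td <- template_deviation(x)
  expect_equal(unname(td), rep(0, 6))

  ## perturb one hour of day 2; hand-compute all six statistics
  x2 <- x
  x2[24 + 5] <- x2[24 + 5] + 1.2
  td2 <- template_deviation(x2)
  template <- rowMeans(matrix(x2, nrow = 24))
  devs <- apply(matrix(x2, nrow = 24), 2, function(d) mean(abs(d - template)))
  expect_equal(unname(td2[1:3]),
               c(mean(devs), stats::median(devs), stats::sd(devs)))
  expect_equal(unname(td2[4:6]), rep(devs[3], 3))  # last-day value thrice
  ## last day equal to template -> previous-day deviation 0
  x3 <- c(day + 0.3, day - 0.3, day)
  td3 <- template_deviation(x3)
  expect_equal(unname(td3[4]), 0)
})

test_that("interday stability: periodic days give 1, noise gives ~q/n", {
  day <- runif(24, 0, 4)
  expect_equal(interday_stability(rep(day, 5)), 1)
  expect_true(is.na(interday_stability(rep(2, 96))))
  set.seed(4)
  vals <- replicate(200, interday_stability(rnorm(14 * 24)))
  se <- stats::sd(vals) / sqrt(200)
  ## white-noise expectation: E num / E denom = (q-1)/(n-1) ~ q/n = 1/14
  expect_lt(abs(mean(vals) - 23 / 335), 3 * se)
})

test_that("intraday variability: alternating = 4, noise ~2, sinusoid small", {
  x <- rep(c(1, -1), 24) * 0.7
  expect_equal(intraday_variability(x), 4)
  expect_true(is.na(intraday_variability(rep(3, 50))))
  set.seed(6)
  vals <- replicate(200, intraday_variability(rnorm(336)))
  se <- stats::sd(vals) / sqrt(200)
  expect_lt(abs(mean(vals) - 2), 3 * se + 0.02)
  slow <- sin(2 * pi * (0:335) / 24)
  expect_lt(intraday_variability(slow), 0.1)
})

test_that("periodicity classification follows the rhythm taxonomy", {
  expect_equal(categorize_periodicity("4-hour_PSD"), "ultradian")
  expect_equal(categorize_periodicity("16-hour_PSD"), "ultradian")
  expect_equal(categorize_periodicity("22-hour_PSD"), "circadian")
  expect_equal(categorize_periodicity("72-hour_PSD"), "infradian")
  expect_equal(categorize_periodicity("512-hour_PSD"), "infradian")
  expect_equal(categorize_periodicity("3-hour_MSE"), "ultradian")
  expect_equal(
    categorize_periodicity(c("M10", "L5", "amplitude", "mean_deviation",
                             "IS", "IV")),
    rep("circadian", 6))
  expect_error(categorize_periodicity("nonsense"), "unknown")
})
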