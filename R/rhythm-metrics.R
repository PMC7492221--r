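## Nonparametric circadian-rhythm metrics on the hourly grid: periodogram
## band power, M10/L5, rest-activity relative amplitude, deviation from the
## 24-h activity template, interday stability (IS) and intraday variability
## (IV).  Conventions follow the actigraphy literature; masked hours are
## excluded (or mean-imputed where a spectral estimate needs a full grid).

#' Canonical periodogram periods (hours)
#'
#' The periods at which spectral band power is extracted: 2-22 h (ultradian
#' through near-circadian), 27-28 h, and 32-512 h (infradian).
#' @export
psd_periods_default <- function() {
  c(2, 4, 8, 16, 20, 22, 27, 28, 32, 36, 64, 72, 128, 256, 512)
}

#' One-sided FFT periodogram
#'
#' Linearly detrends the series (masked hours mean-imputed first) and returns
#' the one-sided periodogram on the Fourier grid.  Under this normalization
#' the ordinates sum to the mean square of the detrended series (Parseval).
#'
#' @param series an [hourly_series] or numeric vector (`NA` = masked).
#' @return list with `freq` (cycles/hour), `power`, and `mean_square` (of the
#'   detrended series).
#' @export
periodogram <- function(series) {
  x <- as_hourly_values(series)
  obs <- !is.na(x)
  if (!any(obs)) stop("all-masked series has no spectrum", call. = FALSE)
  x[!obs] <- mean(x[obs])
  n <- length(x)
  t <- seq_len(n)
  z <- stats::residuals(stats::lm.fit(cbind(1, t), x))
  ## a (numerically) constant series has an exactly zero spectrum
  if (max(abs(z)) < 1e-10 * max(1, abs(mean(x)))) {
    z <- numeric(n)
  }
  f <- stats::fft(z)
  pg <- Mod(f)^2 / n^2
  kmax <- n %/% 2
  k <- seq_len(kmax)
  power <- 2 * pg[k + 1L]
  if (n %% 2 == 0) power[kmax] <- pg[kmax + 1L]  # Nyquist not doubled
  list(freq = k / n, power = power, mean_square = mean(z^2))
}

#' Spectral band power around listed periods
#'
#' "Area under the power spectral density curve" for each requested period:
#' the trapezoidal integral of the (linearly interpolated) one-sided
#' periodogram over the frequency band bounded by the geometric midpoints to
#' the adjacent listed periods; the outermost periods use bands symmetric in
#' log-frequency.  Periods longer than the series return `NA`.
#'
#' @param series an [hourly_series] or numeric vector (`NA` = masked,
#'   mean-imputed).
#' @param periods_h periods in hours (default [psd_periods_default()]).
#' @return named numeric vector of band powers.
#' @export
psd_band_power <- function(series, periods_h = psd_periods_default()) {
  x <- as_hourly_values(series)
  if (all(is.na(x))) {
    return(stats::setNames(rep(NA_real_, length(periods_h)),
                           paste0(periods_h, "-hour_PSD")))
  }
  n <- length(x)
  pg <- periodogram(series)
  out <- stats::setNames(rep(NA_real_, length(periods_h)),
                         paste0(periods_h, "-hour_PSD"))

  o <- order(periods_h, decreasing = TRUE)   # ascending frequency
  f_c <- 1 / periods_h[o]
  m <- length(f_c)
  lo <- hi <- numeric(m)
  for (i in seq_len(m)) {
    lo[i] <- if (i == 1L) f_c[1L]^2 / sqrt(f_c[1L] * f_c[2L])
             else sqrt(f_c[i] * f_c[i - 1L])
    hi[i] <- if (i == m) f_c[m]^2 / sqrt(f_c[m] * f_c[m - 1L])
             else sqrt(f_c[i] * f_c[i + 1L])
  }

  fg <- pg$freq
  for (i in seq_len(m)) {
    p <- periods_h[o[i]]
    if (p > n) next                          # unresolvable within the window
    a <- max(lo[i], fg[1L])
    b <- min(hi[i], fg[length(fg)])
    if (b <= a) { out[paste0(p, "-hour_PSD")] <- 0; next }
    inside <- fg > a & fg < b
    grid <- c(a, fg[inside], b)
    vals <- stats::approx(fg, pg$power, xout = grid, rule = 2)$y
    out[paste0(p, "-hour_PSD")] <- trapz(grid, vals)
  }
  out
}

#' M10 and L5
#'
#' Mean level over the most active 10 and least active 5 *consecutive* hours
#' of the average 24-h profile of the window (hour-of-day means, circular
#' runs).  If any hour-of-day has no observation in the whole window, both
#' are `NA`.
#'
#' @param series an [hourly_series] or numeric vector (`NA` = masked).
#' @return named numeric vector `c(M10 = , L5 = )`.
#' @export
m10_l5 <- function(series) {
  prof <- day_profile(series)
  if (anyNA(prof)) return(c(M10 = NA_real_, L5 = NA_real_))
  run_mean <- function(len) {
    ext <- c(prof, prof[seq_len(len - 1L)])
    vapply(1:24, function(s) mean(ext[s:(s + len - 1L)]), numeric(1))
  }
  c(M10 = max(run_mean(10L)), L5 = min(run_mean(5L)))
}

## Hour-of-day means (24 values), respecting the series' start hour.
day_profile <- function(series) {
  x <- as_hourly_values(series)
  h0 <- start_hour_of_day(series)
  hod <- (h0 + seq_along(x) - 1L) %% 24L
  vapply(0:23, function(h) {
    v <- x[hod == h]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, numeric(1))
}

#' Rest-activity relative amplitude
#'
#' `RA = (M10 - L5) / (M10 + L5)`, the normalized day-night activity
#' contrast, in `[0, 1]` for non-negative activity levels.
#'
#' @param m10,l5 mean activity over the most active 10 h / least active 5 h.
#' @return scalar in `[0, 1]`, `NA` when `M10 + L5 == 0` or inputs missing.
#' @export
relative_amplitude <- function(m10, l5) {
  if (is.na(m10) || is.na(l5)) return(NA_real_)
  if (m10 + l5 <= 0) return(NA_real_)
  (m10 - l5) / (m10 + l5)
}

#' Deviation from the 24-h activity template
#'
#' The template is the hour-of-day mean profile over the window.  For every
#' day the deviation is the mean absolute difference between that day's
#' hourly values and the template.  Returns the mean, median and SD of the
#' per-day deviations, plus the previous (last) day's deviation.  A single
#' number has no spread, so the previous-day value fills all three of its
#' slots.
#'
#' @param series an [hourly_series] or numeric vector covering whole days
#'   (`NA` = masked).
#' @return named numeric vector of six values (`mean_deviation`,
#'   `median_deviation`, `std_deviation`, `prev_mean_deviation`,
#'   `prev_median_deviation`, `prev_std_deviation`).
#' @export
template_deviation <- function(series) {
  x <- as_hourly_values(series)
  nms <- c("mean_deviation", "median_deviation", "std_deviation",
           "prev_mean_deviation", "prev_median_deviation", "prev_std_deviation")
  out <- stats::setNames(rep(NA_real_, 6L), nms)
  nd <- length(x) %/% 24L
  if (nd < 2L) return(out)
  mat <- matrix(x[seq_len(nd * 24L)], nrow = 24L)   # hours x days
  template <- rowMeans(mat, na.rm = TRUE)
  if (anyNA(template)) return(out)                   # some hour never observed
  dev <- apply(mat, 2L, function(day) {
    d <- abs(day - template)
    if (all(is.na(d))) NA_real_ else mean(d, na.rm = TRUE)
  })
  ok <- !is.na(dev)
  if (sum(ok) < 2L || is.na(dev[nd])) return(out)
  out["mean_deviation"] <- mean(dev[ok])
  out["median_deviation"] <- stats::median(dev[ok])
  out["std_deviation"] <- stats::sd(dev[ok])
  out[4:6] <- dev[nd]
  out
}

#' Interday stability
#'
#' Day-to-day reproducibility of the 24-h profile:
#' `IS = n * sum_h (xbar_h - xbar)^2 / (q * sum_i (x_i - xbar)^2)` with
#' hour-of-day means `xbar_h` over `q` hour bins.  Equals 1 for an exactly
#' day-periodic series and about `q/n` for white noise.
#'
#' @param series an [hourly_series] or numeric vector (`NA` = masked).
#' @return scalar; `NA` for a constant series or fewer than 2 days.
#' @export
interday_stability <- function(series) {
  x <- as_hourly_values(series)
  if (length(x) < 48L) return(NA_real_)
  obs <- !is.na(x)
  n <- sum(obs)
  if (n < 24L) return(NA_real_)
  xbar <- mean(x[obs])
  denom <- sum((x[obs] - xbar)^2)
  if (denom <= 0) return(NA_real_)
  h0 <- start_hour_of_day(series)
  hod <- (h0 + seq_along(x) - 1L) %% 24L
  hmeans <- tapply(x[obs], hod[obs], mean)
  q <- length(hmeans)
  n * sum((hmeans - xbar)^2) / (q * denom)
}

#' Intraday variability
#'
#' Hour-to-hour fragmentation:
#' `IV = n * sum (x_i - x_{i-1})^2 / ((n - 1) * sum (x_i - xbar)^2)`, with
#' successive differences taken only within unmasked runs.  Equals exactly 4
#' for an alternating sequence and about 2 for white noise.
#'
#' @param series an [hourly_series] or numeric vector (`NA` = masked).
#' @return scalar; `NA` for a constant series or fewer than 3 points.
#' @export
intraday_variability <- function(series) {
  x <- as_hourly_values(series)
  obs <- !is.na(x)
  n <- sum(obs)
  if (n < 3L) return(NA_real_)
  xbar <- mean(x[obs])
  denom <- sum((x[obs] - xbar)^2)
  if (denom <= 0) return(NA_real_)
  d <- diff(x)                       # NA across masked boundaries
  d <- d[!is.na(d)]
  if (length(d) == 0L) return(NA_real_)
  n * sum(d^2) / ((n - 1) * denom)
}

#' Periodicity class of a rhythm metric
#'
#' Maps a metric identifier to its rhythm class: multiscale entropy and
#' spectral power at periods below 20 h are ultradian; M10, L5, relative
#' amplitude, template deviation, IS, IV and spectral power between 20 and
#' 30 h are circadian; spectral power above 30 h is infradian.
#'
#' @param metric metric identifier, e.g. `"3-hour_MSE"`, `"72-hour_PSD"`,
#'   `"amplitude"`, `"M10"`, `"mean_deviation"`, `"IS"`.
#' @return `"ultradian"`, `"circadian"` or `"infradian"`.
#' @export
categorize_periodicity <- function(metric) {
  vapply(metric, function(m) {
    if (grepl("^[0-9.]+-hour_MSE$", m)) return("ultradian")
    if (grepl("^[0-9.]+-hour_PSD$", m)) {
      p <- as.numeric(sub("-hour_PSD$", "", m))
      if (p < 20) return("ultradian")
      if (p <= 30) return("circadian")
      return("infradian")
    }
    circ <- c("M10", "L5", "amplitude", "IS", "IV",
              "mean_deviation", "median_deviation", "std_deviation",
              "prev_mean_deviation", "prev_median_deviation",
              "prev_std_deviation")
    if (m %in% circ) return("circadian")
    stop(sprintf("unknown rhythm metric: '%s'", m), call. = FALSE)
  }, character(1), USE.NAMES = FALSE)
}
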