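## Sample entropy and its multiscale extension.  SampEn(m, r) is
## -ln(A/B) where B counts template pairs of length m and A pairs of length
## m + 1 within Chebyshev tolerance r, self-matches excluded.  Multiscale
## entropy evaluates SampEn on coarse-grained copies of the series at scales
## tau = 1..6, i.e. behavioral complexity at the 1-6 h time scales.

#' Sample entropy
#'
#' Conditional-probability irregularity measure of a time series: the negative
#' log of the probability that two templates matching at length `m` (within
#' Chebyshev tolerance `r`) still match at length `m + 1`.  Self-matches are
#' excluded.  Returns `NA` when either template count is zero (the measure is
#' undefined).
#'
#' @param x numeric vector (no `NA`s).
#' @param m template length (default 2).
#' @param r tolerance, on the scale of `x` (absolute, not a fraction of the
#'   standard deviation).
#' @return non-negative scalar, or `NA_real_` when undefined.
#' @export
sample_entropy <- function(x, m = 2L, r) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("`x` must not contain NA; impute or slice first", call. = FALSE)
  stopifnot_scalar(r, "r")
  if (r < 0) stop("`r` must be >= 0", call. = FALSE)
  m <- as.integer(m)
  if (m < 1L) stop("`m` must be >= 1", call. = FALSE)
  n <- length(x)
  if (n <= m + 1L) return(NA_real_)
  cnt <- sampen_counts(x, m, r)
  if (cnt$A == 0 || cnt$B == 0) return(NA_real_)
  -log(cnt$A / cnt$B)
}

#' Coarse-grain a series
#'
#' Non-overlapping block means at scale `tau`: element `j` of the output is
#' the mean of elements `(j-1)*tau + 1` to `j*tau`; a trailing partial block
#' is dropped.
#'
#' @param x numeric vector.
#' @param tau integer scale, >= 1.
#' @return numeric vector of length `floor(length(x) / tau)`.
#' @export
coarse_grain <- function(x, tau) {
  tau <- as.integer(tau)
  if (is.na(tau) || tau < 1L) stop("`tau` must be an integer >= 1", call. = FALSE)
  x <- as.numeric(x)
  if (tau == 1L) return(x)
  nb <- length(x) %/% tau
  if (nb == 0L) stop("series shorter than one block at scale tau", call. = FALSE)
  colMeans(matrix(x[seq_len(nb * tau)], nrow = tau))
}

#' Multiscale entropy
#'
#' Sample entropy of the coarse-grained series at scales `tau = 1..6`, with
#' `m = 2` and a tolerance of `r_frac` times the standard deviation of the
#' *original* (scale-1) series, held fixed across scales (the standard
#' multiscale-entropy convention).  On the hourly grid the scales capture
#' complexity at the 1-6 h time scales.
#'
#' Masked hours are mean-imputed when overall coverage is at least
#' `min_coverage`; otherwise (and for constant series, whose tolerance
#' degenerates to zero) all scales are `NA`.
#'
#' @param series an [hourly_series] or numeric vector (`NA` = masked).
#' @param scales integer scales (default `1:6`).
#' @param m template length (default 2).
#' @param r_frac tolerance as a fraction of the series SD (default 0.25).
#' @param min_coverage minimum fraction of observed hours (default 0.7).
#' @return named numeric vector, one entry per scale (`NA` where undefined).
#' @export
multiscale_entropy <- function(series, scales = 1:6, m = 2L, r_frac = 0.25,
                               min_coverage = 0.7) {
  x <- as_hourly_values(series)
  out <- stats::setNames(rep(NA_real_, length(scales)),
                         paste0(scales, "-hour_MSE"))
  obs <- !is.na(x)
  if (length(x) == 0L || mean(obs) < min_coverage) return(out)
  s <- stats::sd(x[obs])
  if (!is.finite(s) || s <= 0) return(out)  # degenerate: r would be 0
  r <- r_frac * s
  x[!obs] <- mean(x[obs])
  for (i in seq_along(scales)) {
    tau <- scales[i]
    if (length(x) %/% tau <= m + 1L) next
    y <- coarse_grain(x, tau)
    out[i] <- sample_entropy(y, m = m, r = r)
  }
  out
}
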