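## Windowed rhythm feature extraction.  Every feature is named
## [Modality](x)[Rhythm Metric](x)[Window Length] with the circled-times
## separator, e.g. "light⊗amplitude⊗2-day_window", and carries a
## (modality, metric, window, periodicity) tag.

FEATURE_SEP <- "\u2297"  # the circled-times (⊗) separator

## Modalities treated as continuous-valued series; IS and IV apply only to
## these (accelerometer, ambient light, ambient sound).
CONTINUOUS_IS_IV <- c("acceleration", "light", "sound")

metric_names <- function(psd_periods = psd_periods_default(),
                         is_iv = FALSE) {
  c(paste0(1:6, "-hour_MSE"),
    paste0(psd_periods, "-hour_PSD"),
    "M10", "L5", "amplitude",
    "mean_deviation", "median_deviation", "std_deviation",
    "prev_mean_deviation", "prev_median_deviation", "prev_std_deviation",
    if (is_iv) c("IS", "IV"))
}

#' Compose a feature name
#' @param modality sensor modality.
#' @param metric rhythm metric identifier.
#' @param window_days window length in days.
#' @return character name in the canonical `modality (x) metric (x) window`
#'   format.
#' @export
feature_name <- function(modality, metric, window_days) {
  paste(modality, metric, paste0(window_days, "-day_window"),
        sep = FEATURE_SEP)
}

#' Parse feature names into their three dimensions
#'
#' @param names character vector of canonical feature names.
#' @return data frame with columns `name`, `modality`, `metric`,
#'   `window_days`, `periodicity`.
#' @export
parse_feature_name <- function(names) {
  parts <- strsplit(names, FEATURE_SEP, fixed = TRUE)
  bad <- lengths(parts) != 3L
  if (any(bad)) {
    stop("unparseable feature name(s): ",
         paste(utils::head(names[bad], 3L), collapse = ", "), call. = FALSE)
  }
  modality <- vapply(parts, `[[`, character(1), 1L)
  metric <- vapply(parts, `[[`, character(1), 2L)
  win <- vapply(parts, `[[`, character(1), 3L)
  if (!all(grepl("^[0-9]+-day_window$", win))) {
    stop("unparseable window tag in feature name", call. = FALSE)
  }
  window_days <- as.integer(sub("-day_window$", "", win))
  data.frame(name = names, modality = modality, metric = metric,
             window_days = window_days,
             periodicity = categorize_periodicity(metric),
             stringsAsFactors = FALSE)
}

#' The canonical feature catalog
#'
#' Enumerates, in fixed order, every feature produced for a given set of
#' modalities and window lengths: six multiscale-entropy scales, the spectral
#' band powers, M10/L5/relative amplitude, six template-deviation statistics,
#' and (for continuous modalities) IS and IV, for every window length.
#'
#' @param modalities character vector of modality names.
#' @param windows window lengths in days (default `c(2,4,6,8,10,12,14)`).
#' @param psd_periods periodogram periods (default [psd_periods_default()]).
#' @param continuous modalities for which IS/IV are computed.
#' @return data frame as from [parse_feature_name()].
#' @export
feature_catalog <- function(modalities,
                            windows = c(2, 4, 6, 8, 10, 12, 14),
                            psd_periods = psd_periods_default(),
                            continuous = intersect(modalities, CONTINUOUS_IS_IV)) {
  rows <- list()
  for (mod in modalities) {
    for (w in sort(windows)) {
      mets <- metric_names(psd_periods, is_iv = mod %in% continuous)
      rows[[length(rows) + 1L]] <- data.frame(
        name = feature_name(mod, mets, w),
        modality = mod, metric = mets, window_days = as.integer(w),
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out$periodicity <- categorize_periodicity(out$metric)
  rownames(out) <- NULL
  out
}

#' Extract the rhythm feature vector for one EMA date and window
#'
#' Applies every applicable rhythm metric to every modality over the window
#' `[d - w, d)` of whole days anchored at midnight (UTC) of the EMA date `d`.
#' Windows reaching before the start of a series, and modality-windows with
#' less than `min_coverage` observed hours (after interpolating gaps of at
#' most 3 h), yield `NA` features.
#'
#' @param series named list of [hourly_series], one per modality, covering
#'   the patient's observation span.
#' @param ema_date the EMA report date (`Date`).
#' @param window_days window length in days.
#' @param psd_periods periodogram periods.
#' @param continuous modalities receiving IS/IV.
#' @param min_coverage minimum fraction of observed hours per modality-window.
#' @return named numeric feature vector, in catalog order for this window.
#' @export
extract_features <- function(series, ema_date, window_days,
                             psd_periods = psd_periods_default(),
                             continuous = intersect(names(series),
                                                    CONTINUOUS_IS_IV),
                             min_coverage = 0.7) {
  d <- as.Date(ema_date)
  to <- as.POSIXct(paste(d, "00:00:00"), tz = "UTC")
  from <- to - window_days * 86400
  out <- list()
  for (mod in names(series)) {
    is_iv <- mod %in% continuous
    mets <- metric_names(psd_periods, is_iv = is_iv)
    vals <- stats::setNames(rep(NA_real_, length(mets)), mets)
    win <- slice_hours(series[[mod]], from, to)
    win <- fill_gaps(win, max_gap = 3L)
    x <- win$values
    if (mean(!is.na(x)) >= min_coverage) {
      mse <- multiscale_entropy(win, min_coverage = min_coverage)
      vals[names(mse)] <- mse
      psd <- psd_band_power(win, periods_h = psd_periods)
      vals[names(psd)] <- psd
      ml <- m10_l5(win)
      vals["M10"] <- ml["M10"]
      vals["L5"] <- ml["L5"]
      vals["amplitude"] <- relative_amplitude(ml["M10"], ml["L5"])
      td <- template_deviation(win)
      vals[names(td)] <- td
      if (is_iv) {
        vals["IS"] <- interday_stability(win)
        vals["IV"] <- intraday_variability(win)
      }
    }
    names(vals) <- feature_name(mod, mets, window_days)
    out[[mod]] <- vals
  }
  do.call(c, unname(out))
}

#' Build the per-patient feature matrix and label matrix
#'
#' One row per EMA record; columns are the full canonical catalog (all
#' windows x metrics x modalities), identical across patients given the same
#' configuration.  Rows with more than `max_missing` missing features are
#' dropped; remaining missing values are imputed with the patient's
#' per-feature median (0 when a feature is missing in every retained row).
#'
#' @param series named list of [hourly_series] per modality.
#' @param ema data frame with a `date` column and one column per EMA item.
#' @param windows window lengths in days.
#' @param psd_periods periodogram periods.
#' @param continuous modalities receiving IS/IV.
#' @param min_coverage per-window coverage threshold.
#' @param max_missing maximum fraction of missing features per row (default
#'   0.5).
#' @return list with `X` (rows x features matrix), `Y` (rows x items matrix),
#'   `dates` (retained EMA dates), `dropped` (dropped EMA dates), and
#'   `catalog`.  `X` has zero rows when every row was dropped.
#' @export
build_feature_matrix <- function(series, ema,
                                 windows = c(2, 4, 6, 8, 10, 12, 14),
                                 psd_periods = psd_periods_default(),
                                 continuous = intersect(names(series),
                                                        CONTINUOUS_IS_IV),
                                 min_coverage = 0.7,
                                 max_missing = 0.5) {
  stopifnot(nrow(ema) >= 1L, "date" %in% names(ema))
  catalog <- feature_catalog(names(series), windows, psd_periods, continuous)
  dates <- as.Date(ema$date)
  item_cols <- setdiff(names(ema), "date")
  X <- matrix(NA_real_, nrow = length(dates), ncol = nrow(catalog),
              dimnames = list(as.character(dates), catalog$name))
  for (i in seq_along(dates)) {
    row <- unlist(lapply(sort(windows), function(w) {
      extract_features(series, dates[i], w, psd_periods = psd_periods,
                       continuous = continuous, min_coverage = min_coverage)
    }))
    X[i, names(row)] <- row
  }
  miss_frac <- rowMeans(is.na(X))
  keep <- miss_frac <= max_missing
  dropped <- dates[!keep]
  X <- X[keep, , drop = FALSE]
  Y <- as.matrix(ema[keep, item_cols, drop = FALSE])
  rownames(Y) <- rownames(X)
  if (nrow(X) > 0L) {
    med <- apply(X, 2L, stats::median, na.rm = TRUE)
    med[!is.finite(med)] <- 0
    for (j in which(colSums(is.na(X)) > 0L)) {
      X[is.na(X[, j]), j] <- med[j]
    }
  }
  list(X = X, Y = Y, dates = dates[keep], dropped = dropped,
       catalog = catalog)
}
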