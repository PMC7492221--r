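## HourlySeries: a regular hourly grid with an availability mask.  This is the
## common currency of all rhythm metrics: event streams become hourly counts,
## continuous streams hourly means, and every metric below consumes it.

#' Construct an hourly series
#'
#' A regular hourly grid of values starting at a given UTC hour.  Masked
#' (unavailable) hours are stored as `NA`; all metrics exclude them.
#'
#' @param values numeric vector, one element per hour; `NA` marks masked hours.
#' @param start `POSIXct` timestamp of the first hour (truncated to the hour,
#'   UTC).  Defaults to midnight 2020-01-01 UTC, which is only a label: the
#'   metrics depend on the hour-of-day of `start`, not its calendar date.
#' @return an object of class `hourly_series`.
#' @export
hourly_series <- function(values,
                          start = as.POSIXct("2020-01-01 00:00:00", tz = "UTC")) {
  if (!is.numeric(values)) stop("`values` must be numeric", call. = FALSE)
  start <- as.POSIXct(start, tz = "UTC")
  start <- trunc(start, units = "hours")
  structure(
    list(values = as.numeric(values), start = start),
    class = "hourly_series"
  )
}

#' @export
length.hourly_series <- function(x) length(x$values)

#' @export
print.hourly_series <- function(x, ...) {
  n <- length(x$values)
  cat(sprintf(
    "<hourly_series> %d h from %s UTC (%.1f%% observed)\n",
    n, format(x$start, "%Y-%m-%d %H:%M"),
    if (n) 100 * mean(!is.na(x$values)) else NA_real_
  ))
  invisible(x)
}

## Accept either an hourly_series or a bare numeric vector (assumed to start
## at hour-of-day 0).
as_hourly_values <- function(x) {
  if (inherits(x, "hourly_series")) x$values else as.numeric(x)
}

start_hour_of_day <- function(x) {
  if (inherits(x, "hourly_series")) {
    as.integer(format(x$start, "%H", tz = "UTC"))
  } else {
    0L
  }
}

#' Bin a raw sensor stream to the hourly grid
#'
#' Event streams become counts per hour; continuous streams become the mean of
#' the samples falling in each hour, with sample-free hours masked (`NA`).
#' An entirely empty stream yields a fully masked series over the requested
#' span.
#'
#' @param stream data frame with a `timestamp` column (`POSIXct` or ISO-8601
#'   character, UTC) and, for continuous streams, a `value` column.
#' @param kind `"event"` or `"continuous"`.
#' @param start,end span of the output grid (`POSIXct`, UTC); `end` is
#'   exclusive.  Defaults to the stream's own extent (required for an empty
#'   stream).
#' @return an [hourly_series].
#' @export
bin_hourly <- function(stream, kind = c("event", "continuous"),
                       start = NULL, end = NULL) {
  kind <- match.arg(kind)
  ts <- stream$timestamp
  if (is.character(ts)) ts <- as.POSIXct(ts, tz = "UTC")
  if (!is.null(ts) && is.unsorted(ts)) {
    o <- order(ts)
    ts <- ts[o]
    stream <- stream[o, , drop = FALSE]
  }
  if (is.null(start)) {
    if (length(ts) == 0L) {
      stop("empty stream: an explicit `start`/`end` span is required",
           call. = FALSE)
    }
    start <- ts[1L]
  }
  start <- trunc(as.POSIXct(start, tz = "UTC"), units = "hours")
  if (is.null(end)) {
    if (length(ts) == 0L) {
      stop("empty stream: an explicit `start`/`end` span is required",
           call. = FALSE)
    }
    end <- ts[length(ts)] + 1
  }
  end <- as.POSIXct(end, tz = "UTC")
  n_hours <- ceiling(as.numeric(difftime(end, start, units = "hours")))
  if (n_hours < 1L) stop("requested span contains no whole hour", call. = FALSE)

  if (length(ts) == 0L) {
    return(hourly_series(rep(NA_real_, n_hours), start = start))
  }

  idx <- floor(as.numeric(difftime(ts, start, units = "hours"))) + 1L
  keep <- idx >= 1L & idx <= n_hours
  idx <- idx[keep]

  if (kind == "event") {
    counts <- tabulate(idx, nbins = n_hours)
    hourly_series(as.numeric(counts), start = start)
  } else {
    vals <- stream$value[keep]
    sums <- rep(0, n_hours)
    ns <- rep(0L, n_hours)
    ok <- !is.na(vals)
    agg_sum <- tapply(vals[ok], idx[ok], sum)
    agg_n <- tapply(vals[ok], idx[ok], length)
    at <- as.integer(names(agg_sum))
    sums[at] <- agg_sum
    ns[at] <- agg_n
    out <- ifelse(ns > 0L, sums / pmax(ns, 1L), NA_real_)
    hourly_series(out, start = start)
  }
}

#' Interpolate short masked gaps
#'
#' Linearly interpolates masked runs of at most `max_gap` hours that are
#' flanked by observed hours; longer gaps (and leading/trailing gaps) stay
#' masked.
#'
#' @param series an [hourly_series] (or numeric vector with `NA`s).
#' @param max_gap longest gap, in hours, to fill (default 3).
#' @return object of the same type as `series`.
#' @export
fill_gaps <- function(series, max_gap = 3L) {
  x <- as_hourly_values(series)
  na <- is.na(x)
  if (!any(na) || all(na)) return(series)
  r <- rle(na)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in seq_along(r$lengths)) {
    if (!r$values[k] || r$lengths[k] > max_gap) next
    i0 <- starts[k] - 1L
    i1 <- ends[k] + 1L
    if (i0 < 1L || i1 > length(x)) next
    gap <- seq.int(starts[k], ends[k])
    x[gap] <- x[i0] + (x[i1] - x[i0]) * (gap - i0) / (i1 - i0)
  }
  if (inherits(series, "hourly_series")) {
    series$values <- x
    series
  } else {
    x
  }
}

## Slice a window of whole days [from, to) out of an hourly series, where
## `from`/`to` are POSIXct hour boundaries.  Hours outside the series extent
## are NA (masked) and flagged.
slice_hours <- function(series, from, to) {
  stopifnot(inherits(series, "hourly_series"))
  n <- length(series$values)
  i0 <- round(as.numeric(difftime(from, series$start, units = "hours"))) + 1L
  i1 <- round(as.numeric(difftime(to, series$start, units = "hours")))
  len <- i1 - i0 + 1L
  out <- rep(NA_real_, len)
  src <- seq.int(max(i0, 1L), min(i1, n))
  if (length(src) > 0L && src[1L] <= src[length(src)]) {
    out[src - i0 + 1L] <- series$values[src]
  }
  hourly_series(out, start = from)
}
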