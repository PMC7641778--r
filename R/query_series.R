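#' Daily query-fraction series
#'
#' A `query_series` holds one geography x topic daily time series of query
#' fractions: searches matching a term set per 10 million total searches from
#' that geography on that day. The date grid is contiguous (spacing exactly
#' one calendar day); days with no data carry `NA`, never a silently skipped
#' row.
#'
#' @param geography Geography code ("US" for national, otherwise a state/DC
#'   postal code such as "MN" or "DC").
#' @param topic Topic label, e.g. "reform", "training", "union", "immunity",
#'   "militarization".
#' @param dates `Date` vector, strictly increasing with spacing exactly 1 day.
#' @param values Non-negative numeric query fractions (per 10 million), same
#'   length as `dates`; `NA` marks a missing day.
#' @return An object of class `query_series`.
#' @examples
#' qs <- query_series("US", "reform", as.Date("2020-01-01") + 0:2, c(1, 2, 3))
#' qs
#' @export
query_series <- function(geography, topic, dates, values) {
  stopifnot(is.character(geography), length(geography) == 1L,
            is.character(topic), length(topic) == 1L)
  dates <- as.Date(dates)
  values <- as.numeric(values)
  if (length(dates) == 0L)
    stop("query_series requires at least one day", call. = FALSE)
  if (length(dates) != length(values))
    stop("dates and values must have equal length", call. = FALSE)
  if (anyNA(dates))
    stop("dates must not contain NA", call. = FALSE)
  if (length(dates) > 1L) {
    dd <- as.integer(diff(dates))
    if (any(dd <= 0L))
      stop("dates must be strictly increasing with no duplicates",
           call. = FALSE)
    if (any(dd != 1L))
      stop("date grid must be contiguous (1-day spacing); represent missing ",
           "days as NA values", call. = FALSE)
  }
  if (any(values < 0, na.rm = TRUE))
    stop("query fractions must be non-negative", call. = FALSE)
  structure(list(geography = geography, topic = topic,
                 dates = dates, values = values),
            class = "query_series")
}

#' @export
print.query_series <- function(x, ...) {
  cat(sprintf("<query_series> %s / %s: %d days (%s .. %s), %d missing\n",
              x$geography, x$topic, length(x$dates),
              format(min(x$dates)), format(max(x$dates)),
              sum(is.na(x$values))))
  invisible(x)
}

#' @export
length.query_series <- function(x) length(x$dates)

#' Analysis window around an event
#'
#' Splits time into a baseline period `[baseline_start, event_date)` used for
#' model fitting and a closed post-event period `[event_date, post_end]` over
#' which excess is measured. The event day belongs to the post period because
#' search surges begin on the day of the event itself.
#'
#' @param baseline_start,event_date,post_end Dates (coercible via `as.Date`)
#'   with `baseline_start < event_date <= post_end`.
#' @return An object of class `analysis_window`.
#' @examples
#' analysis_window("2010-01-01", "2020-05-25", "2020-07-05")
#' @export
analysis_window <- function(baseline_start, event_date, post_end) {
  baseline_start <- as.Date(baseline_start)
  event_date <- as.Date(event_date)
  post_end <- as.Date(post_end)
  if (!(baseline_start < event_date))
    stop("baseline_start must precede event_date", call. = FALSE)
  if (!(event_date <= post_end))
    stop("event_date must not be after post_end", call. = FALSE)
  structure(list(baseline_start = baseline_start, event_date = event_date,
                 post_end = post_end),
            class = "analysis_window")
}

#' @export
print.analysis_window <- function(x, ...) {
  cat(sprintf("<analysis_window> baseline [%s, %s), post [%s, %s] (%d days)\n",
              format(x$baseline_start), format(x$event_date),
              format(x$event_date), format(x$post_end),
              as.integer(x$post_end - x$event_date) + 1L))
  invisible(x)
}

#' Split a series into baseline and post-event parts
#'
#' The baseline part covers `[baseline_start, event_date)` (event day
#' excluded); the post part covers the closed interval
#' `[event_date, post_end]`. Concatenating the two restores the sliced range.
#'
#' @param series A [query_series].
#' @param window An [analysis_window] lying inside the series' date span.
#' @return A list with elements `baseline` and `post`, both `query_series`.
#' @examples
#' qs <- query_series("US", "reform", as.Date("2020-05-20") + 0:10, rep(1, 11))
#' w <- analysis_window("2020-05-20", "2020-05-25", "2020-05-30")
#' sw <- slice_window(qs, w)
#' length(sw$baseline); length(sw$post)
#' @export
slice_window <- function(series, window) {
  stopifnot(inherits(series, "query_series"),
            inherits(window, "analysis_window"))
  span <- range(series$dates)
  if (window$baseline_start < span[1] || window$post_end > span[2])
    stop(sprintf("window [%s, %s] outside series span [%s, %s]",
                 format(window$baseline_start), format(window$post_end),
                 format(span[1]), format(span[2])), call. = FALSE)
  base_idx <- series$dates >= window$baseline_start &
    series$dates < window$event_date
  post_idx <- series$dates >= window$event_date &
    series$dates <= window$post_end
  if (!any(base_idx))
    stop("empty baseline: event_date coincides with the first date in the window",
         call. = FALSE)
  list(
    baseline = query_series(series$geography, series$topic,
                            series$dates[base_idx], series$values[base_idx]),
    post = query_series(series$geography, series$topic,
                        series$dates[post_idx], series$values[post_idx])
  )
}

#' Interpolate short gaps in a series
#'
#' ARIMA fitting needs a complete regular grid. Gaps (runs of `NA`) of at most
#' `max_gap` consecutive days are filled by linear interpolation between the
#' flanking observed values; a longer gap, or missing values at either end of
#' the series, is an error.
#'
#' @param series A [query_series].
#' @param max_gap Maximum run length of consecutive missing days to fill
#'   (default 3).
#' @return The series with gaps filled; attribute `n_interpolated` counts
#'   filled days.
#' @export
fill_gaps <- function(series, max_gap = 3L) {
  stopifnot(inherits(series, "query_series"))
  v <- series$values
  if (!anyNA(v)) {
    attr(series, "n_interpolated") <- 0L
    return(series)
  }
  if (is.na(v[1L]) || is.na(v[length(v)]))
    stop("cannot interpolate missing values at the series boundary",
         call. = FALSE)
  r <- rle(is.na(v))
  if (max(r$lengths[r$values]) > max_gap)
    stop(sprintf("gap of %d consecutive missing days exceeds max_gap = %d",
                 max(r$lengths[r$values]), max_gap), call. = FALSE)
  n_miss <- sum(is.na(v))
  filled <- stats::approx(x = which(!is.na(v)), y = v[!is.na(v)],
                          xout = seq_along(v))$y
  out <- query_series(series$geography, series$topic, series$dates, filled)
  attr(out, "n_interpolated") <- n_miss
  out
}
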