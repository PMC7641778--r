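#' Read query-fraction series from CSV
#'
#' Two dialects are supported:
#' \describe{
#'   \item{`"long"`}{header `geography,topic,date,qf`, one row per
#'     geography/topic/day. Non-contiguous dates are expanded to a full daily
#'     grid with `NA` for the missing days.}
#'   \item{`"trends_widetable"`}{the public Google Trends export: one preamble
#'     line (category), one blank line, then a header `Day,<series>,...` and
#'     one column per series. Cells reading `"<1"` are censored low values and
#'     are imputed with `lt_value`. Column names become topic labels; the
#'     whole file is attributed to a single `geography` (Trends exports one
#'     geography per file).}
#' }
#'
#' The public Trends dialect is on a 0-100 relative scale, not query fractions
#' per 10 million; supply `scale` to convert (values are multiplied by it),
#' otherwise analyses run on the relative scale and absolute-volume conversion
#' is meaningless.
#'
#' @param path CSV file path.
#' @param dialect `"long"` (default) or `"trends_widetable"`.
#' @param geography Geography code for the wide dialect (default `"US"`).
#' @param lt_value Imputation value for `"<1"` cells (default 0.5, the
#'   midpoint of the censored interval).
#' @param scale Optional positive multiplier applied to wide-dialect values.
#' @return A named list of [query_series] (names `"<geography>/<topic>"`).
#' @export
read_series_csv <- function(path, dialect = c("long", "trends_widetable"),
                            geography = "US", lt_value = 0.5, scale = NULL) {
  dialect <- match.arg(dialect)
  if (dialect == "long") read_series_long(path)
  else read_series_widetable(path, geography, lt_value, scale)
}

series_key <- function(geography, topic) paste(geography, topic, sep = "/")

read_series_long <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("geography", "topic", "date", "qf")
  if (!all(need %in% names(df)))
    stop("long dialect requires columns geography,topic,date,qf", call. = FALSE)
  dates <- as.Date(df$date, format = "%Y-%m-%d")
  bad <- which(is.na(dates))
  if (length(bad))
    stop(sprintf("malformed date %-10s at data row %d", df$date[bad[1]], bad[1]),
         call. = FALSE)
  qf <- suppressWarnings(as.numeric(df$qf))
  bad <- which(is.na(qf) & !(df$qf %in% c("", "NA")))
  if (length(bad))
    stop(sprintf("non-numeric qf value '%s' at data row %d", df$qf[bad[1]], bad[1]),
         call. = FALSE)
  bad <- which(qf < 0)
  if (length(bad))
    stop(sprintf("negative qf value at data row %d", bad[1]), call. = FALSE)
  key <- series_key(df$geography, df$topic)
  dup <- which(duplicated(paste(key, dates)))
  if (length(dup))
    stop(sprintf("duplicate (geography, topic, date) at data row %d", dup[1]),
         call. = FALSE)
  out <- lapply(split(seq_len(nrow(df)), key), function(ix) {
    d <- dates[ix]; v <- qf[ix]
    o <- order(d); d <- d[o]; v <- v[o]
    grid <- seq(min(d), max(d), by = "day")
    full <- rep(NA_real_, length(grid))
    full[match(d, grid)] <- v
    query_series(df$geography[ix[1]], df$topic[ix[1]], grid, full)
  })
  out[order(names(out))]
}

read_series_widetable <- function(path, geography, lt_value, scale) {
  header <- readLines(path, n = 3L)
  if (length(header) < 3L)
    stop("trends_widetable file must have 2 preamble lines plus a header",
         call. = FALSE)
  df <- utils::read.csv(path, skip = 2L, check.names = FALSE,
                        colClasses = "character")
  if (names(df)[1] != "Day")
    stop("trends_widetable header must start with 'Day'", call. = FALSE)
  dates <- as.Date(df$Day, format = "%Y-%m-%d")
  if (anyNA(dates))
    stop(sprintf("malformed date at data row %d", which(is.na(dates))[1]),
         call. = FALSE)
  out <- lapply(names(df)[-1], function(nm) {
    raw <- df[[nm]]
    raw[raw == "<1"] <- as.character(lt_value)
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & !(raw %in% c("", "NA")))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s' at data row %d",
                   raw[bad[1]], nm, bad[1]), call. = FALSE)
    if (!is.null(scale)) v <- v * scale
    o <- order(dates)
    grid <- seq(min(dates), max(dates), by = "day")
    full <- rep(NA_real_, length(grid))
    full[match(dates[o], grid)] <- v[o]
    query_series(geography, nm, grid, full)
  })
  names(out) <- vapply(out, function(s) series_key(s$geography, s$topic), "")
  out[order(names(out))]
}

#' Write query-fraction series to long-dialect CSV
#'
#' Writes ISO-8601 dates and full float precision so that
#' [read_series_csv()] round-trips the collection field-for-field. `NA`
#' (missing-day) values are written as empty cells.
#'
#' @param collection A non-empty list of [query_series].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_series_csv <- function(collection, path) {
  if (inherits(collection, "query_series")) collection <- list(collection)
  if (length(collection) == 0L)
    stop("refusing to write an empty collection", call. = FALSE)
  stopifnot(all(vapply(collection, inherits, TRUE, "query_series")))
  rows <- lapply(collection, function(s)
    data.frame(geography = s$geography, topic = s$topic,
               date = format(s$dates, "%Y-%m-%d"),
               qf = format(s$values, digits = 17, trim = TRUE,
                           scientific = FALSE),
               stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  df$qf[df$qf == "NA"] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read the per-geography covariate table
#'
#' Expects header `geography,vote_share_trump,winner`. The vote share is the
#' fraction (in `[0,1]`) of the two-party 2016 presidential vote cast for
#' Trump; `winner` must equal "Trump" exactly when the share exceeds 0.5
#' (two-party convention), which is validated unless `check = FALSE`.
#'
#' @param path CSV file path.
#' @param check Validate winner/vote-share consistency (default TRUE).
#' @return A data.frame with one row per geography.
#' @export
read_covariates <- function(path, check = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("geography", "vote_share_trump", "winner")
  if (!all(need %in% names(df)))
    stop("covariate table requires columns geography,vote_share_trump,winner",
         call. = FALSE)
  validate_covariates(df[need], check = check)
}

validate_covariates <- function(df, check = TRUE) {
  if (anyDuplicated(df$geography))
    stop("covariate table must have one row per geography", call. = FALSE)
  if (any(df$vote_share_trump < 0 | df$vote_share_trump > 1))
    stop("vote_share_trump must lie in [0, 1]", call. = FALSE)
  if (!all(df$winner %in% c("Trump", "Clinton")))
    stop("winner must be 'Trump' or 'Clinton'", call. = FALSE)
  if (check) {
    implied <- ifelse(df$vote_share_trump > 0.5, "Trump", "Clinton")
    bad <- which(implied != df$winner)
    if (length(bad))
      stop(sprintf("winner inconsistent with two-party vote share for %s",
                   df$geography[bad[1]]), call. = FALSE)
  }
  df
}
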