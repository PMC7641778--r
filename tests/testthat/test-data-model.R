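test_that("query_series validates its invariants", {
  d <- as.Date("2020-01-01") + 0:4
  expect_s3_class(query_series("US", "reform", d, 1:5), "query_series")
  expect_error(query_series("US", "reform", d[c(1, 3, 2, 4, 5)], 1:5),
               "strictly increasing")
  expect_error(query_series("US", "reform", d[c(1, 2, 2, 3, 4)], 1:5),
               "strictly increasing")
  expect_error(query_series("US", "reform", d[c(1, 2, 4, 5)], 1:4),
               "contiguous")
  expect_error(query_series("US", "reform", d, c(1, -2, 3, 4, 5)),
               "non-negative")
  expect_error(query_series("US", "reform", d, 1:4), "equal length")
})

test_that("long-dialect CSV parses, validates, and reports offending rows", {
  df <- data.frame(geography = "US", topic = "reform",
                   date = as.character(as.Date("2020-01-01") + 0:2),
                   qf = c(1, 2, 3))
  coll <- read_series_csv(write_long_fixture(df))
  expect_length(coll, 1L)
  expect_equal(coll[["US/reform"]]$values, c(1, 2, 3))

  bad_date <- df; bad_date$date[2] <- "2020-13-01"
  expect_error(read_series_csv(write_long_fixture(bad_date)),
               "malformed date.*row 2")
  bad_neg <- df; bad_neg$qf[3] <- -1
  expect_error(read_series_csv(write_long_fixture(bad_neg)),
               "negative qf.*row 3")
  dup <- rbind(df, df[2, ])
  expect_error(read_series_csv(write_long_fixture(dup)),
               "duplicate.*row 4")
})

test_that("a skipped day becomes an explicit NA gap, fillable up to max_gap", {
  df <- data.frame(geography = "US", topic = "reform",
                   date = c("2020-01-01", "2020-01-02", "2020-01-05"),
                   qf = c(1, 2, 8))
  s <- read_series_csv(write_long_fixture(df))[[1]]
  expect_length(s, 5L)
  expect_equal(which(is.na(s$values)), c(3L, 4L))
  filled <- fill_gaps(s, max_gap = 3)
  expect_equal(filled$values, c(1, 2, 4, 6, 8))
  expect_equal(attr(filled, "n_interpolated"), 2L)
  expect_error(fill_gaps(s, max_gap = 1), "exceeds max_gap")
})

test_that("trends widetable dialect skips the preamble and imputes '<1'", {
  path <- tempfile(fileext = ".csv")
  writeLines(c("Category: All categories", "",
               "Day,police reform,police training",
               "2020-01-01,5,<1",
               "2020-01-02,<1,7"), path)
  coll <- read_series_csv(path, dialect = "trends_widetable",
                          geography = "US", lt_value = 0.5)
  expect_named(coll, c("US/police reform", "US/police training"))
  expect_equal(coll[["US/police reform"]]$values, c(5, 0.5))
  expect_equal(coll[["US/police training"]]$values, c(0.5, 7))
  scaled <- read_series_csv(path, dialect = "trends_widetable", scale = 10)
  expect_equal(scaled[["US/police training"]]$values, c(5, 70))
})

test_that("write/read round-trip is the identity, empty collection refused", {
  set.seed(11)
  coll <- list()
  for (g in c("MN", "DC")) for (tp in c("reform", "union")) {
    s <- make_series(round(runif(10, 0, 50), 6), geography = g, topic = tp)
    coll[[paste(g, tp, sep = "/")]] <- s
  }
  path <- tempfile(fileext = ".csv")
  write_series_csv(coll, path)
  expect_equal(length(readLines(path)), 1L + 4L * 10L)  # header + data rows
  back <- read_series_csv(path)
  expect_equal(back[sort(names(coll))], coll[sort(names(coll))])
  expect_error(write_series_csv(list(), tempfile()), "empty collection")
})

test_that("analysis_window and slice_window enforce and partition the span", {
  expect_error(analysis_window("2020-05-25", "2020-05-25", "2020-07-05"),
               "precede")
  w <- analysis_window("2010-01-01", "2020-05-25", "2020-07-05")
  s <- make_series(rep(1, as.integer(as.Date("2020-07-05") -
                                       as.Date("2010-01-01")) + 1L),
                   start = "2010-01-01")
  sw <- slice_window(s, w)
  # the post period is the event day plus the 41 following days
  expect_length(sw$post, 42L)
  expect_identical(sw$post$dates[1], as.Date("2020-05-25"))
  expect_length(sw$baseline,
                as.integer(as.Date("2020-05-25") - as.Date("2010-01-01")))
  # partition: |baseline| + |post| = days in [baseline_start, post_end]
  expect_equal(length(sw$baseline) + length(sw$post),
               as.integer(w$post_end - w$baseline_start) + 1L)

  # boundary: post_end = event_date gives a single post day
  w1 <- analysis_window("2020-05-01", "2020-05-25", "2020-05-25")
  expect_length(slice_window(s, w1)$post, 1L)
  # event on the first covered day leaves no baseline: the window necessarily
  # starts before the series and is rejected
  s2 <- make_series(rep(1, 10), start = "2020-05-25")
  expect_error(
    slice_window(s2, analysis_window("2020-05-24", "2020-05-25", "2020-05-30")),
    "outside")
  expect_error(
    slice_window(s2, analysis_window("2020-05-25", "2020-05-26", "2020-07-30")),
    "outside")
})

test_that("slice partition property holds on random windows", {
  set.seed(3)
  for (rep in 1:20) {
    n <- sample(30:120, 1)
    s <- make_series(runif(n), start = "2019-03-01")
    ev <- sample(2:(n - 1), 1)
    pe <- sample(ev:n, 1)
    w <- analysis_window(s$dates[1], s$dates[ev], s$dates[pe])
    sw <- slice_window(s, w)
    expect_equal(length(sw$baseline) + length(sw$post),
                 as.integer(w$post_end - w$baseline_start) + 1L)
    expect_equal(c(sw$baseline$values, sw$post$values), s$values[1:pe])
  }
})

test_that("covariate table validation catches inconsistent winners", {
  cov <- make_covariates(c("MN", "TX"), c(0.45, 0.55))
  expect_silent(validate_ok <- read_covariates(write_long_fixture(cov)))
  cov$winner[1] <- "Trump"
  expect_error(read_covariates(write_long_fixture(cov)), "inconsistent")
  cov2 <- make_covariates(c("MN", "MN"), c(0.4, 0.4))
  expect_error(read_covariates(write_long_fixture(cov2)), "one row per")
})
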