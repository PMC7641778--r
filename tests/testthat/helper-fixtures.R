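# Shared fixture builders: everything is generated in code at test time.

make_series <- function(values, start = "2020-01-01", geography = "US",
                        topic = "reform") {
  query_series(geography, topic, as.Date(start) + seq_along(values) - 1L,
               values)
}

# A tiny long-dialect CSV on disk; returns the path.
write_long_fixture <- function(df, path = tempfile(fileext = ".csv")) {
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

# Small state x topic panel as a state_panel built from constant series.
make_panel <- function(qf_matrix, window = default_window(),
                       covariates = NULL) {
  n_days <- as.integer(window$post_end - window$event_date) + 1L
  coll <- list()
  for (g in rownames(qf_matrix)) for (tp in colnames(qf_matrix)) {
    daily <- qf_matrix[g, tp] / n_days
    s <- query_series(g, tp,
                      seq(window$baseline_start, window$post_end, by = "day"),
                      rep(daily, as.integer(window$post_end -
                                              window$baseline_start) + 1L))
    coll[[series_key_t(g, tp)]] <- s
  }
  state_panel(coll, window, covariates)
}

series_key_t <- function(g, tp) paste(g, tp, sep = "/")

default_window <- function() {
  analysis_window("2020-05-01", "2020-05-25", "2020-07-05")
}

# Independent one-way ANOVA ICC oracle: brute-force sums of squares from the
# textbook definitions, kept deliberately separate from the package formula.
icc_anova_oracle <- function(m) {
  long <- data.frame(y = as.vector(m),
                     g = factor(rep(rownames(m), times = ncol(m))))
  fit <- stats::aov(y ~ g, data = long)
  ms <- summary(fit)[[1]]$`Mean Sq`
  k <- ncol(m)
  (ms[1] - ms[2]) / (ms[1] + (k - 1) * ms[2])
}

# Covariate table for n geographies with given vote shares.
make_covariates <- function(geos, vote) {
  data.frame(geography = geos, vote_share_trump = vote,
             winner = ifelse(vote > 0.5, "Trump", "Clinton"),
             stringsAsFactors = FALSE)
}
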