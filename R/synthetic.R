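#' Configuration for the synthetic search-interest world
#'
#' The generator emulates the design of the study system: daily query-fraction
#' series per geography and topic from a long pre-event baseline, a large
#' multiplicative surge on the event day that decays exponentially to an
#' elevated plateau, and state-level topic preferences that vary linearly with
#' a political covariate (2016 two-party vote share).
#'
#' Defaults state the emulated world: 51 geographies (50 states + DC), four
#' reform topics, baseline 2010-01-01 to the event on 2020-05-25, post window
#' through 2020-07-05 (42 days), an AR(1) day-to-day baseline with mean 2
#' query fractions per 10 million, a peak surge of 37.7x decaying with a
#' 10-day half-life to a 5x plateau (cumulative excess on the order of
#' thousands of percent), and topic-share slopes of +0.45 (union) and -0.43
#' (training) per unit vote share. The default intercepts put the
#' training/union crossover at vote share ~0.54, so training leads in about
#' two thirds of geographies and union in the rest, with union favoured in
#' Trump-won states and training in Clinton-won states.
#'
#' @param n_geographies Number of geographies (default 51).
#' @param topics Topic labels (default the four reform topics).
#' @param order ARIMA orders `c(p, d, q)` of the baseline process.
#' @param ar,ma Baseline AR and MA coefficients (must be causal/invertible).
#' @param mean_level Baseline mean query fraction per 10 million per day for a
#'   single-series world (default 2).
#' @param innovation_sd Innovation standard deviation for a single-series
#'   baseline (default 0.5).
#' @param noise_cv In panels, per-topic innovation sd as a fraction of that
#'   topic's mean level (default 0.25), so small topics stay non-negative.
#' @param baseline_start,event_date,post_end Analysis dates (defaults
#'   2010-01-01, 2020-05-25, 2020-07-05).
#' @param effect_multiplier Peak multiplicative surge on the event day
#'   (default 37.7).
#' @param decay_halflife Half-life in days of the surge decay (default 10).
#' @param floor_multiplier Long-run post-event multiplier (default 5; the
#'   series stays above its expected level through the end of observation).
#' @param topic_intercepts,topic_slopes Expected topic share of a geography is
#'   `intercept + slope * vote_share`; intercepts must sum to 1 and slopes to
#'   0 so shares always sum to 1.
#' @param vote_range Range of the uniform draw for per-geography Trump vote
#'   share (default `c(0.25, 0.70)`).
#' @param state_level_sd SD of the log-normal per-geography level factor
#'   shared across topics (default 0.4); this is what makes search rates
#'   correlate by state across topics.
#' @param total_level Total mean daily query fraction across topics before the
#'   state level factor (default 8).
#' @param seed Integer seed; a fixed seed makes every output byte-identical.
#' @return A validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_geographies = 51L,
                             topics = c("union", "training", "immunity",
                                        "militarization"),
                             order = c(1L, 0L, 0L),
                             ar = 0.7, ma = numeric(0),
                             mean_level = 2, innovation_sd = 0.5,
                             noise_cv = 0.25,
                             baseline_start = "2010-01-01",
                             event_date = "2020-05-25",
                             post_end = "2020-07-05",
                             effect_multiplier = 37.7,
                             decay_halflife = 10,
                             floor_multiplier = 5,
                             topic_intercepts = c(union = 0.18,
                                                  training = 0.655,
                                                  immunity = 0.13,
                                                  militarization = 0.035),
                             topic_slopes = c(union = 0.45,
                                              training = -0.43,
                                              immunity = -0.01,
                                              militarization = -0.01),
                             vote_range = c(0.25, 0.70),
                             state_level_sd = 0.4,
                             total_level = 8,
                             seed = 1L) {
  cfg <- list(n_geographies = as.integer(n_geographies), topics = topics,
              order = as.integer(order), ar = ar, ma = ma,
              mean_level = mean_level, innovation_sd = innovation_sd,
              noise_cv = noise_cv,
              baseline_start = as.Date(baseline_start),
              event_date = as.Date(event_date),
              post_end = as.Date(post_end),
              effect_multiplier = effect_multiplier,
              decay_halflife = decay_halflife,
              floor_multiplier = floor_multiplier,
              topic_intercepts = topic_intercepts[topics],
              topic_slopes = topic_slopes[topics],
              vote_range = vote_range,
              state_level_sd = state_level_sd,
              total_level = total_level,
              seed = as.integer(seed))
  stopifnot(cfg$n_geographies >= 1L, length(cfg$order) == 3L,
            cfg$innovation_sd >= 0, cfg$noise_cv >= 0,
            cfg$effect_multiplier >= cfg$floor_multiplier,
            cfg$floor_multiplier >= 1, cfg$decay_halflife > 0,
            cfg$baseline_start < cfg$event_date,
            cfg$event_date <= cfg$post_end)
  if (abs(sum(cfg$topic_intercepts) - 1) > 1e-8)
    stop("topic intercepts must sum to 1", call. = FALSE)
  if (abs(sum(cfg$topic_slopes)) > 1e-8)
    stop("topic slopes must sum to 0", call. = FALSE)
  for (v in cfg$vote_range) {
    sh <- cfg$topic_intercepts + cfg$topic_slopes * v
    if (any(sh <= 0) || any(sh >= 1))
      stop("topic shares implied by intercepts/slopes leave (0,1) over vote_range",
           call. = FALSE)
  }
  check_arma_roots(cfg$ar, cfg$ma)
  structure(cfg, class = "synthetic_config")
}

check_arma_roots <- function(ar, ma) {
  if (length(ar) && any(abs(polyroot(c(1, -ar))) <= 1 + 1e-8))
    stop("AR coefficients are not causal (root on or inside the unit circle)",
         call. = FALSE)
  if (length(ma) && any(abs(polyroot(c(1, ma))) <= 1 + 1e-8))
    stop("MA coefficients are not invertible", call. = FALSE)
  invisible(TRUE)
}

#' Simulate a baseline query-fraction series
#'
#' Draws a Gaussian ARIMA sample path at the configured orders and
#' coefficients, adds the mean level, and clips at zero (query fractions are
#' non-negative). The fraction of clipped days is attached as attribute
#' `clip_rate`.
#'
#' @param config A [synthetic_config()].
#' @param start,end First and last date (default the config baseline span
#'   through `post_end`, so the event window is inside the series).
#' @param seed Integer seed (default `config$seed`).
#' @param geography,topic Labels for the returned series.
#' @param mean_level,innovation_sd Overrides of the config values.
#' @return A [query_series].
#' @export
generate_baseline <- function(config, start = config$baseline_start,
                              end = config$post_end, seed = config$seed,
                              geography = "US", topic = "reform",
                              mean_level = config$mean_level,
                              innovation_sd = config$innovation_sd) {
  stopifnot(inherits(config, "synthetic_config"))
  start <- as.Date(start); end <- as.Date(end)
  if (!(start < end)) stop("start must precede end", call. = FALSE)
  check_arma_roots(config$ar, config$ma)
  n <- as.integer(end - start) + 1L
  set.seed(seed)
  model <- list(order = config$order)
  if (config$order[1] > 0) model$ar <- config$ar
  if (config$order[3] > 0) model$ma <- config$ma
  x <- as.numeric(stats::arima.sim(model, n = n, sd = innovation_sd))
  # for d >= 1, arima.sim returns n + d values; drop the burn-in origin
  x <- x[(length(x) - n + 1L):length(x)]
  x <- x + mean_level
  clipped <- x < 0
  x[clipped] <- 0
  out <- query_series(geography, topic, seq(start, end, by = "day"), x)
  attr(out, "clip_rate") <- mean(clipped)
  out
}

#' Post-event surge multiplier
#'
#' `m(t) = floor + (peak - floor) * 2^(-t / halflife)` where `t` is days since
#' the event (the event day has `t = 0` and multiplier exactly `peak`).
#'
#' @param t Days since the event (numeric vector, >= 0).
#' @param peak,floor Peak and long-run multiplier, `peak >= floor >= 1`.
#' @param halflife Decay half-life in days.
#' @return Multiplier values, same length as `t`.
#' @export
event_multiplier <- function(t, peak, floor, halflife) {
  stopifnot(peak >= floor, floor >= 1, halflife > 0, all(t >= 0))
  floor + (peak - floor) * 2^(-t / halflife)
}

#' Mean surge multiplier over a post window (closed form)
#'
#' Average of [event_multiplier()] over `t = 0, ..., n_days - 1`, via the
#' geometric series: `floor + (peak - floor) * (1 - r^n) / (n (1 - r))` with
#' `r = 2^(-1 / halflife)`. On a flat baseline this equals the true cumulative
#' observed/expected ratio, so the injected excess is available exactly.
#'
#' @inheritParams event_multiplier
#' @param n_days Number of post-event days (the event day counts).
#' @return The mean multiplier (scalar).
#' @export
mean_event_multiplier <- function(n_days, peak, floor, halflife) {
  stopifnot(n_days >= 1)
  r <- 2^(-1 / halflife)
  floor + (peak - floor) * (1 - r^n_days) / (n_days * (1 - r))
}

#' Apply a decaying multiplicative event effect to a series
#'
#' Values on and after `event_date` are multiplied by [event_multiplier()];
#' earlier values are untouched.
#'
#' @param series A [query_series] containing `event_date`.
#' @param event_date Event day.
#' @param effect_multiplier Peak multiplier at `t = 0`.
#' @param decay_halflife Half-life of the decay, days.
#' @param floor_multiplier Long-run multiplier.
#' @return The modified [query_series].
#' @export
apply_event_effect <- function(series, event_date, effect_multiplier,
                               decay_halflife, floor_multiplier) {
  stopifnot(inherits(series, "query_series"))
  event_date <- as.Date(event_date)
  if (event_date < min(series$dates) || event_date > max(series$dates))
    stop("event_date outside the series' date span", call. = FALSE)
  post <- series$dates >= event_date
  t <- as.numeric(series$dates[post] - event_date)
  series$values[post] <- series$values[post] *
    event_multiplier(t, effect_multiplier, floor_multiplier, decay_halflife)
  series
}

#' Generate a full state x topic panel with known ground truth
#'
#' Per geography: a Trump vote share is drawn uniformly over
#' `config$vote_range`; expected topic shares follow
#' `intercept + slope * vote_share`; a log-normal level factor shared across
#' the geography's topics induces between-state correlation. Each topic
#' series is an AR baseline around `total_level * share * level_factor`
#' (innovation sd = `noise_cv` times that mean), with the event surge applied.
#'
#' @param config A [synthetic_config()].
#' @param baseline_start Optionally shorten the baseline (e.g. for fast
#'   simulation studies); defaults to `config$baseline_start`.
#' @return A list with `series` (named list of [query_series]), `covariates`
#'   (data.frame `geography, vote_share_trump, winner`), and `truth` (every
#'   injected parameter: vote shares, expected share matrix, level factors,
#'   surge parameters, true mean post-window multiplier, clip rate).
#' @export
generate_panel <- function(config, baseline_start = config$baseline_start) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)
  geos <- panel_geography_codes(config$n_geographies)
  k <- length(config$topics)
  vote <- stats::runif(config$n_geographies, config$vote_range[1],
                       config$vote_range[2])
  level_factor <- exp(stats::rnorm(config$n_geographies, 0,
                                   config$state_level_sd))
  shares <- outer(vote, config$topic_slopes, `*`) +
    matrix(config$topic_intercepts, config$n_geographies, k, byrow = TRUE)
  dimnames(shares) <- list(geos, config$topics)
  if (any(shares <= 0) || any(shares >= 1))
    stop("infeasible share system: expected shares leave (0,1)", call. = FALSE)

  n_days <- as.integer(config$post_end - as.Date(baseline_start)) + 1L
  dates <- seq(as.Date(baseline_start), config$post_end, by = "day")
  post <- dates >= config$event_date
  tpost <- as.numeric(dates[post] - config$event_date)
  mult <- event_multiplier(tpost, config$effect_multiplier,
                           config$floor_multiplier, config$decay_halflife)
  model <- list(order = config$order)
  if (config$order[1] > 0) model$ar <- config$ar
  if (config$order[3] > 0) model$ma <- config$ma

  series <- vector("list", config$n_geographies * k)
  nm <- character(length(series))
  n_clipped <- 0L
  idx <- 0L
  for (g in seq_len(config$n_geographies)) {
    for (j in seq_len(k)) {
      idx <- idx + 1L
      lambda <- config$total_level * shares[g, j] * level_factor[g]
      x <- as.numeric(stats::arima.sim(model, n = n_days,
                                       sd = config$noise_cv * lambda))
      x <- x[(length(x) - n_days + 1L):length(x)] + lambda
      n_clipped <- n_clipped + sum(x < 0)
      x[x < 0] <- 0
      x[post] <- x[post] * mult
      s <- query_series(geos[g], config$topics[j], dates, x)
      series[[idx]] <- s
      nm[idx] <- series_key(geos[g], config$topics[j])
    }
  }
  names(series) <- nm
  covariates <- data.frame(
    geography = geos,
    vote_share_trump = vote,
    winner = ifelse(vote > 0.5, "Trump", "Clinton"),
    stringsAsFactors = FALSE)
  truth <- list(
    vote_share = stats::setNames(vote, geos),
    expected_shares = shares,
    level_factor = stats::setNames(level_factor, geos),
    effect_multiplier = config$effect_multiplier,
    decay_halflife = config$decay_halflife,
    floor_multiplier = config$floor_multiplier,
    true_mean_multiplier = mean_event_multiplier(
      sum(post), config$effect_multiplier, config$floor_multiplier,
      config$decay_halflife),
    clip_rate = n_clipped / (length(series) * n_days),
    config = unclass(config))
  list(series = series, covariates = covariates, truth = truth)
}

# Synthetic geography codes: real postal codes when 51 or fewer are needed,
# then generated codes G52, G53, ...
panel_geography_codes <- function(n) {
  codes <- c("AL", "AK", "AZ", "AR", "CA", "CO", "CT", "DE", "DC", "FL", "GA",
             "HI", "ID", "IL", "IN", "IA", "KS", "KY", "LA", "ME", "MD", "MA",
             "MI", "MN", "MS", "MO", "MT", "NE", "NV", "NH", "NJ", "NM", "NY",
             "NC", "ND", "OH", "OK", "OR", "PA", "RI", "SC", "SD", "TN", "TX",
             "UT", "VT", "VA", "WA", "WV", "WI", "WY")
  if (n <= length(codes)) codes[seq_len(n)]
  else c(codes, sprintf("G%02d", seq(length(codes) + 1L, n)))
}
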