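#' Observed/expected excess ratios
#'
#' Point estimates of excess search interest over a post-event window: the
#' per-day ratio `o_t / e_t`, the cumulative ratio `sum(o_t) / sum(e_t)`
#' (a ratio of sums, which is robust to near-zero expected days), and the
#' cumulative percent above expected, `(ratio - 1) * 100`.
#'
#' @param observed A [query_series] covering the post window, or a numeric
#'   vector.
#' @param expected A `forecast_result` from [forecast_counterfactual()] (its
#'   mean is the expected path), or a numeric vector. When both sides carry
#'   dates they must match exactly.
#' @param floor_eps Expected values are floored at this positive value before
#'   ratio formation (default `1e-6 * mean(expected)`); flooring events are
#'   counted in `n_floored`.
#' @return An object of class `excess_result` with the point estimates (no
#'   confidence intervals; see [bootstrap_excess_ci()]).
#' @export
excess_ratios <- function(observed, expected, floor_eps = NULL) {
  obs_dates <- exp_dates <- NULL
  if (inherits(observed, "query_series")) {
    obs_dates <- observed$dates; observed <- observed$values
  }
  if (inherits(expected, "forecast_result")) {
    exp_dates <- expected$dates; expected <- expected$mean
  }
  observed <- as.numeric(observed); expected <- as.numeric(expected)
  if (length(observed) != length(expected))
    stop("observed and expected must cover the same days", call. = FALSE)
  if (!is.null(obs_dates) && !is.null(exp_dates) &&
      !identical(as.Date(obs_dates), as.Date(exp_dates)))
    stop("observed and expected dates do not match", call. = FALSE)
  if (anyNA(observed) || anyNA(expected))
    stop("missing values in the post window", call. = FALSE)
  if (is.null(floor_eps)) floor_eps <- 1e-6 * mean(abs(expected))
  n_floored <- sum(expected < floor_eps)
  expected <- pmax(expected, floor_eps)
  if (any(expected <= 0))
    stop("expected values must be positive after flooring", call. = FALSE)
  ratio <- sum(observed) / sum(expected)
  structure(list(dates = obs_dates,
                 observed = observed, expected = expected,
                 daily_ratio = observed / expected,
                 cumulative_ratio = ratio,
                 cumulative_percent = (ratio - 1) * 100,
                 n_floored = n_floored),
            class = "excess_result")
}

#' @export
print.excess_result <- function(x, ...) {
  cat(sprintf("<excess_result> %d days, cumulative ratio %.3f (%+.1f%% vs expected)\n",
              length(x$daily_ratio), x$cumulative_ratio, x$cumulative_percent))
  if (!is.null(x$cumulative_ci))
    cat(sprintf("  %.0f%% bootstrap CI on percent excess: (%.1f, %.1f), B = %d%s\n",
                100 * x$level, x$cumulative_ci[1], x$cumulative_ci[2], x$B,
                if (isTRUE(x$significant)) ", significant" else ""))
  invisible(x)
}

#' Bootstrap confidence intervals for excess ratios
#'
#' Resamples the fitted baseline model's (centred) residuals with replacement
#' and pushes them through the model recursion to simulate `B` replicate
#' counterfactual paths over the post horizon. Each replicate statistic
#' compares the actual observed series with a replicate expected path;
#' percentile intervals (type-1 quantiles, i.e. order statistics) are formed
#' per day on the ratio scale and cumulatively on the percent-excess scale.
#' Fully deterministic under a fixed seed.
#'
#' @param spec A fitted `arima_spec` for the baseline period.
#' @param observed A [query_series] (or numeric vector) for the post window.
#' @param B Number of bootstrap replicates (default 10000; at least 100).
#' @param level Interval coverage (default 0.95).
#' @param seed Integer seed (required: reported intervals must be
#'   reproducible).
#' @param floor_eps Replicate expected paths are floored at this value
#'   (default `1e-6 *` baseline mean) before ratio formation.
#' @return An `excess_result` augmented with `daily_ci` (2 x h matrix),
#'   `cumulative_ci` (on the percent scale), `significant` (lower CI bound
#'   above 0% excess), `B`, `level`, `seed`, and flooring counts.
#' @export
bootstrap_excess_ci <- function(spec, observed, B = 10000L, level = 0.95,
                                seed, floor_eps = NULL) {
  stopifnot(inherits(spec, "arima_spec"))
  if (missing(seed) || is.null(seed))
    stop("a seed is required for reproducible bootstrap intervals",
         call. = FALSE)
  B <- as.integer(B)
  if (B < 100L) stop("B must be at least 100", call. = FALSE)
  if (level <= 0 || level >= 1) stop("invalid level", call. = FALSE)

  obs_series <- observed
  h <- if (inherits(observed, "query_series")) length(observed$dates)
       else length(observed)
  fc <- forecast_counterfactual(spec, horizon = h, level = level)
  point <- excess_ratios(obs_series, fc, floor_eps = floor_eps)
  o <- point$observed

  res <- spec$residuals
  res <- res[!is.na(res)]
  # drop initialization residuals (Kalman burn-in), then centre
  burn <- min(spec$p + spec$d + spec$q, length(res) - 10L)
  if (burn > 0L) res <- res[-seq_len(burn)]
  res <- res - mean(res)
  # relative tolerance: Kalman-filter residuals of an exactly deterministic
  # series carry O(1e-12) numerical noise
  if (max(res) - min(res) <= 1e-9 * (1 + max(abs(spec$y)))) {
    warning("degenerate residuals: bootstrap intervals have zero width")
    res <- rep(0, length(res))
  }
  if (is.null(floor_eps)) floor_eps <- 1e-6 * mean(abs(spec$y))

  set.seed(seed)
  innov <- matrix(sample(res, h * B, replace = TRUE), h, B)
  paths <- simulate_arima_paths(spec, innov)
  n_floored_boot <- sum(paths < floor_eps)
  paths[paths < floor_eps] <- floor_eps

  alpha <- (1 - level) / 2
  rep_daily <- o / paths                             # h x B replicate ratios
  daily_ci <- apply(rep_daily, 1, stats::quantile,
                    probs = c(alpha, 1 - alpha), type = 1, names = FALSE)
  rep_cum_pct <- (sum(o) / colSums(paths) - 1) * 100
  cumulative_ci <- stats::quantile(rep_cum_pct, probs = c(alpha, 1 - alpha),
                                   type = 1, names = FALSE)

  point$daily_ci <- daily_ci
  point$cumulative_ci <- cumulative_ci
  point$significant <- cumulative_ci[1] > 0
  point$B <- B
  point$level <- level
  point$seed <- seed
  point$n_floored_bootstrap <- n_floored_boot
  point
}

#' Significance flags from excess results
#'
#' An excess is flagged significant when the lower bound of the cumulative
#' bootstrap interval exceeds 0% above expected.
#'
#' @param x An `excess_result` with intervals, or a list of them.
#' @return Named logical vector.
#' @export
significance_flags <- function(x) {
  if (inherits(x, "excess_result")) x <- list(x)
  vapply(x, function(r) {
    if (is.null(r$cumulative_ci))
      stop("confidence intervals not computed; run bootstrap_excess_ci first",
           call. = FALSE)
    r$cumulative_ci[1] > 0
  }, logical(1))
}

#' Convert query fractions to absolute search counts
#'
#' A query fraction is searches per 10 million total searches, so the daily
#' count is `qf / 1e7 * total_volume`. Requires a user-supplied total daily
#' search-volume series covering the post window; no such series ships with
#' the package.
#'
#' @param excess An `excess_result`.
#' @param total_volume Numeric vector of total searches per day, aligned with
#'   the post window (same length as the excess result's days).
#' @param digits Rounding applied to the returned totals (default 0; use
#'   `NULL` for none).
#' @return A list with `observed_counts`, `expected_counts`,
#'   `excess_counts` (totals over the window) and the per-day count vectors.
#' @export
absolute_volume <- function(excess, total_volume, digits = 0) {
  stopifnot(inherits(excess, "excess_result"))
  total_volume <- as.numeric(total_volume)
  if (length(total_volume) != length(excess$observed) || anyNA(total_volume))
    stop("total_volume must cover every day of the post window", call. = FALSE)
  daily_obs <- excess$observed / 1e7 * total_volume
  daily_exp <- excess$expected / 1e7 * total_volume
  rnd <- function(v) if (is.null(digits)) v else round(v, digits)
  list(observed_counts = rnd(sum(daily_obs)),
       expected_counts = rnd(sum(daily_exp)),
       excess_counts = rnd(sum(daily_obs - daily_exp)),
       daily_observed = daily_obs, daily_expected = daily_exp)
}
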