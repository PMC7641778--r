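#' KPSS level-stationarity statistic
#'
#' The KPSS statistic for the null of level stationarity: with demeaned values
#' `e_t` and partial sums `S_t`, the statistic is
#' `sum(S_t^2) / (n^2 * s2(l))` where `s2(l)` is the Bartlett-window long-run
#' variance estimate at lag truncation `l`. Large values reject stationarity.
#'
#' A zero-variance (constant) series is stationary by construction and
#' returns 0.
#'
#' @param x Numeric vector.
#' @param lags Lag truncation for the long-run variance. The default is the
#'   long Bartlett rule `trunc(12 * (n/100)^(1/4))`, which keeps the test
#'   close to its nominal size under strong short-range autocorrelation (the
#'   short rule badly over-rejects for, e.g., AR(1) with coefficient 0.8,
#'   which would inflate the chosen differencing order).
#' @return The statistic (scalar).
#' @export
kpss_statistic <- function(x, lags = trunc(12 * (length(x) / 100)^0.25)) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) stop("series too short for the KPSS statistic", call. = FALSE)
  e <- x - mean(x)
  s2 <- sum(e^2) / n
  if (s2 == 0) return(0)
  if (lags > 0) {
    for (k in seq_len(lags)) {
      s2 <- s2 + 2 * (1 - k / (lags + 1)) *
        sum(e[(k + 1):n] * e[1:(n - k)]) / n
    }
  }
  sum(cumsum(e)^2) / (n^2 * s2)
}

# Level-stationarity critical values (Kwiatkowski et al. table), interpolated
# on the significance level as standard implementations do.
kpss_critical <- function(alpha) {
  p <- c(0.10, 0.05, 0.025, 0.01)
  cv <- c(0.347, 0.463, 0.574, 0.739)
  if (alpha < min(p) || alpha > max(p))
    stop("alpha must be in [0.01, 0.10] for the KPSS critical-value table",
         call. = FALSE)
  stats::approx(p, cv, xout = alpha)$y
}

#' Choose the differencing order by successive KPSS tests
#'
#' Returns the smallest `d <= max_d` at which the KPSS statistic of the
#' d-times differenced series no longer rejects level stationarity at
#' `alpha`. If the test still rejects at `max_d`, `max_d` is returned.
#'
#' @param x Numeric vector or [query_series].
#' @param alpha Significance level (default 0.05).
#' @param max_d Maximum differencing order (default 2).
#' @return Integer differencing order.
#' @export
choose_differencing <- function(x, alpha = 0.05, max_d = 2L) {
  if (inherits(x, "query_series")) x <- x$values
  x <- as.numeric(x)
  if (anyNA(x)) stop("series contains missing values; fill gaps first",
                     call. = FALSE)
  cv <- kpss_critical(alpha)
  for (d in 0:max_d) {
    y <- if (d == 0) x else diff(x, differences = d)
    if (length(y) < 20L)
      stop("series too short after differencing", call. = FALSE)
    if (kpss_statistic(y) <= cv) return(d)
  }
  max_d
}

#' Fit a Gaussian ARIMA model
#'
#' Maximum-likelihood fit (via [stats::arima()]) of an ARIMA(p,d,q) to a
#' baseline series, with the conventional constant handling of automatic
#' order selection: for `d = 0` the constant is the process mean, for `d = 1`
#' it is a drift (linear trend) term, and for `d >= 2` no constant is fit.
#' AICc adds the small-sample correction `2k(k+1)/(n-k-1)` to the AIC, with
#' `k` counting the coefficients plus the innovation variance.
#'
#' @param x Numeric vector or [query_series] (the baseline period).
#' @param order Integer vector `c(p, d, q)`.
#' @param include_constant Fit a mean (d=0) or drift (d=1) term
#'   (default TRUE; ignored for d >= 2).
#' @return An object of class `arima_spec` carrying the orders, coefficients
#'   (`ar`, `ma`, `intercept` = mean or drift), `sigma2`, `aicc`, `n_obs`,
#'   the residuals, and the training data needed for forecasting.
#' @export
fit_arima <- function(x, order, include_constant = TRUE) {
  dates <- NULL
  if (inherits(x, "query_series")) { dates <- x$dates; x <- x$values }
  x <- as.numeric(x)
  if (anyNA(x)) stop("series contains missing values; fill gaps first",
                     call. = FALSE)
  order <- as.integer(order)
  stopifnot(length(order) == 3L, all(order >= 0L))
  p <- order[1]; d <- order[2]; q <- order[3]
  n_diff <- length(x) - d
  if (n_diff <= p + q + 2L)
    stop("series too short for the requested orders", call. = FALSE)
  w <- if (d > 0) diff(x, differences = d) else x
  if (stats::var(w) == 0 && p + q > 0)
    stop("degenerate (zero-variance) series", call. = FALSE)
  constant <- include_constant && d <= 1L
  xreg <- NULL
  if (constant && d == 1L)
    xreg <- matrix(seq_along(x), dimnames = list(NULL, "drift"))
  # do.call inlines evaluated arguments into the stored call, which keeps
  # stats::predict.Arima self-contained (it re-evaluates call$xreg)
  fit_args <- list(x, order = c(p, d, q),
                   include.mean = constant && d == 0L, method = "CSS-ML")
  if (!is.null(xreg)) fit_args$xreg <- xreg
  fit <- do.call(stats::arima, fit_args)
  cf <- stats::coef(fit)
  ar <- unname(cf[grep("^ar", names(cf))])
  ma <- unname(cf[grep("^ma", names(cf))])
  intercept <- if (constant && d == 0L) unname(cf["intercept"])
               else if (constant && d == 1L) unname(cf["drift"])
               else 0
  k <- length(cf) + 1L
  aicc <- fit$aic + 2 * k * (k + 1) / (n_diff - k - 1)
  structure(list(p = p, d = d, q = q, drift = constant && d == 1L,
                 include_constant = constant,
                 ar = ar, ma = ma, intercept = intercept,
                 sigma2 = fit$sigma2, aic = fit$aic, aicc = aicc,
                 loglik = fit$loglik, n_obs = n_diff,
                 residuals = as.numeric(stats::residuals(fit)),
                 y = x, dates = dates, fit = fit),
            class = "arima_spec")
}

#' @export
print.arima_spec <- function(x, ...) {
  const <- if (!x$include_constant) "no constant"
           else if (x$d == 0) sprintf("mean %.4g", x$intercept)
           else sprintf("drift %.4g", x$intercept)
  cat(sprintf("<arima_spec> ARIMA(%d,%d,%d), %s; sigma2 = %.4g, AICc = %.2f, n = %d\n",
              x$p, x$d, x$q, const, x$sigma2, x$aicc, x$n_obs))
  invisible(x)
}

# Candidate admissibility during order search. Two rejection rules, applied
# identically to stepwise and exhaustive searches:
#  * a root of the AR or MA polynomial inside/on a 1.001 circle (effectively
#    non-causal / non-invertible; the standard selection scheme discards
#    these), and
#  * an AR root within `cancel_tol` of an MA root: a near-common factor makes
#    the model practically unidentified, with an ill-conditioned likelihood
#    whose spurious AICc gain does not survive refitting.
admissible_roots <- function(spec, margin = 1.001, cancel_tol = 0.1) {
  ar_roots <- if (spec$p > 0) polyroot(c(1, -spec$ar)) else complex(0)
  ma_roots <- if (spec$q > 0) polyroot(c(1, spec$ma)) else complex(0)
  if (length(ar_roots) && any(Mod(ar_roots) < margin)) return(FALSE)
  if (length(ma_roots) && any(Mod(ma_roots) < margin)) return(FALSE)
  if (length(ar_roots) && length(ma_roots)) {
    dist <- outer(ar_roots, ma_roots, function(a, b) Mod(a - b))
    if (min(dist) < cancel_tol) return(FALSE)
  }
  TRUE
}

safe_aicc_fit <- function(x, order, include_constant) {
  tryCatch(fit_arima(x, order, include_constant),
           error = function(e) NULL, warning = function(w) {
             # non-convergence warnings from stats::arima: keep the fit but
             # refit quietly; treat hard failures as Inf via the error branch
             suppressWarnings(tryCatch(fit_arima(x, order, include_constant),
                                       error = function(e) NULL))
           })
}

#' Automatic ARIMA order selection (stepwise AICc search)
#'
#' Implements the standard automatic selection scheme: the differencing order
#' comes from successive KPSS tests ([choose_differencing()]); the ARMA
#' orders and the constant are then chosen by a stepwise search that starts
#' from the four usual models ((2,d,2), (0,d,0), (1,d,0), (0,d,1)), moves to
#' the best AICc-improving neighbour (p and/or q shifted by one, or the
#' constant toggled), and stops when no neighbour improves. Ties in AICc are
#' broken toward smaller `p + q`, then smaller `q`, for reproducibility.
#'
#' @param x Numeric vector or [query_series].
#' @param max_p,max_q Order caps (default 5).
#' @param alpha KPSS significance level for differencing (default 0.05).
#' @param d Differencing order override (default `NULL`: use KPSS).
#' @param stepwise If `FALSE`, search all `(p, q)` pairs exhaustively instead
#'   (slower; mainly for validation).
#' @return The AICc-minimal visited model as an `arima_spec`.
#' @export
select_order <- function(x, max_p = 5L, max_q = 5L, alpha = 0.05, d = NULL,
                         stepwise = TRUE) {
  series <- x
  if (inherits(x, "query_series")) x <- x$values
  x <- as.numeric(x)
  if (is.null(d)) d <- choose_differencing(x, alpha = alpha)
  constants <- if (d <= 1L) c(TRUE, FALSE) else FALSE

  cache <- new.env(parent = emptyenv())
  eval_model <- function(p, q, const) {
    if (p > max_p || q > max_q || p < 0 || q < 0) return(NULL)
    key <- paste(p, q, const, sep = ".")
    if (!is.null(cache[[key]])) return(cache[[key]])
    fit <- safe_aicc_fit(x, c(p, d, q), const)
    ok <- !is.null(fit) && is.finite(fit$aicc) && admissible_roots(fit)
    val <- list(fit = fit, p = p, q = q, const = const,
                aicc = if (ok) fit$aicc else Inf)
    cache[[key]] <- val
    val
  }
  better <- function(a, b) {
    # is candidate a better than incumbent b?
    if (is.null(a)) return(FALSE)
    if (is.null(b)) return(is.finite(a$aicc))
    if (abs(a$aicc - b$aicc) > 1e-8) return(a$aicc < b$aicc)
    if (a$p + a$q != b$p + b$q) return(a$p + a$q < b$p + b$q)
    a$q < b$q
  }

  best <- NULL
  if (!stepwise) {
    for (p in 0:max_p) for (q in 0:max_q) for (const in constants) {
      cand <- eval_model(p, q, const)
      if (better(cand, best)) best <- cand
    }
  } else {
    start_const <- d <= 1L
    # the four classic starting models plus the (max_p, max_q) corner; the
    # extra start costs one fit and guards against distant AICc optima that
    # plain hill-climbing from small models cannot reach
    for (pq in list(c(2, 2), c(0, 0), c(1, 0), c(0, 1),
                    c(max_p, max_q))) {
      cand <- eval_model(min(pq[1], max_p), min(pq[2], max_q), start_const)
      if (better(cand, best)) best <- cand
    }
    if (is.null(best) || !is.finite(best$aicc))
      stop("all starting ARIMA fits failed", call. = FALSE)
    repeat {
      improved <- FALSE
      for (dp in -1:1) for (dq in -1:1) {
        if (dp == 0 && dq == 0) next
        cand <- eval_model(best$p + dp, best$q + dq, best$const)
        if (better(cand, best)) { best <- cand; improved <- TRUE }
      }
      if (length(constants) > 1L) {
        cand <- eval_model(best$p, best$q, !best$const)
        if (better(cand, best)) { best <- cand; improved <- TRUE }
      }
      if (!improved) break
    }
  }
  if (is.null(best) || !is.finite(best$aicc))
    stop("all candidate ARIMA fits failed", call. = FALSE)
  spec <- best$fit
  if (inherits(series, "query_series")) spec$dates <- series$dates
  spec
}

#' Counterfactual forecast from a fitted baseline model
#'
#' Point forecasts are the conditional expectation recursion of the fitted
#' ARIMA; prediction intervals are `mean +/- z * s_h` with `s_h` the
#' psi-weight accumulation of forecast-error variance (both via
#' [stats::predict()] on the underlying fit).
#'
#' @param spec An `arima_spec` from [fit_arima()] or [select_order()].
#' @param horizon Number of days ahead (>= 1).
#' @param level Prediction-interval coverage in (0, 1) (default 0.95).
#' @return An object of class `forecast_result` with `dates` (if the spec was
#'   fit on a dated series), `mean`, `se`, `lower`, `upper`, `level`.
#' @export
forecast_counterfactual <- function(spec, horizon, level = 0.95) {
  stopifnot(inherits(spec, "arima_spec"))
  horizon <- as.integer(horizon)
  if (horizon < 1L) stop("horizon must be >= 1", call. = FALSE)
  if (!is.numeric(level) || length(level) != 1L || level <= 0 || level >= 1)
    stop("level must be a single number in (0, 1)", call. = FALSE)
  newxreg <- NULL
  if (spec$drift) {
    n <- length(spec$y)
    newxreg <- matrix(n + seq_len(horizon), dimnames = list(NULL, "drift"))
  }
  pr <- stats::predict(spec$fit, n.ahead = horizon, newxreg = newxreg)
  z <- stats::qnorm(1 - (1 - level) / 2)
  m <- as.numeric(pr$pred); se <- as.numeric(pr$se)
  dates <- if (!is.null(spec$dates))
    max(spec$dates) + seq_len(horizon) else NULL
  structure(list(dates = dates, mean = m, se = se,
                 lower = m - z * se, upper = m + z * se, level = level),
            class = "forecast_result")
}

#' @export
print.forecast_result <- function(x, ...) {
  cat(sprintf("<forecast_result> horizon %d, level %.0f%%, mean in [%.4g, %.4g]\n",
              length(x$mean), 100 * x$level, min(x$mean), max(x$mean)))
  invisible(x)
}

# Simulate B post-horizon paths from a fitted spec by the model recursion,
# feeding the supplied (h x B) innovation matrix; history (observed
# differenced values and fitted residuals) seeds the lags. Returns an h x B
# matrix of paths on the original scale.
simulate_arima_paths <- function(spec, innovations) {
  h <- nrow(innovations); B <- ncol(innovations)
  p <- spec$p; q <- spec$q; d <- spec$d
  y <- spec$y
  w <- if (d == 0) y else diff(y, differences = d)
  m <- if (spec$include_constant && d == 0L) spec$intercept
       else if (spec$drift) spec$intercept
       else 0
  zhist <- w - m
  ehist <- spec$residuals
  Z <- matrix(0, h, B)
  E <- innovations
  for (t in seq_len(h)) {
    acc <- E[t, ]
    if (p > 0) for (i in seq_len(p)) {
      lag <- t - i
      acc <- acc + spec$ar[i] *
        (if (lag >= 1) Z[lag, ] else rep(zhist[length(zhist) + lag], B))
    }
    if (q > 0) for (j in seq_len(q)) {
      lag <- t - j
      acc <- acc + spec$ma[j] *
        (if (lag >= 1) E[lag, ] else rep(ehist[length(ehist) + lag], B))
    }
    Z[t, ] <- acc
  }
  W <- Z + m
  if (d == 0) return(W)
  if (d == 1) {
    Y <- apply(W, 2, cumsum)
    if (h == 1) Y <- matrix(Y, 1, B)
    return(Y + y[length(y)])
  }
  if (d == 2) {
    last_diff <- y[length(y)] - y[length(y) - 1]
    D <- apply(W, 2, cumsum)
    if (h == 1) D <- matrix(D, 1, B)
    D <- D + last_diff
    Y <- apply(D, 2, cumsum)
    if (h == 1) Y <- matrix(Y, 1, B)
    return(Y + y[length(y)])
  }
  stop("differencing orders above 2 are not supported", call. = FALSE)
}
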