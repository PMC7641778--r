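#' Regress a topic's share on Trump vote share
#'
#' Ordinary least squares of the topic share (fraction of a geography's
#' combined search volume across all tracked topics) on the geography's 2016
#' two-party Trump vote share. The slope is in share fraction per unit vote
#' share; `per10_effect = 10 * slope` restates it as the percentage-point
#' change in share per 10-percentage-point increase in vote share, the
#' field's usual reporting convention. The confidence interval uses the
#' t-distribution with `n - 2` degrees of freedom.
#'
#' @param shares A [topic_shares()] result (covariates attached), or a share
#'   matrix with geography rownames if `covariates` is supplied.
#' @param topic Topic to model.
#' @param covariates Covariate data.frame (`geography, vote_share_trump,
#'   winner`); defaults to the one attached to `shares`.
#' @param level CI coverage (default 0.95).
#' @param weights Optional per-geography weights (e.g. total QF); default
#'   unweighted.
#' @return An object of class `vote_share_model` with `topic`, `slope`,
#'   `intercept`, `slope_ci`, `per10_effect`, `per10_ci`, `r2`, `n`, `level`.
#' @export
fit_vote_share_model <- function(shares, topic, covariates = NULL,
                                 level = 0.95, weights = NULL) {
  sm <- if (inherits(shares, "topic_shares")) shares$shares else shares
  if (is.null(covariates) && inherits(shares, "topic_shares"))
    covariates <- shares$covariates
  if (is.null(covariates))
    stop("covariates required (none attached to shares)", call. = FALSE)
  stopifnot(topic %in% colnames(sm))
  ix <- match(rownames(sm), covariates$geography)
  if (anyNA(ix))
    stop("covariate table missing geographies present in shares", call. = FALSE)
  v <- covariates$vote_share_trump[ix]
  y <- sm[, topic]
  n <- length(y)
  if (n < 3L) stop("need at least 3 geographies", call. = FALSE)
  if (stats::var(v) == 0)
    stop("zero variance in vote share", call. = FALSE)
  fit <- if (is.null(weights)) stats::lm(y ~ v)
         else stats::lm(y ~ v, weights = weights)
  slope <- unname(stats::coef(fit)[2])
  se <- summary(fit)$coefficients[2, 2]
  tq <- stats::qt(1 - (1 - level) / 2, df = n - 2)
  ci <- slope + c(-1, 1) * tq * se
  structure(list(topic = topic, slope = slope,
                 intercept = unname(stats::coef(fit)[1]),
                 slope_se = se, slope_ci = ci,
                 per10_effect = 10 * slope, per10_ci = 10 * ci,
                 r2 = summary(fit)$r.squared, n = n, level = level),
            class = "vote_share_model")
}

#' @export
print.vote_share_model <- function(x, ...) {
  cat(sprintf(
    "<vote_share_model> %s: +10pp vote share -> %+.2f pp share (%.0f%% CI %.2f to %.2f), R2 = %.2f, n = %d\n",
    x$topic, x$per10_effect, 100 * x$level, x$per10_ci[1], x$per10_ci[2],
    x$r2, x$n))
  invisible(x)
}

#' Fit the vote-share regression for every topic
#'
#' @inheritParams fit_vote_share_model
#' @return A data.frame with one row per topic: slope, CI bounds,
#'   per-10-point effect, and R-squared.
#' @export
fit_all_vote_share_models <- function(shares, covariates = NULL,
                                      level = 0.95, weights = NULL) {
  sm <- if (inherits(shares, "topic_shares")) shares$shares else shares
  models <- lapply(colnames(sm), function(tp)
    fit_vote_share_model(shares, tp, covariates, level, weights))
  data.frame(topic = vapply(models, `[[`, "", "topic"),
             slope = vapply(models, `[[`, 0, "slope"),
             slope_lo = vapply(models, function(m) m$slope_ci[1], 0),
             slope_hi = vapply(models, function(m) m$slope_ci[2], 0),
             per10_effect = vapply(models, `[[`, 0, "per10_effect"),
             r2 = vapply(models, `[[`, 0, "r2"),
             stringsAsFactors = FALSE)
}

#' Leading-topic breakdown by election winner
#'
#' Within each winner group (states carried by Trump vs by Clinton), the
#' percentage of geographies whose leading search topic is each tracked
#' topic. Geographies with an exact tie for the lead are excluded from the
#' percentages and counted separately.
#'
#' @param shares A [topic_shares()] result.
#' @param covariates Covariate data.frame; defaults to the attached one.
#' @return A list with `percent` (winner x topic matrix of percentages),
#'   `n` (geographies per winner group, ties excluded), and `n_ties`.
#' @export
winner_breakdown <- function(shares, covariates = NULL) {
  stopifnot(inherits(shares, "topic_shares"))
  if (is.null(covariates)) covariates <- shares$covariates
  if (is.null(covariates)) stop("covariates required", call. = FALSE)
  geos <- rownames(shares$shares)
  ix <- match(geos, covariates$geography)
  if (anyNA(ix)) stop("covariate table missing geographies", call. = FALSE)
  winner <- covariates$winner[ix]
  topics <- colnames(shares$shares)
  groups <- c("Trump", "Clinton")
  if (!all(groups %in% winner))
    stop(sprintf("empty winner group: %s",
                 paste(setdiff(groups, winner), collapse = ", ")),
         call. = FALSE)
  keep <- !is.na(shares$leading)
  pct <- matrix(NA_real_, 2, length(topics),
                dimnames = list(groups, topics))
  n <- stats::setNames(integer(2), groups)
  for (g in groups) {
    sel <- keep & winner == g
    n[g] <- sum(sel)
    if (n[g] == 0L) stop(sprintf("winner group %s has only tied geographies", g),
                         call. = FALSE)
    for (tp in topics) pct[g, tp] <- 100 * mean(shares$leading[sel] == tp)
  }
  list(percent = pct, n = n, n_ties = sum(!keep))
}
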