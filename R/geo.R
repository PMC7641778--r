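#' Cumulative query fraction over a post window
#'
#' Sum of the daily query fractions over the closed post interval
#' `[event_date, post_end]`.
#'
#' @param series A [query_series] covering the window.
#' @param window An [analysis_window].
#' @return The cumulative QF (scalar).
#' @export
cumulative_qf <- function(series, window) {
  stopifnot(inherits(series, "query_series"),
            inherits(window, "analysis_window"))
  idx <- series$dates >= window$event_date & series$dates <= window$post_end
  n_days <- as.integer(window$post_end - window$event_date) + 1L
  if (sum(idx) != n_days || anyNA(series$values[idx]))
    stop(sprintf("series %s/%s does not cover every day of the post window",
                 series$geography, series$topic), call. = FALSE)
  sum(series$values[idx])
}

#' Build a state x topic panel of cumulative query fractions
#'
#' @param collection Named list of [query_series] covering all
#'   geography x topic combinations.
#' @param window An [analysis_window].
#' @param covariates Optional covariate data.frame (attached as attribute).
#' @return A numeric matrix (rows geographies, columns topics) of class
#'   `state_panel`; covariates, if given, in `attr(, "covariates")`.
#' @export
state_panel <- function(collection, window, covariates = NULL) {
  stopifnot(length(collection) >= 1L)
  geos <- sort(unique(vapply(collection, `[[`, "", "geography")))
  topics <- unique(vapply(collection, `[[`, "", "topic"))
  m <- matrix(NA_real_, length(geos), length(topics),
              dimnames = list(geos, topics))
  for (s in collection) m[s$geography, s$topic] <- cumulative_qf(s, window)
  if (anyNA(m))
    stop("panel has missing geography x topic cells", call. = FALSE)
  if (!is.null(covariates)) {
    covariates <- validate_covariates(covariates)
    if (!all(geos %in% covariates$geography))
      stop("covariate table missing geographies present in the panel",
           call. = FALSE)
    attr(m, "covariates") <-
      covariates[match(geos, covariates$geography), , drop = FALSE]
  }
  attr(m, "window") <- window
  class(m) <- c("state_panel", class(m))
  m
}

#' Rank geographies by cumulative query fraction for one topic
#'
#' Geographies are ordered by descending QF. Each is contrasted with the mean
#' of a comparison set: `fold = QF / mean`, and for geographies below the
#' mean, `pct_below_mean = (1 - fold) * 100`. Ties share the minimum rank.
#'
#' @param panel A [state_panel].
#' @param topic Topic column to rank on.
#' @param comparison `"all"` (default): the mean includes every geography;
#'   `"exclude_focal"`: each geography is compared with the mean of the
#'   others. Both conventions are plausible readings of "the average for the
#'   states", so both are offered.
#' @return A data.frame with columns `geography, qf, rank, fold,
#'   pct_below_mean`, ordered by rank.
#' @export
rank_states <- function(panel, topic, comparison = c("all", "exclude_focal")) {
  comparison <- match.arg(comparison)
  stopifnot(inherits(panel, "state_panel"), topic %in% colnames(panel))
  if (nrow(panel) < 2L) stop("need at least 2 geographies", call. = FALSE)
  qf <- panel[, topic]
  n <- length(qf)
  cmp_mean <- if (comparison == "all") rep(mean(qf), n)
              else (sum(qf) - qf) / (n - 1)
  if (any(cmp_mean == 0)) stop("comparison mean is zero", call. = FALSE)
  fold <- qf / cmp_mean
  out <- data.frame(geography = rownames(panel), qf = unname(qf),
                    rank = rank(-qf, ties.method = "min"),
                    fold = unname(fold),
                    pct_below_mean = ifelse(fold < 1, (1 - fold) * 100, NA_real_),
                    stringsAsFactors = FALSE)
  out[order(out$rank, out$geography), , drop = FALSE]
}

#' Normalize a panel to within-geography topic shares
#'
#' Each geography's cumulative QF per topic is scaled by its total across all
#' topics, so shares sum to 1 per geography. The leading topic attains the
#' maximum share; an exact tie for the lead is recorded (all tied topics) and
#' the geography's `leading` entry is set to `NA` so that single-winner
#' tallies can exclude it explicitly.
#'
#' @param panel A [state_panel] (or bare matrix with dimnames).
#' @return An object of class `topic_shares`: list with `shares` (matrix),
#'   `leading` (character, `NA` on ties), `ties` (named list of tied topic
#'   sets), and the covariates carried over from the panel.
#' @export
topic_shares <- function(panel) {
  m <- unclass(panel)
  tot <- rowSums(m)
  zero <- which(tot == 0)
  if (length(zero))
    stop(sprintf("geography %s has zero total QF; shares undefined",
                 rownames(m)[zero[1]]), call. = FALSE)
  shares <- m / tot
  leading <- character(nrow(m))
  ties <- list()
  for (i in seq_len(nrow(m))) {
    mx <- max(shares[i, ])
    lead <- colnames(m)[shares[i, ] == mx]
    if (length(lead) > 1L) {
      leading[i] <- NA_character_
      ties[[rownames(m)[i]]] <- lead
    } else leading[i] <- lead
  }
  structure(list(shares = shares,
                 leading = stats::setNames(leading, rownames(m)),
                 ties = ties,
                 covariates = attr(panel, "covariates")),
            class = "topic_shares")
}

#' @export
print.topic_shares <- function(x, ...) {
  cat(sprintf("<topic_shares> %d geographies x %d topics, %d tie(s)\n",
              nrow(x$shares), ncol(x$shares), length(x$ties)))
  invisible(x)
}

#' Tally leading topics across geographies
#'
#' Counts, per topic, the geographies whose leading (largest-share) topic it
#' is, along with the average leading share among those geographies. Tied
#' geographies are excluded from the single-winner counts and reported
#' separately.
#'
#' @param shares A [topic_shares()] result.
#' @return A list with `counts` (named integer vector over all topics),
#'   `mean_leading_share` (named, `NA` where a topic leads nowhere), and
#'   `n_ties`.
#' @export
leading_topic_tally <- function(shares) {
  stopifnot(inherits(shares, "topic_shares"))
  topics <- colnames(shares$shares)
  lead <- shares$leading[!is.na(shares$leading)]
  counts <- stats::setNames(integer(length(topics)), topics)
  tab <- table(lead)
  counts[names(tab)] <- as.integer(tab)
  mls <- stats::setNames(rep(NA_real_, length(topics)), topics)
  for (tp in names(tab)) {
    g <- names(lead)[lead == tp]
    mls[tp] <- mean(shares$shares[g, tp])
  }
  list(counts = counts, mean_leading_share = mls,
       n_ties = length(shares$ties))
}

# One-way random-effects ICC(1) for a geographies x topics matrix:
# (MSB - MSW) / (MSB + (k - 1) MSW), geography as the grouping factor.
icc_oneway <- function(m) {
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) stop("need at least 2 rows and 2 columns", call. = FALSE)
  row_means <- rowMeans(m)
  grand <- mean(m)
  ssb <- k * sum((row_means - grand)^2)
  ssw <- sum((m - row_means)^2)
  msb <- ssb / (n - 1)
  msw <- ssw / (n * (k - 1))
  if (msb + (k - 1) * msw == 0)
    stop("zero total variance; ICC undefined", call. = FALSE)
  (msb - msw) / (msb + (k - 1) * msw)
}

#' Intraclass correlation of search rates across topics
#'
#' One-way random-effects ICC(1) treating geography as the grouping factor
#' and topics as repeated measures: the share of total variance attributable
#' to between-geography differences. Because raw query fractions are heavily
#' right-skewed, the default first applies a rank-based inverse-normal
#' transform to all cells; `transform = "raw"` uses the values as-is.
#'
#' @param panel A [state_panel] (or bare numeric matrix), no missing cells.
#' @param transform `"rank"` (default) or `"raw"`.
#' @return The ICC (scalar in `[-1, 1]`).
#' @export
icc <- function(panel, transform = c("rank", "raw")) {
  transform <- match.arg(transform)
  m <- unclass(panel)
  attributes(m)[setdiff(names(attributes(m)), c("dim", "dimnames"))] <- NULL
  if (anyNA(m)) stop("panel has missing cells", call. = FALSE)
  if (transform == "rank") {
    v <- stats::qnorm((rank(m, ties.method = "average") - 0.5) / length(m))
    m <- matrix(v, nrow(m), ncol(m), dimnames = dimnames(m))
  }
  icc_oneway(m)
}

#' Bottom-k versus top-k group contrast
#'
#' Geographies are scored by their mean cumulative QF across topics; the
#' contrast is how much lower the bottom `k` group's mean is than the top
#' `k` group's: `(1 - mean_bottom / mean_top) * 100`. The interval resamples
#' geographies with replacement within each group (percentile bootstrap,
#' seeded).
#'
#' @param panel A [state_panel].
#' @param k Group size (default 5); `2k` must not exceed the number of
#'   geographies.
#' @param B Bootstrap replicates (default 2000).
#' @param level Interval coverage (default 0.95).
#' @param seed Integer seed.
#' @return A list with `percent_lower` (point estimate), `ci`, the group
#'   memberships, and the group means.
#' @export
group_contrast <- function(panel, k = 5L, B = 2000L, level = 0.95, seed = 1L) {
  m <- unclass(panel)
  k <- as.integer(k)
  if (2L * k > nrow(m)) stop("k too large for the number of geographies",
                             call. = FALSE)
  scores <- rowMeans(m)
  ord <- order(scores, decreasing = TRUE)
  top <- scores[ord[seq_len(k)]]
  bottom <- scores[ord[seq(length(scores) - k + 1L, length(scores))]]
  est <- (1 - mean(bottom) / mean(top)) * 100
  set.seed(seed)
  reps <- vapply(seq_len(B), function(b) {
    tb <- sample(top, k, replace = TRUE)
    bb <- sample(bottom, k, replace = TRUE)
    (1 - mean(bb) / mean(tb)) * 100
  }, numeric(1))
  alpha <- (1 - level) / 2
  list(percent_lower = est,
       ci = stats::quantile(reps, c(alpha, 1 - alpha), type = 1,
                            names = FALSE),
       top = names(top), bottom = names(bottom),
       mean_top = mean(top), mean_bottom = mean(bottom),
       B = B, level = level, seed = seed)
}
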