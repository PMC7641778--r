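#' Load a pipeline configuration
#'
#' Configurations are plain lists, usually read from a YAML (or JSON) file.
#' Top-level blocks:
#' \describe{
#'   \item{`seed`}{integer root seed, mandatory whenever any stochastic stage
#'     runs (simulation or bootstrap); every stage seed is derived from it.}
#'   \item{`simulate`}{arguments for [synthetic_config()]; mutually exclusive
#'     with `input`.}
#'   \item{`input`}{`series_csv` (long dialect) and `covariates_csv` paths.}
#'   \item{`window`}{`baseline_start`, `event_date`, `post_end`.}
#'   \item{`model`}{`orders` (fixed `[p, d, q]`, or null for automatic
#'     selection), `max_p`, `max_q`, `level`, `B`.}
#'   \item{`geo`}{`contrast_k`, `comparison`, `icc_transform`.}
#' }
#'
#' @param path YAML or JSON file path.
#' @return The configuration list.
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) jsonlite::read_json(path,
                                                          simplifyVector = TRUE)
         else yaml::read_yaml(path)
  cfg
}

pipeline_defaults <- function(config) {
  config$model <- utils::modifyList(
    list(orders = NULL, max_p = 5L, max_q = 5L, level = 0.95, B = 1000L),
    as.list(config$model))
  config$geo <- utils::modifyList(
    list(contrast_k = 5L, comparison = "all", icc_transform = "rank"),
    as.list(config$geo))
  config
}

# Deterministic derivation of stage seeds from the root seed; offsets keep
# independent stages on distinct, reproducible streams.
derive_seed <- function(root, offset) {
  as.integer((as.numeric(root) * 7919 + offset) %% 2147483647)
}

#' Run the full excess-search-interest pipeline
#'
#' Stages: obtain data (synthetic panel or CSV input), fit a baseline ARIMA
#' per geography x topic series, forecast the counterfactual, compute excess
#' ratios with bootstrap intervals, build the state x topic panel and its
#' summaries (rankings, topic shares, leading-topic tally, ICC, bottom-k vs
#' top-k contrast), and fit the vote-share regressions. The returned bundle
#' (and anything written to `out_dir`) is a pure function of the
#' configuration, including its seed.
#'
#' @param config A configuration list or a path accepted by
#'   [read_pipeline_config()].
#' @param out_dir Optional output directory; when given, writes
#'   `report.json`, `report.md`, `ranking_<topic>.csv`, `shares.csv`, and
#'   (for simulated data) `series.csv`, `covariates.csv`, `truth.json`.
#' @param quiet Suppress stage progress messages (they go to `stderr`).
#' @return The report bundle (list), invisibly when `out_dir` is given.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  config <- pipeline_defaults(config)
  say <- function(fmt, ...) if (!quiet) message(sprintf(fmt, ...))
  stochastic <- !is.null(config$simulate) || config$model$B > 0
  if (stochastic && is.null(config$seed))
    stop("config must set a seed: stochastic stages (simulation/bootstrap) requested",
         call. = FALSE)
  seed <- config$seed

  # --- stage: data -----------------------------------------------------
  t0 <- proc.time()[["elapsed"]]
  truth <- NULL
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- derive_seed(seed, 1L)
    scfg <- do.call(synthetic_config, sim_args)
    panel_data <- generate_panel(scfg)
    collection <- panel_data$series
    covariates <- panel_data$covariates
    truth <- panel_data$truth
    if (is.null(config$window))
      config$window <- list(baseline_start = format(scfg$baseline_start),
                            event_date = format(scfg$event_date),
                            post_end = format(scfg$post_end))
  } else if (!is.null(config$input)) {
    collection <- read_series_csv(config$input$series_csv, dialect = "long")
    covariates <- if (!is.null(config$input$covariates_csv))
      read_covariates(config$input$covariates_csv) else NULL
  } else stop("config needs either a 'simulate' or an 'input' block",
              call. = FALSE)
  if (is.null(config$window))
    stop("config must declare the analysis window", call. = FALSE)
  window <- analysis_window(config$window$baseline_start,
                            config$window$event_date,
                            config$window$post_end)
  say("[data] %d series, %.1fs", length(collection),
      proc.time()[["elapsed"]] - t0)

  # --- stage: counterfactual + excess per series -----------------------
  t0 <- proc.time()[["elapsed"]]
  excess <- vector("list", length(collection))
  names(excess) <- names(collection)
  for (i in seq_along(collection)) {
    s <- collection[[i]]
    key <- names(collection)[i]
    res <- tryCatch({
      parts <- slice_window(s, window)
      baseline <- fill_gaps(parts$baseline)
      spec <- if (!is.null(config$model$orders))
        fit_arima(baseline, order = config$model$orders)
      else select_order(baseline, max_p = config$model$max_p,
                        max_q = config$model$max_q)
      bootstrap_excess_ci(spec, parts$post, B = config$model$B,
                          level = config$model$level,
                          seed = derive_seed(seed, 100L + i))
    }, error = function(e)
      stop(sprintf("stage counterfactual/excess failed for %s: %s",
                   key, conditionMessage(e)), call. = FALSE))
    excess[[i]] <- res
  }
  say("[excess] %d series, B = %d, %.1fs", length(excess), config$model$B,
      proc.time()[["elapsed"]] - t0)

  # --- stage: geography x topic summaries ------------------------------
  t0 <- proc.time()[["elapsed"]]
  panel <- state_panel(collection, window, covariates)
  topics <- colnames(panel)
  multi_geo <- nrow(panel) >= 2L
  rankings <- if (multi_geo)
    stats::setNames(lapply(topics, function(tp)
      rank_states(panel, tp, comparison = config$geo$comparison)), topics)
  else NULL
  shares <- topic_shares(panel)
  tally <- leading_topic_tally(shares)
  panel_icc <- if (multi_geo && length(topics) >= 2L)
    icc(panel, transform = config$geo$icc_transform) else NA_real_
  contrast <- if (multi_geo && 2L * config$geo$contrast_k <= nrow(panel))
    group_contrast(panel, k = config$geo$contrast_k,
                   level = config$model$level,
                   seed = derive_seed(seed %||% 0L, 7L))
  else NULL
  say("[geo] panel %d x %d, %.1fs", nrow(panel), ncol(panel),
      proc.time()[["elapsed"]] - t0)

  # --- stage: political ------------------------------------------------
  political <- NULL
  if (!is.null(covariates) && multi_geo && nrow(panel) >= 3L) {
    political <- list(
      models = fit_all_vote_share_models(shares, level = config$model$level),
      breakdown = tryCatch(winner_breakdown(shares),
                           error = function(e) conditionMessage(e)))
  }

  bundle <- list(
    config = config,
    window = list(baseline_start = format(window$baseline_start),
                  event_date = format(window$event_date),
                  post_end = format(window$post_end)),
    excess = lapply(excess, summarize_excess),
    panel = as_panel_df(panel),
    rankings = rankings,
    shares = as.data.frame(shares$shares),
    leading = as.list(shares$leading),
    tally = tally,
    icc = panel_icc,
    group_contrast = contrast[c("percent_lower", "ci", "top", "bottom")],
    political = political,
    truth = truth)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(truth)) {
      write_series_csv(collection, file.path(out_dir, "series.csv"))
      utils::write.csv(covariates, file.path(out_dir, "covariates.csv"),
                       row.names = FALSE)
      jsonlite::write_json(truth_serializable(truth),
                           file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
    }
    jsonlite::write_json(bundle_serializable(bundle),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         na = "null")
    writeLines(render_report_md(bundle), file.path(out_dir, "report.md"))
    if (multi_geo) for (tp in topics)
      utils::write.csv(rankings[[tp]],
                       file.path(out_dir, sprintf("ranking_%s.csv", tp)),
                       row.names = FALSE)
    utils::write.csv(data.frame(geography = rownames(shares$shares),
                                shares$shares, check.names = FALSE),
                     file.path(out_dir, "shares.csv"), row.names = FALSE)
    return(invisible(bundle))
  }
  bundle
}

`%||%` <- function(a, b) if (is.null(a)) b else a

summarize_excess <- function(r) {
  list(cumulative_ratio = r$cumulative_ratio,
       cumulative_percent = r$cumulative_percent,
       cumulative_ci = as.numeric(r$cumulative_ci),
       significant = isTRUE(r$significant),
       B = r$B, level = r$level, seed = r$seed,
       n_floored = r$n_floored + r$n_floored_bootstrap)
}

as_panel_df <- function(panel) {
  data.frame(geography = rownames(panel), unclass(panel)[, , drop = FALSE],
             check.names = FALSE, row.names = NULL)
}

truth_serializable <- function(truth) {
  truth$expected_shares <- as.data.frame(truth$expected_shares)
  truth$config$baseline_start <- format(truth$config$baseline_start)
  truth$config$event_date <- format(truth$config$event_date)
  truth$config$post_end <- format(truth$config$post_end)
  truth
}

bundle_serializable <- function(bundle) {
  bundle$truth <- if (!is.null(bundle$truth))
    truth_serializable(bundle$truth) else NULL
  bundle
}

render_report_md <- function(bundle) {
  ex <- bundle$excess
  sig <- vapply(ex, `[[`, TRUE, "significant")
  lines <- c(
    "# Excess search interest report",
    "",
    sprintf("Post window: %s to %s (event %s).",
            bundle$window$event_date, bundle$window$post_end,
            bundle$window$event_date),
    "",
    sprintf("Series analysed: %d; significant cumulative excess in %d (%.0f%%).",
            length(ex), sum(sig), 100 * mean(sig)),
    "",
    "## Cumulative excess by series",
    "",
    "| series | ratio | % above expected | CI | significant |",
    "|---|---|---|---|---|",
    vapply(names(ex), function(k) {
      e <- ex[[k]]
      sprintf("| %s | %.2f | %.0f%% | (%.0f, %.0f) | %s |", k,
              e$cumulative_ratio, e$cumulative_percent,
              e$cumulative_ci[1], e$cumulative_ci[2],
              if (e$significant) "yes" else "no")
    }, ""),
    "")
  if (!is.null(bundle$tally)) {
    lines <- c(lines, "## Leading topics", "",
               vapply(names(bundle$tally$counts), function(tp)
                 sprintf("- %s: leads in %d geographies", tp,
                         bundle$tally$counts[[tp]]), ""),
               "", sprintf("Intraclass correlation across topics: %.2f.",
                           bundle$icc), "")
  }
  if (!is.null(bundle$political) && is.data.frame(bundle$political$models)) {
    md <- bundle$political$models
    lines <- c(lines, "## Vote-share regressions", "",
               vapply(seq_len(nrow(md)), function(i)
                 sprintf("- %s: %+.2f pp share per +10 pp Trump vote share (R2 = %.2f)",
                         md$topic[i], md$per10_effect[i], md$r2[i]), ""),
               "")
  }
  lines
}
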