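# searchexcess

Excess search interest analysis with ARIMA counterfactuals.

## What problem does this solve?

Aggregate internet search volumes are a fast, freely observable proxy for
public interest. After a salient event — a celebrity health disclosure, a
policy controversy, a death in police custody — search interest in related
topics can surge by orders of magnitude, and analysts in digital
epidemiology / infoveillance want to answer: *how much higher is search
interest than it would have been without the event, where, and for which
topics?*

`searchexcess` implements that workflow for daily **query fractions**
(searches matching a term set per 10 million total searches from a geography
on a day):

1. **Counterfactual baseline.** An ARIMA(p,d,q) model is selected
   automatically (successive KPSS tests choose the differencing order `d`;
   a stepwise AICc search over `p`, `q` and the constant does the rest) and
   fit by maximum likelihood to the pre-event series. The fitted model is
   forecast over the post-event window to give the expected search rates had
   the event not occurred.
2. **Excess statistics.** Observed vs expected is summarised per day
   (`o_t / ê_t`) and cumulatively (`Σo_t / Σê_t`; percent excess
   `(ratio − 1)·100`). Uncertainty comes from a residual bootstrap: fitted
   residuals are resampled and pushed through the model recursion to
   simulate replicate counterfactual paths, giving percentile intervals that
   are exactly reproducible under a seed. A result is *significant* when the
   lower cumulative bound exceeds 0 % excess.
3. **Geographic and topic structure.** Per-state cumulative query fractions
   feed rankings with fold-vs-mean contrasts, within-state topic shares
   (normalised so each state's topics sum to 1), leading-topic tallies, a
   one-way random-effects intraclass correlation across topics, and a
   bottom-k vs top-k group contrast with a bootstrap interval.
4. **Political covariate.** Topic shares are regressed on each state's 2016
   two-party Trump vote share (OLS, t-based intervals); effects are reported
   as percentage points of share per 10-percentage-point vote-share
   increase, plus a leading-topic breakdown by state winner.
5. **Synthetic data.** Because real search extracts are proprietary, the
   package ships a generator with fully known ground truth: AR(1) baselines,
   a multiplicative event surge `m(t) = floor + (peak − floor)·2^(−t/h)`
   whose cumulative effect has a closed form, lognormal state level factors,
   and topic shares linear in vote share. Every downstream stage is
   validated against these injected truths.

## Worked example

```r
library(searchexcess)

cfg <- synthetic_config(baseline_start = "2018-01-01")   # stated world
s   <- generate_baseline(cfg, seed = 7)                  # daily QF series
obs <- apply_event_effect(s, cfg$event_date, 37.7, 10, 5)

w  <- analysis_window("2018-01-01", "2020-05-25", "2020-07-05")
sw <- slice_window(obs, w)
spec <- select_order(fill_gaps(sw$baseline))
spec
#> <arima_spec> ARIMA(1,0,0), mean 1.994; sigma2 = 0.2372, AICc = 1231.05, n = 875

bootstrap_excess_ci(spec, sw$post, B = 2000, seed = 11)
#> <excess_result> 42 days, cumulative ratio 11.504 (+1050.4% vs expected)
#>   95% bootstrap CI on percent excess: (820.9, 1449.3), B = 2000, significant
```

Reading: over the 42-day post window the observed series ran 11.5 times its
counterfactual expectation, i.e. about +1050 % (bootstrap 95 % CI 821–1449 %),
and the excess is significant. The injected truth for this world is a mean
multiplier of 16.0 (+1499 %); an individual draw scatters around it
(estimates are unbiased across seeds), and the draw above landed low.

The full pipeline runs from a YAML config:

```r
run_pipeline(system.file("extdata", "demo_config.yaml",
                         package = "searchexcess"),
             out_dir = "demo_out")
```

which writes `report.json` / `report.md`, per-topic ranking CSVs, and topic
shares. On the demo world (10 geographies) the vote-share regressions
recover the injected slopes (+4.55 and −5.03 pp per 10 pp against injected
+4.5 / −4.3) and all 40 series are flagged significant against the injected
surge.

A command-line launcher with `simulate`, `counterfactual`, `excess`, `geo`,
`political` and `run` subcommands is installed at

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "searchexcess",
                                       package = "searchexcess"))')" run \
  --config demo_config.yaml --out-dir demo_out
```

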