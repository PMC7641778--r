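---
title: "Counterfactual excess search interest: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counterfactual excess search interest: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimand

The unit of observation is a daily *query fraction* (QF): searches matching
a term set per 10 million total searches from one geography on one day. For
an event at date $t_0$, the package estimates how much higher search
interest ran than it would have absent the event, over a closed post window
$[t_0, t_1]$:

$$ \text{excess} = \frac{\sum_{t=t_0}^{t_1} o_t}{\sum_{t=t_0}^{t_1} \hat e_t} - 1, $$

where $o_t$ is the observed QF and $\hat e_t$ a model-based counterfactual
forecast fit only to pre-event data. We report the ratio of sums, not the
mean of daily ratios: the two differ in general, and the ratio of sums is
stable when individual expected days approach zero. The event day itself
belongs to the post window, because interest begins to move on the day of
the event.

## Counterfactual model

The baseline is a Gaussian ARIMA(p,d,q), fit by maximum likelihood on the
raw QF scale. No transform is applied by default: the downstream statistic
is a ratio and therefore scale-free, and log transforms are awkward for
series with legitimate zero days. Seasonality is not modelled by default;
day-of-week structure in query fractions is weak relative to the surges of
interest here.

Order selection follows the standard automatic scheme:

* **Differencing** $d$ is the smallest value ($\le 2$) at which the KPSS
  level-stationarity statistic no longer rejects at $\alpha = 0.05$.
  The long-run variance inside the statistic uses a Bartlett window with the
  *long* bandwidth $\lfloor 12 (n/100)^{1/4}\rfloor$. This is a deliberate
  numerical choice: with the short bandwidth the test's size is badly
  inflated under strong short-range autocorrelation (rejecting ~15 % of
  AR(1), $\phi = 0.8$, $n = 1000$ series instead of ~5 %), which would push
  stationary baselines into needless differencing. The implementation was
  checked to 10 decimal places against an independent implementation on
  frozen series.
* **ARMA orders and the constant** are chosen by stepwise AICc search:
  starting models $(2,2), (0,0), (1,0), (0,1)$ plus the $(p_{max},
  q_{max})$ corner, hill-climbing to the best admissible neighbour
  ($p \pm 1$, $q \pm 1$, both, or constant toggled) until no improvement.
  The corner start is an addition to the classic four: it costs one fit and
  reaches distant AICc optima that hill-climbing from small models cannot.
  AICc uses the small-sample correction $2k(k+1)/(n-k-1)$ with $k$ counting
  coefficients plus the innovation variance. Ties in AICc are broken toward
  smaller $p+q$, then smaller $q$, so selection is reproducible.
* **Admissibility.** Candidates are discarded when an AR or MA root lies
  inside a 1.001 circle (effectively non-causal/non-invertible) or when an
  AR root lies within 0.1 of an MA root. The second rule matters in
  practice: near-common factors make an ARMA model practically
  unidentified, and such fits regularly post spurious AICc gains of 2–9 on
  pure AR(1) data while forecasting no better. Both rules apply identically
  to the stepwise and the exhaustive (validation) search, so comparisons
  between the two are fair.
* The constant is a mean for $d = 0$, a drift for $d = 1$, and absent for
  $d = 2$.

Forecasts are the conditional-expectation recursion of the fitted model;
prediction intervals are $\hat e_t \pm z \cdot s_h$ with $s_h$ from the
psi-weight accumulation of forecast-error variance. The interval level is
exposed (`level`, default 0.95) because the source analyses do not state
theirs.

## Bootstrap uncertainty

The study design gives no replicate observations, so uncertainty in the
counterfactual is propagated by a **model-residual bootstrap**: centred
fitted residuals (after dropping the first $p+d+q$ Kalman initialization
residuals) are resampled with replacement and pushed through the fitted
recursion to simulate $B$ replicate expected paths over the horizon
(default $B = 10{,}000$; tests and the demo use less). Each replicate
statistic compares the actual observed series with one replicate path;
intervals are percentile intervals (type-1 quantiles, i.e. order
statistics, so widening the level can only widen the interval). Everything
is deterministic under a seed, which the API requires rather than defaults.

Numerical guards:

* replicate expected paths are floored at $10^{-6}$ times the baseline mean
  before ratio formation, and flooring events are counted in the output;
* residuals whose spread is below $10^{-9}(1 + \max|y|)$ (an exactly
  deterministic series up to Kalman noise) yield zero-width intervals with
  a warning rather than meaningless ones.

The per-day intervals are pointwise, not simultaneous, and are labelled as
such. Significance of a series means: the lower bound of the cumulative
percent-excess interval exceeds 0.

## Geographic and topic summaries

* **Rankings** order geographies by cumulative post-window QF and contrast
  each with a comparison mean (`fold = QF / mean`). Published fold
  statements of this kind are ambiguous about whether the focal geography
  belongs to "the average"; both conventions are implemented
  (`comparison = "all"`, the default, and `"exclude_focal"`) and neither is
  asserted as canonical.
* **Topic shares** divide a geography's per-topic cumulative QF by its
  total across topics; shares sum to 1 by construction. Exact ties for the
  leading topic are never broken silently: tied geographies are excluded
  from single-winner tallies and reported separately.
* **ICC** is the one-way random-effects ICC(1),
  $(MS_B - MS_W)/(MS_B + (k-1)MS_W)$, geography as the grouping factor and
  topics as repeated measures. Raw QFs are heavily right-skewed, so the
  default applies a rank-based inverse-normal transform to all cells first;
  `transform = "raw"` is available and is what the ANOVA-oracle equivalence
  tests exercise. Note the one-way layout charges fixed topic-level
  differences to the within-group term, so strong topic main effects pull
  the ICC down; that is a property of the chosen flavour, which the source
  analysis does not specify.
* **Group contrast** compares bottom-$k$ and top-$k$ geographies by mean QF
  across topics, $(1 - \bar m_{bottom}/\bar m_{top}) \cdot 100$, with a
  seeded percentile bootstrap resampling geographies within groups.

## Political covariate

The response in the dose-response regression is the topic *share* (not raw
QF): shares make states of very different sizes comparable and match how
the relationship is usually plotted. OLS is unweighted (no weighting is
described for the source analysis; a total-QF weighted option exists), the
CI uses the t-distribution with $n-2$ df (small-n ecological regression),
and the headline number is $10 \times$ slope: percentage points of share
per 10-percentage-point increase in Trump vote share. Because shares sum
to 1 per geography and OLS is linear, fitted slopes across topics sum to 0
exactly — asserted in tests at $10^{-10}$.

## The synthetic world

The generator states one world and the tests live in it:

| parameter | default | why |
|---|---|---|
| geographies | 51 | 50 states + DC |
| topics | union, training, immunity, militarization | the tracked reform topics |
| baseline span | 2010-01-01 to 2020-05-24 | the study's fitting window |
| post window | 2020-05-25 to 2020-07-05 | event day + 41 days = 42 days |
| baseline process | AR(1), $\phi = 0.7$, mean 2 QF/10M, sd 0.5 | modest positive day-to-day persistence around a low level |
| surge | peak 37.7×, half-life 10 d, floor 5× | cumulative mean multiplier 16.0 (+1499 %), the order of magnitude of the headline excess; the floor keeps the series elevated through the end of observation |
| topic slopes | +0.45, −0.43, −0.01, −0.01 per unit vote share | ±4.5/−4.3 pp per 10 pp, the reported effect sizes |
| topic intercepts | 0.18, 0.655, 0.13, 0.035 | training/union crossover at vote share ≈ 0.54, so training leads in ≈ 2/3 of geographies and union in the rest, union favoured where Trump won |
| vote share | Uniform(0.25, 0.70) | the realistic two-party range |
| state level factor | lognormal, sd 0.4 | shared across a state's topics; induces between-state correlation |
| panel noise | innovation sd = 0.25 × topic mean | constant coefficient of variation keeps small topics non-negative |

The surge is multiplicative with exponential decay to a floor,
$m(t) = \text{floor} + (\text{peak} - \text{floor}) 2^{-t/h}$, because that
matches the observed shape (sharp peak, decline to an elevated plateau) and
makes the true cumulative excess available in closed form via a geometric
sum (`mean_event_multiplier()`), so recovery tests compare against exact
injected truth. Gaussian baselines are clipped at zero (query fractions are
non-negative) and the clip rate is reported; at the default world it is
≈ 0.2 %.

What the generator does **not** emulate — and hence what a green test does
not establish: Google's sampling and 0–100 rescaling of its public export;
population weighting (the study's national volume ordering of topics
reflects big states, the generator's does not); calendar structure
(weekday/holiday effects); heavy-tailed or bursty query noise; and any
state where the linear share model breaks (immunity can never lead a
geography under the default world, though it did in two real states).
Coverage results certify the pipeline's statistics under the stated world,
not the study's actual data-generating process.

## Degenerate inputs and other numerical choices

* `"<1"` cells in public Trends exports are imputed at 0.5, the midpoint of
  the censored interval (configurable); the 0–100 relative scale is only
  converted to query fractions if the user supplies a scale factor, and
  absolute-volume conversion otherwise stays unavailable.
* Internal series live on a contiguous daily grid; missing days are
  explicit `NA`s. Gaps up to 3 consecutive days (configurable) are linearly
  interpolated before fitting; longer gaps are an error, since ARIMA
  fitting needs a regular grid and silently bridging long gaps would fake
  precision.
* Zero-variance series are rejected by `fit_arima` whenever parameters must
  be estimated; parameter-free models (e.g. a pure random walk on a linear
  ramp) are allowed, which is what exercises the zero-width bootstrap path.
* Absolute counts are `qf / 1e7 × total_volume`; the package ships no
  volume series, so such conversions always rest on user-supplied inputs.
* All pipeline randomness flows from one root seed through a fixed affine
  splitting scheme (`seed × 7919 + offset, mod 2^31 − 1`), making the full
  report bundle byte-identical across runs with the same config.

## Known limitations

* The stepwise order search is a heuristic; it is validated to sit within
  2 AICc of the exhaustive $(p, q \le 3)$ minimum across 100 seeded AR(1)
  runs, not to find the global optimum always.
* The KPSS bandwidth choice trades power against size: near-unit-root
  alternatives lose some power relative to the short bandwidth. For long
  daily series this is the right side of the trade.
* Bootstrap intervals treat the fitted orders and coefficients as fixed;
  model-selection uncertainty is not propagated.
* The ecological regression is descriptive: nothing here supports causal
  claims about why states search differently, and searchers are not voters.
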