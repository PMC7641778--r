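Package: searchexcess
Title: Excess Search Interest Analysis with ARIMA Counterfactuals
Version: 0.1.0
Authors@R:
    person("Search", "Excess Contributors", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying event-driven surges in aggregate internet
    search interest. Fits an automatically selected ARIMA baseline to daily
    query-fraction series (searches per 10 million total searches), forecasts
    a counterfactual for the post-event window, and reports observed/expected
    excess ratios with residual-bootstrap confidence intervals, daily and
    cumulatively. Includes state-level summaries (rankings, topic shares,
    leading-topic tallies, intraclass correlation, top/bottom group
    contrasts), an ecological regression of topic shares on a political
    covariate, a fully parameterized synthetic-data generator with known
    ground truth, and a command-line pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
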