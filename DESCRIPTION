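Package: microdrift
Title: Quantifying Selection and Ecological Drift in Replicated Microbial Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the relative contribution of selection and ecological
    drift to community assembly in dispersal-limited, replicated microbial
    time series. Provides a stochastic microcosm simulator (per-taxon logistic
    growth with washout, continuous or pulsed dilution disturbance, crossover
    designs, multinomial read sampling), multi-rarefaction normalisation and
    Hill diversity, replicate-pair Bray-Curtis and Sorensen similarity
    trajectories, a hierarchical Bayesian distributional regression of
    similarity on time with fixed effects on both the mean and the standard
    deviation, predictive-density model comparison, and a slope-sign quadrant
    rule that labels each experimental group as dominated by selection, drift,
    or a mix of both.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    vegan,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
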