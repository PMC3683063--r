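Package: shulk
Title: Context-Dependent Strain Competition in Serial Batch Culture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing intra-specific bacterial competition whose
    outcome depends on nutrient context: Monod growth kinetics with
    gleaner/exploiter (high-mu_max vs low-K_s) pair classification and
    crossover concentrations, doubling-time extraction from OD600 growth
    curves, Monod parameter fitting from concentration-series designs, a
    consumer-resource ODE simulator of batch and serial-batch culture
    (transfer regimes, long-term stationary phase, background-community and
    spike-in scenarios, nutrient-dilution media), two-strain Lotka-Volterra
    isocline analysis from carrying capacities, constrained linear unmixing
    of mixed marker-gene electropherogram traces into strain relative
    abundances with a detection-limit observation model, small-sample
    summary-statistic t tests and an exact tie-aware Mann-Whitney U test,
    and seeded synthetic-data generators for every input the pipeline
    consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    minpack.lm,
    pracma,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
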