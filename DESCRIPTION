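Package: trailmc
Title: Self-Avoiding Trail MCMC and Collective-Exploration Trajectory Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for stigmergic ("trail") Markov chain Monte Carlo sampling
    and for the analysis of central-place exploration trajectories. Provides a
    Metropolis-Hastings sampler on periodic 2D lattices together with a
    self-avoiding variant that targets P*P/M, where M is an externalized
    memory of visited states accumulated as Dirichlet-prior pseudo-counts with
    optional cleaning resets and exponential decay. Includes a trajectory
    pipeline that turns planar exploration paths into blurred log-polar
    density targets, cumulative cross-entropy convergence curves by walker
    order, a memoryless "Markov ant" resampling null model, exit-side
    summaries, paired permutation tests, chi-square and exact multinomial
    goodness-of-fit tests, and a synthetic cohort generator with controllable
    avoidance coupling so every stage can be exercised without tracking data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
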