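Package: spikemap
Title: State-Space Mapping of Spike-Train Dynamics in Small Neural Circuits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts paired spike trains from identified neurons (such as the
    pyloric dilator and lateral pyloric neurons of the crustacean
    stomatogastric ganglion) into fixed-length statistical feature vectors
    built from interspike-interval and spike-phase percentiles, embeds them
    into a two-dimensional map with t-SNE, assigns dynamic-state labels via
    cluster boundary polygons, and quantifies state probabilities, transition
    matrices with a resampling null model, burst metrics, and within- versus
    across-animal variability statistics. Includes seeded synthetic spike-train
    generators for twelve canonical and atypical circuit states so that every
    pipeline stage can be validated without recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rtsne,
    deldir,
    jsonlite,
    stats,
    utils,
    tools,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
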