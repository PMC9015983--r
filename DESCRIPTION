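Package: ppsbayes
Title: Bayesian Analysis of Peripersonal-Space Visuo-Tactile Reaction Times
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the Bayesian analysis of multisensory reaction-time
    experiments probing peripersonal space (PPS). Provides a synthetic
    generator for visuo-tactile looming paradigms (visuo-tactile,
    tactile-only and catch trials over five looming distances), per-participant
    interquartile-range outlier filtering and cell-mean aggregation,
    normalization of visuo-tactile reaction times against tactile-only
    baselines, hierarchical linear model fitting by conjugate Gibbs sampling,
    product-space (Carlin-Chib) comparison of hypotheses about the structure of
    tactile-only reaction times, Kuo-Mallick indicator variable selection over
    experimental factors, contrast-based localization of the PPS boundary, and
    the repeated-measures sample-size computation used to plan such designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    MASS,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    rjags
Config/testthat/edition: 3
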