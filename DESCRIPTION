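Package: dirdom
Title: Bayesian Genomic Evaluation with Directional Dominance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits Bayesian whole-genome regression models for repeated-record
    traits that allow for directional dominance, either through a regression
    on average individual SNP homozygosity (genomic inbreeding) or through a
    skew-Gaussian prior on SNP dominance effects with an asymmetry parameter,
    or both.  Models are fitted by a single-site Gibbs sampler with a
    compiled kernel.  The package derives additive and dominance genetic
    variances, heritability and dominance ratios, inbreeding depression,
    breeding values and dominance deviations from the posterior draws,
    provides MCMC summaries and diagnostics (HPD intervals, effective sample
    size, Geweke drift scores), and compares models by DIC and the logarithm
    of the conditional predictive ordinate.  A synthetic-data generator
    emulating pig litter-size recording schemes is included for validation
    and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
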