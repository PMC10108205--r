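Package: moranER
Title: Bayesian Inference of Selection from Evolve-and-Resequence Time
    Series under the Moran Model
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates selection coefficients from pooled-sequencing
    allele-frequency time series collected in Evolve-and-Resequence
    experiments. Allele evolution is modelled as a continuous-time Moran
    birth-death chain with absorbing boundaries; binomial or
    beta-binomial emission kernels account for finite sequencing depth.
    The log posterior of the selection coefficient is evaluated on a
    small grid, fitted to a gamma surface by closed-form least squares,
    and summarised as a posterior mean, variance and log Bayes factor
    testing departure from neutrality. Includes an exact Moran
    trajectory simulator with pool-seq sampling, sync-format input and
    output, an allele-frequency variance pre-filter, and command-line
    style entry points for inference, simulation and validation runs.
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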