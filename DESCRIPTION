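Package: bymgrowth
Title: Bayesian Small-Area Mapping of Poor Fetal Growth
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Small-area analysis of poor fetal growth (births under 80% of
    optimal birth weight) aggregated to suburbs. Provides a synthetic suburb
    registry generator, queen-contiguity adjacency with supplementary
    cross-river edges, birth-record eligibility filtering and case
    classification, four nested binomial-logit models combining an intrinsic
    conditional autoregressive (ICAR) and an exchangeable random effect
    fitted by Metropolis-within-Gibbs MCMC, DIC/pD model comparison, Geweke
    convergence diagnostics, interquartile odds-ratio effect summaries,
    posterior exceedance probabilities, Moran's I and Oden's I_pop spatial
    tests, and missing-data sensitivity checks for the case definition.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
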