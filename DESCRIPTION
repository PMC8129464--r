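Package: bridgetox
Title: Robust Bayesian Bridging of Dose-Toxicity Information in Phase I
    Trials with Animal Co-Data
Version: 0.1.0
Authors@R:
    person("Artifact", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Bayesian hierarchical dose-toxicity modelling for phase I
    oncology dose-escalation trials run in several patient subgroups or
    geographic regions, with co-data from completed animal toxicology
    studies. Animal doses are mapped onto an equivalent human dosing scale
    through species-specific log-normal translation parameters, and
    subgroup doses through truncated-normal bridging parameters.  Each
    subgroup's dose-toxicity parameter vector follows an
    exchangeability/non-exchangeability (EXNEX) mixture over animal
    species populations, a human-only population, and a robust
    non-exchangeable prior.  The package provides an adaptive
    Metropolis-within-Gibbs sampler for the full hierarchy, meta-analytic
    predictive (MAP) priors for human DLT risks, Beta moment-matching
    effective sample sizes, overdose-controlled escalation rules with
    safety stopping and MTD declaration, and a simulator of paired
    sequential trials for operating-characteristics studies.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
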