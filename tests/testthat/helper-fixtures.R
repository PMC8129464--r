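# shared builders for the test suite; everything is generated in code

toy_animal <- function() {
  list(
    animal_study("m1", "monkey", c(1, 10, 30, 100), rep(8L, 4), c(0L, 1L, 3L, 6L)),
    animal_study("r1", "rat", c(0.5, 2, 5, 15), rep(10L, 4), c(0L, 2L, 4L, 7L)))
}

toy_human <- function() {
  list(human_trial(1L, dose_panel(), n = c(3L, 3L, 6L, 9L, 3L, 0L),
                   r = c(0L, 0L, 1L, 2L, 1L, 0L)))
}

toy_point <- function(config = model_preset("A"), M = 2L) {
  K <- length(config$species); L <- config$n_subgroups
  parameter_point(
    theta = matrix(c(-1.2, 0.1, -0.8, -0.2), nrow = M, byrow = TRUE),
    muS = matrix(rep(c(-1.0, 0.05), K), nrow = K, byrow = TRUE),
    m = c(-1.1, 0), muH = c(-1.0, 0.1),
    gamma = matrix(rep(c(-1.3, 0.2), L), nrow = L, byrow = TRUE),
    eps = rep(0.9, L), delta = c(0.16, 0.33),
    tau = c(0.4, 0.2, 0.3, 0.1), sigma = c(0.8, 0.4),
    rho = 0.1, kappa = -0.2, eta = 0.3, z = c(2L, K + 2L))
}

quick_mcmc <- function(seed = NULL)
  mcmc_settings(chains = 2L, iterations = 4000L, burnin = 1000L, seed = seed)

# printed reference table of predictive-summary moments and their
# Beta-moment-matching ESS decomposition (divergent / consistent outcome
# scenarios for a completed first-in-region trial); used by the ESS checks
ess_reference <- function() {
  read.csv(system.file("extdata", "ess_reference_summaries.csv",
                       package = "bridgetox"))
}
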