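test_that("fits are reproducible given a seed", {
  cfg <- model_preset("A")
  an <- toy_animal()
  f1 <- fit_bridge_model(cfg, an, list(), quick_mcmc(seed = 123))
  f2 <- fit_bridge_model(cfg, an, list(), quick_mcmc(seed = 123))
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$z, f2$z)
  f3 <- fit_bridge_model(cfg, an, list(), quick_mcmc(seed = 124))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("fit validates inputs", {
  cfg <- model_preset("A")
  expect_error(fit_bridge_model(cfg, list(), list(), quick_mcmc(1)),
               "prior_only")
  bad <- animal_study("x", "dog", c(1, 2), c(3, 3), c(0, 0))
  expect_error(fit_bridge_model(cfg, list(bad), list(), quick_mcmc(1)),
               "dog")
  expect_error(fit_bridge_model(cfg, list(), list(human_trial(3, 1, 0L, 0L)),
                                quick_mcmc(1)), "subgroup")
  expect_error(mcmc_settings(iterations = 100, burnin = 100), "burn-in")
})

test_that("non-exchangeable prior-only reduction matches BVN(m0, R0)", {
  cfg <- bridge_config()  # w_R = 1 for both subgroups
  f <- fit_bridge_model(cfg, list(), list(), quick_mcmc(seed = 31),
                        prior_only = TRUE)
  g1 <- f$draws[, "gamma1[1]"]; g2 <- f$draws[, "gamma2[1]"]
  expect_lt(abs(mean(g1) - (-1.099)), 3 * mcse_mean(g1))
  expect_lt(abs(mean(g2) - 0), 3 * mcse_mean(g2))
  expect_equal(sd(g1), 2, tolerance = 0.1)
  expect_equal(sd(g2), 1, tolerance = 0.05)
  # degenerate mixture: indicator is identically the robust component
  expect_identical(unname(component_probabilities(f, 1)), c(0, 0, 0, 1))
  expect_error(component_probabilities(f, 3), "unknown")
  # symmetric truncated bridging prior
  e <- f$draws[, "eps[1]"]
  expect_lt(abs(mean(e) - 1), 3 * mcse_mean(e))
  expect_lt(abs(mean(e < 1) - 0.5), 3 * mcse_mean(as.numeric(e < 1)))
})

test_that("prior component probabilities recover the configured weights", {
  cfg <- model_preset("A")  # subgroup 1: (0.2, 0.6, 0, 0.2)
  f <- fit_bridge_model(cfg, list(), list(), quick_mcmc(seed = 32),
                        prior_only = TRUE)
  p <- component_probabilities(f, 1)
  for (c in 1:4) {
    se <- mcse_mean(as.numeric(f$z[, 1] == c))
    expect_lt(abs(p[c] - cfg$weights[1, c]), max(3 * se, 0.02))
  }
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("risk samples are monotone, bounded, and handle degenerate draws", {
  cfg <- model_preset("A")
  f <- fit_bridge_model(cfg, toy_animal(), toy_human(), quick_mcmc(seed = 33))
  r <- dlt_risk(f, 1, dose_panel())
  expect_true(all(r >= 0 & r <= 1))
  expect_true(all(apply(r, 1L, function(x) all(diff(x) >= 0))))
  expect_error(dlt_risk(f, 1, numeric(0)), "empty")
  expect_error(dlt_risk(f, 1, c(5, 1)), "increasing")
  expect_error(dlt_risk(f, 9, 5), "unknown")

  # pinned parameters: risk at the reference dose is exactly 25%
  fp <- fit_bridge_model(cfg, toy_animal(), list(), quick_mcmc(seed = 34),
                         fix = list(gamma = rbind(c(-1.099, 0), c(-1.099, 0)),
                                    eps = c(1, 1)))
  rp <- dlt_risk(fp, 1, dose_panel())
  expect_true(all(abs(rp[, 4] - plogis(-1.099)) < 1e-12))
})

test_that("w_R = 1 isolates a subgroup from animal co-data", {
  cfg <- bridge_config()  # w_R = 1
  f0 <- fit_bridge_model(cfg, list(), list(), quick_mcmc(seed = 35),
                         prior_only = TRUE)
  f1 <- fit_bridge_model(cfg, toy_animal(), list(), quick_mcmc(seed = 36))
  r0 <- dlt_risk(f0, 1, dose_panel()); r1 <- dlt_risk(f1, 1, dose_panel())
  for (j in c(1L, 4L, 6L)) {
    se <- sqrt(mcse_mean(r0[, j])^2 + mcse_mean(r1[, j])^2)
    expect_lt(abs(mean(r0[, j]) - mean(r1[, j])), 4 * se)
  }
  # the predictive construction for a future subgroup shows the same isolation
  rm0 <- dlt_risk(f0, 2, dose_panel(), map = TRUE)
  rm1 <- dlt_risk(f1, 2, dose_panel(), map = TRUE)
  for (j in c(1L, 4L)) {
    se <- sqrt(mcse_mean(rm0[, j])^2 + mcse_mean(rm1[, j])^2)
    expect_lt(abs(mean(rm0[, j]) - mean(rm1[, j])), 4 * se)
  }
})

test_that("interval probabilities implement the boundary conventions", {
  mk <- function(v, doses = 1) structure(cbind(v), doses = doses,
                                         subgroup = 1L, class = "risk_samples")
  expect_equal(unlist(interval_probabilities(mk(rep(0.10, 100)))[, 2:4]),
               c(p_under = 1, p_target = 0, p_over = 0))
  # right-closed overdose interval: risk exactly at the cut counts as over
  expect_equal(unlist(interval_probabilities(mk(rep(0.33, 100)))[, 2:4]),
               c(p_under = 0, p_target = 0, p_over = 1))
  expect_equal(unlist(interval_probabilities(mk(rep(0.16, 100)))[, 2:4]),
               c(p_under = 0, p_target = 1, p_over = 0))
  set.seed(8)
  u <- interval_probabilities(mk(runif(2e5)))
  expect_equal(u$p_under, 0.16, tolerance = 0.01)
  expect_equal(u$p_target, 0.17, tolerance = 0.01)
  expect_equal(u$p_over, 0.67, tolerance = 0.01)
  expect_equal(u$p_under + u$p_target + u$p_over, 1, tolerance = 1e-12)
  expect_error(interval_probabilities(mk(rep(0.2, 10)), under_cut = 0.5,
                                      over_cut = 0.3), "under_cut")
})

test_that("risk summaries match an independent recomputation", {
  mk <- function(m) structure(m, doses = seq_len(ncol(m)), subgroup = 1L,
                              class = "risk_samples")
  s <- summarize_risk(mk(cbind(rep(0.4, 50))))
  expect_equal(s$mean, 0.4); expect_equal(s$median, 0.4); expect_equal(s$sd, 0)
  s2 <- summarize_risk(mk(cbind(c(0.1, 0.2, 0.3))))
  expect_equal(s2$mean, 0.2)

  cfg <- model_preset("A")
  f <- fit_bridge_model(cfg, toy_animal(), list(), quick_mcmc(seed = 37))
  r <- dlt_risk(f, 1, dose_panel())
  s3 <- summarize_risk(r)
  # second, independent statistics route
  for (j in seq_along(dose_panel())) {
    x <- sort(r[, j]); n <- length(x)
    expect_equal(s3$mean[j], sum(x) / n, tolerance = 1e-12)
    expect_equal(s3$sd[j], sqrt(sum((x - sum(x) / n)^2) / (n - 1)),
                 tolerance = 1e-9)
    expect_equal(s3$median[j], unname(quantile(x, 0.5)), tolerance = 1e-12)
    expect_true(s3$median[j] >= min(x) && s3$median[j] <= max(x))
  }
})

test_that("posterior concentrates on the truth at large n", {
  truth <- c(-0.7, 0.25)
  doses <- dose_panel()
  set.seed(55)
  p <- dlt_probability(truth[1], truth[2], 1, doses, 5)
  h <- human_trial(1, doses, n = rep(300L, 6), r = rbinom(6, 300, p))
  cfg <- bridge_config(n_subgroups = 1,
                       weights = matrix(c(0, 0, 0, 1), 1))
  f <- fit_bridge_model(cfg, list(), list(h),
                        mcmc_settings(2, 6000, 2000, seed = 56),
                        fix = list(eps = 1))
  expect_lt(abs(mean(f$draws[, "gamma1[1]"]) - truth[1]), 0.1)
  expect_lt(abs(mean(f$draws[, "gamma2[1]"]) - truth[2]), 0.1)
})

test_that("draws export to long format", {
  cfg <- model_preset("A")
  f <- fit_bridge_model(cfg, toy_animal(), list(), quick_mcmc(seed = 38))
  long <- draws_long(f)
  expect_equal(nrow(long), nrow(f$draws) * ncol(f$draws))
  expect_equal(mean(long$value[long$parameter == "m1"]),
               mean(f$draws[, "m1"]))
})
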