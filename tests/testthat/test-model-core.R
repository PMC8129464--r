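test_that("dlt_probability matches its closed form and handles errors", {
  # log term vanishes at the rescaled reference dose
  expect_equal(dlt_probability(0, 0, 1, dose = 5, d_ref = 5), 0.5)
  expect_equal(dlt_probability(-1.099, 0, 1, dose = 5, d_ref = 5),
               plogis(-1.099), tolerance = 1e-12)
  expect_equal(dlt_probability(-1.099, 0, 1, dose = 5, d_ref = 5), 0.25,
               tolerance = 1e-3)
  expect_equal(dlt_probability(-1.099, 0, 1, dose = 10, d_ref = 5),
               plogis(-1.099 + log(2)), tolerance = 1e-12)
  expect_equal(dlt_probability(-1.099, 0, 1, dose = 10, d_ref = 5), 0.400,
               tolerance = 1e-3)
  expect_error(dlt_probability(0, 0, 1, dose = -1, d_ref = 5), "dose")
  expect_error(dlt_probability(0, 0, 0, dose = 1, d_ref = 5), "scale")
  expect_error(dlt_probability(0, 0, 1, dose = 1, d_ref = 0), "d_ref")
})

test_that("dlt_probability is strictly increasing in dose", {
  set.seed(41)
  for (i in 1:25) {
    ic <- rnorm(1, -1, 1.5); ls <- rnorm(1, 0, 0.7); sc <- exp(rnorm(1, -0.5, 0.5))
    d <- sort(exp(runif(8, log(0.05), log(50))))
    p <- dlt_probability(ic, ls, sc, d, d_ref = 5)
    expect_true(all(diff(p) > 0))
    expect_true(all(p > 0 & p < 1))
  }
})

# independent term-by-term oracle for the joint log density, written from
# first principles (quadratic forms via solve/determinant, explicit
# truncation constants) rather than reusing the package helpers
oracle_logdens <- function(config, animal, human, pt) {
  bvn <- function(x, mu, s1, s2, r) {
    S <- matrix(c(s1^2, r * s1 * s2, r * s1 * s2, s2^2), 2)
    -log(2 * pi) - 0.5 * log(det(S)) -
      0.5 * drop(t(x - mu) %*% solve(S) %*% (x - mu))
  }
  hp <- config$hierarchy; K <- length(config$species)
  out <- dnorm(pt$m[1], hp$b1, hp$s1, TRUE) + dnorm(pt$m[2], hp$b2, hp$s2, TRUE) +
    dnorm(pt$muH[1], hp$b1, hp$s1, TRUE) + dnorm(pt$muH[2], hp$b2, hp$s2, TRUE)
  out <- out + sum(log(2) + dnorm(pt$tau, 0, hp$z, TRUE))
  out <- out + sum(log(2) + dnorm(pt$sigma, 0, hp$c_sigma, TRUE))
  out <- out + 3 * log(0.5)  # three U(-1,1) correlations
  for (k in seq_len(K))
    out <- out + dlnorm(pt$delta[k], config$translation$meanlog[k],
                        config$translation$sdlog[k], TRUE) +
      bvn(pt$muS[k, ], pt$m, pt$sigma[1], pt$sigma[2], pt$kappa)
  for (l in seq_len(config$n_subgroups)) {
    nu <- config$bridging$nu[l]
    out <- out + dnorm(pt$eps[l], 1, nu, TRUE) -
      log(pnorm(config$bridging$upper, 1, nu) -
            pnorm(config$bridging$lower, 1, nu))
    zl <- pt$z[l]
    dens <- if (zl <= K) bvn(pt$gamma[l, ], pt$muS[zl, ], pt$tau[1], pt$tau[2], pt$rho)
    else if (zl == K + 1) bvn(pt$gamma[l, ], pt$muH, pt$tau[3], pt$tau[4], pt$eta)
    else bvn(pt$gamma[l, ], config$nonex[[l]]$mean, config$nonex[[l]]$sd[1],
             config$nonex[[l]]$sd[2], config$nonex[[l]]$corr)
    out <- out + log(config$weights[l, zl]) + dens
  }
  for (i in seq_along(animal)) {
    st <- animal[[i]]; k <- match(st$species, config$species)
    p <- plogis(pt$theta[i, 1] +
                  exp(pt$theta[i, 2]) * log(pt$delta[k] * st$dose / hp$d_ref))
    out <- out + sum(dbinom(st$r, st$n, p, log = TRUE)) +
      bvn(pt$theta[i, ], pt$muS[k, ], pt$tau[1], pt$tau[2], pt$rho)
  }
  for (h in human) {
    l <- h$subgroup; keep <- h$n > 0
    p <- plogis(pt$gamma[l, 1] +
                  exp(pt$gamma[l, 2]) * log(pt$eps[l] * h$dose[keep] / hp$d_ref))
    out <- out + sum(dbinom(h$r[keep], h$n[keep], p, log = TRUE))
  }
  out
}

test_that("joint_log_density agrees with an independent summation oracle", {
  cfg <- model_preset("A")
  an <- toy_animal(); hu <- toy_human()
  set.seed(7)
  for (i in 1:10) {
    pt <- toy_point(cfg)
    pt$theta <- pt$theta + matrix(rnorm(4, 0, 0.5), 2)
    pt$gamma <- pt$gamma + matrix(rnorm(4, 0, 0.5), 2)
    pt$eps <- runif(2, 0.3, 1.7)
    pt$z <- c(sample(c(1L, 2L, 4L), 1), sample(c(1L, 2L, 3L, 4L), 1))
    expect_equal(joint_log_density(cfg, an, hu, pt),
                 oracle_logdens(cfg, an, hu, pt), tolerance = 1e-10)
  }
})

test_that("joint_log_density reductions, invariances and error handling", {
  cfg <- model_preset("A")
  pt <- toy_point(cfg)
  # empty data: priors only (equals the oracle's prior block)
  expect_equal(joint_log_density(cfg, list(), list(), pt),
               oracle_logdens(cfg, list(), list(), pt), tolerance = 1e-10)

  # a single Bernoulli non-event adds exactly log(1-p) on top of the
  # study-level random-effect density
  base <- joint_log_density(cfg, list(), list(), pt)
  st <- animal_study("s", "monkey", 10, 1L, 0L)
  pt1 <- pt; pt1$theta <- pt$theta[1, , drop = FALSE]
  p <- dlt_probability(pt1$theta[1, 1], pt1$theta[1, 2], pt$delta[2], 10, 5)
  re_term <- oracle_logdens(cfg, list(st), list(), pt1) -
    oracle_logdens(cfg, list(), list(), pt1) - log(1 - p)
  expect_equal(joint_log_density(cfg, list(st), list(), pt1),
               base + re_term + log(1 - p), tolerance = 1e-10)

  # permutation invariance over study order (swap rows consistently)
  an <- toy_animal(); hu <- toy_human()
  lp <- joint_log_density(cfg, an, hu, pt)
  pt_sw <- pt; pt_sw$theta <- pt$theta[2:1, , drop = FALSE]
  expect_equal(joint_log_density(cfg, an[2:1], hu, pt_sw), lp, tolerance = 1e-12)

  # boundary correlation: -Inf, not an exception
  pt_b <- pt; pt_b$rho <- 1
  expect_identical(joint_log_density(cfg, an, hu, pt_b), -Inf)
  pt_b <- pt; pt_b$kappa <- -1
  expect_identical(joint_log_density(cfg, an, hu, pt_b), -Inf)
  # eps outside the truncation interval: -Inf
  pt_b <- pt; pt_b$eps[1] <- 2.5
  expect_identical(joint_log_density(cfg, an, hu, pt_b), -Inf)

  # indicator out of range: domain error
  pt_b <- pt; pt_b$z[1] <- 5L
  expect_error(joint_log_density(cfg, an, hu, pt_b), "indicator")
})
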