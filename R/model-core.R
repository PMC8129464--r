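#' Two-parameter logistic dose-toxicity model
#'
#' Probability of a dose-limiting toxicity at a given dose under the
#' logistic model
#' \deqn{\mathrm{logit}(p) = \theta_1 + e^{\theta_2}\,
#'   \log(\mathrm{scale} \cdot d / d_{ref})}
#' where `scale` is the dose-rescaling parameter: the species translation
#' parameter delta for an animal study, or the subgroup bridging parameter
#' eps for a human trial.  The slope is parameterised on the log scale so
#' the curve is always strictly increasing in dose.
#'
#' @param intercept Intercept theta1 (log-odds of a DLT at the rescaled
#'   reference dose).
#' @param log_slope Log of the slope, theta2.
#' @param scale Positive dose-rescaling factor (delta or eps).
#' @param dose Positive dose, mg/kg.  Vectorised.
#' @param d_ref Positive reference dose, mg/kg.
#' @return DLT probability/ies in (0, 1).
#' @examples
#' dlt_probability(-1.099, 0, 1, dose = 5, d_ref = 5)  # ~0.25
#' @export
dlt_probability <- function(intercept, log_slope, scale, dose, d_ref) {
  if (any(dose <= 0)) stop("dose must be positive")
  if (any(scale <= 0)) stop("scale must be positive")
  if (any(d_ref <= 0)) stop("d_ref must be positive")
  stats::plogis(intercept + exp(log_slope) * log(scale * dose / d_ref))
}

# log Binomial(r | n, p) with p = plogis(lin), written in terms of the
# linear predictor for numerical stability at extreme lin.
binom_loglik_logit <- function(r, n, lin) {
  softplus <- ifelse(lin > 35, lin, log1p(exp(lin)))
  sum(lchoose(n, r) + r * lin - n * softplus)
}

# log bivariate normal density parameterised by sds and correlation
bvn_logpdf <- function(x, mean, sd1, sd2, corr) {
  if (sd1 <= 0 || sd2 <= 0 || abs(corr) >= 1) return(-Inf)
  a <- (x[1L] - mean[1L]) / sd1
  b <- (x[2L] - mean[2L]) / sd2
  -log(2 * pi) - log(sd1 * sd2) - 0.5 * log1p(-corr^2) -
    0.5 * (a^2 - 2 * corr * a * b + b^2) / (1 - corr^2)
}

half_normal_logpdf <- function(x, scale) {
  if (x <= 0) return(-Inf)
  log(2) + stats::dnorm(x, 0, scale, log = TRUE)
}

trunc_normal_logpdf <- function(x, mean, sd, lower, upper) {
  if (x <= lower || x >= upper) return(-Inf)
  stats::dnorm(x, mean, sd, log = TRUE) -
    log(stats::pnorm(upper, mean, sd) - stats::pnorm(lower, mean, sd))
}

#' A point in the parameter space of the hierarchical model
#'
#' Bundles one value of every model parameter, as used by
#' [joint_log_density()] and by the brute-force oracles in the test suite.
#' Matrices have one row per unit and columns (intercept, log-slope).
#'
#' @param theta M x 2 matrix of animal-study parameters (may have 0 rows).
#' @param muS K x 2 matrix of species population means.
#' @param m Length-2 supra-species mean vector.
#' @param muH Length-2 human-population mean vector.
#' @param gamma L x 2 matrix of subgroup parameters.
#' @param eps Length-L bridging parameters, each in (0, 2).
#' @param delta Length-K positive translation parameters.
#' @param tau Length-4 positive sds (tau1, tau2, tau3, tau4).
#' @param sigma Length-2 positive sds (sigma1, sigma2).
#' @param rho,kappa,eta Correlations in (-1, 1) of the Psi, Sigma and Phi
#'   covariance matrices.
#' @param z Length-L integer mixture-component indicators in 1..K+2
#'   (1..K: exchangeable with species k; K+1: human-only; K+2:
#'   non-exchangeable).
#' @return An object of class `parameter_point`.
#' @export
parameter_point <- function(theta, muS, m, muH, gamma, eps, delta,
                            tau, sigma, rho, kappa, eta, z) {
  theta <- rbind(theta)[, 1:2, drop = FALSE]
  muS <- if (is.null(muS) || length(muS) == 0L)
    matrix(0, 0L, 2L) else rbind(muS)[, 1:2, drop = FALSE]
  gamma <- rbind(gamma)[, 1:2, drop = FALSE]
  stopifnot(length(m) == 2L, length(muH) == 2L, length(tau) == 4L,
            length(sigma) == 2L, length(eps) == nrow(gamma),
            length(z) == nrow(gamma), length(delta) == nrow(muS))
  structure(list(theta = theta, muS = muS, m = as.numeric(m),
                 muH = as.numeric(muH), gamma = gamma,
                 eps = as.numeric(eps), delta = as.numeric(delta),
                 tau = as.numeric(tau), sigma = as.numeric(sigma),
                 rho = rho, kappa = kappa, eta = eta, z = as.integer(z)),
            class = "parameter_point")
}

#' Joint log density of data and parameters
#'
#' Log of the unnormalised joint density assembled from: binomial
#' likelihoods of every animal study and human subgroup, the study-level
#' and species-level random-effects densities, each subgroup's mixture
#' component density (selected by its indicator `z`) times the component's
#' prior weight, the hyperpriors on means, heterogeneity sds and
#' correlations, and the translation/bridging priors.  Used both as a
#' reference implementation for the compiled sampler and by the
#' grid-quadrature oracles.
#'
#' Out-of-support points (non-positive sds, correlations at +-1, eps
#' outside its truncation interval) give `-Inf`; an indicator outside
#' 1..K+2 is an error.
#'
#' @param config A [bridge_config()].
#' @param animal List of [animal_study()] (may be empty).
#' @param human List of [human_trial()] (may be empty; subgroups may also
#'   be present with all-zero counts).
#' @param point A [parameter_point()] conforming to `config`.
#' @return A scalar log density (possibly `-Inf`).
#' @export
joint_log_density <- function(config, animal = list(), human = list(), point) {
  stopifnot(inherits(config, "bridge_config"), inherits(point, "parameter_point"))
  K <- length(config$species); L <- config$n_subgroups
  hp <- config$hierarchy
  if (nrow(point$muS) != K || nrow(point$gamma) != L)
    stop("parameter point does not conform to the configuration")
  if (any(point$z < 1L | point$z > K + 2L))
    stop("mixture component indicator out of range 1..K+2")
  if (length(animal) && nrow(point$theta) != length(animal))
    stop("theta must have one row per animal study")

  lp <- 0
  # hyperpriors
  lp <- lp + stats::dnorm(point$m[1L], hp$b1, hp$s1, log = TRUE) +
    stats::dnorm(point$m[2L], hp$b2, hp$s2, log = TRUE) +
    stats::dnorm(point$muH[1L], hp$b1, hp$s1, log = TRUE) +
    stats::dnorm(point$muH[2L], hp$b2, hp$s2, log = TRUE)
  for (j in 1:4) lp <- lp + half_normal_logpdf(point$tau[j], hp$z[j])
  for (j in 1:2) lp <- lp + half_normal_logpdf(point$sigma[j], hp$c_sigma[j])
  for (r in c(point$rho, point$kappa, point$eta)) {
    if (abs(r) >= 1) return(-Inf)
    lp <- lp - log(2)
  }
  if (!is.finite(lp)) return(lp)

  # translation and bridging priors
  for (k in seq_len(K)) {
    if (point$delta[k] <= 0) return(-Inf)
    lp <- lp + stats::dlnorm(point$delta[k], config$translation$meanlog[k],
                             config$translation$sdlog[k], log = TRUE)
  }
  for (l in seq_len(L))
    lp <- lp + trunc_normal_logpdf(point$eps[l], 1, config$bridging$nu[l],
                                   config$bridging$lower, config$bridging$upper)
  if (!is.finite(lp)) return(lp)

  # species hierarchy
  for (k in seq_len(K))
    lp <- lp + bvn_logpdf(point$muS[k, ], point$m,
                          point$sigma[1L], point$sigma[2L], point$kappa)

  # animal studies: likelihood + study-level random effect
  for (i in seq_along(animal)) {
    st <- animal[[i]]
    k <- match(st$species, config$species)
    if (is.na(k)) stop("species '", st$species, "' not in the configured set")
    lin <- point$theta[i, 1L] +
      exp(point$theta[i, 2L]) * log(point$delta[k] * st$dose / hp$d_ref)
    lp <- lp + binom_loglik_logit(st$r, st$n, lin)
    lp <- lp + bvn_logpdf(point$theta[i, ], point$muS[k, ],
                          point$tau[1L], point$tau[2L], point$rho)
  }

  # subgroups: mixture component density (+ weight) and likelihood
  for (l in seq_len(L)) {
    zl <- point$z[l]
    w <- config$weights[l, zl]
    if (w <= 0) return(-Inf)
    dens <- if (zl <= K) {
      bvn_logpdf(point$gamma[l, ], point$muS[zl, ],
                 point$tau[1L], point$tau[2L], point$rho)
    } else if (zl == K + 1L) {
      bvn_logpdf(point$gamma[l, ], point$muH,
                 point$tau[3L], point$tau[4L], point$eta)
    } else {
      np <- config$nonex[[l]]
      bvn_logpdf(point$gamma[l, ], np$mean, np$sd[1L], np$sd[2L], np$corr)
    }
    lp <- lp + log(w) + dens
  }
  for (h in human) {
    l <- h$subgroup
    if (l < 1L || l > L) stop("subgroup index out of range")
    keep <- h$n > 0L
    if (!any(keep)) next
    lin <- point$gamma[l, 1L] +
      exp(point$gamma[l, 2L]) * log(point$eps[l] * h$dose[keep] / hp$d_ref)
    lp <- lp + binom_loglik_logit(h$r[keep], h$n[keep], lin)
  }
  lp
}
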