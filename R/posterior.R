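#' Posterior mixture-component probabilities for a subgroup
#'
#' Fraction of retained draws in which the subgroup's dose-toxicity
#' parameter vector was attributed to each exchangeability component
#' (one per animal species, the human-only population) or to the
#' non-exchangeable component.
#'
#' @param fit A [fit_bridge_model()] result.
#' @param subgroup Subgroup index included in the fit.
#' @return Named probability vector of length K+2 summing to 1.
#' @export
component_probabilities <- function(fit, subgroup) {
  stopifnot(inherits(fit, "bridge_fit"))
  if (subgroup < 1L || subgroup > fit$L) stop("unknown subgroup")
  z <- fit$z[, subgroup]
  K <- fit$K
  p <- vapply(seq_len(K + 2L), function(c) mean(z == c), numeric(1L))
  names(p) <- c(fit$config$species, "H", "R")
  p
}

# truncated-normal sampler via the inverse cdf
rtruncnorm <- function(n, mean, sd, lower, upper) {
  plo <- stats::pnorm(lower, mean, sd); phi <- stats::pnorm(upper, mean, sd)
  stats::qnorm(stats::runif(n, plo, phi), mean, sd)
}

# bivariate normal deviates (sd/sd/corr parameterisation), vectorised over
# per-draw means
rbvn <- function(n, mean1, mean2, sd1, sd2, corr) {
  z1 <- stats::rnorm(n); z2 <- stats::rnorm(n)
  x1 <- mean1 + sd1 * z1
  x2 <- mean2 + sd2 * (corr * z1 + sqrt(1 - corr^2) * z2)
  cbind(x1, x2)
}

#' Sampled DLT risks over a dose panel
#'
#' Per retained draw and per dose, the DLT probability
#' `dlt_probability(gamma1, gamma2, eps, dose, d_ref)` for a subgroup.
#' For a subgroup whose parameters were sampled in the fit (the usual
#' case; a not-yet-started trial can simply be included in the fit with no
#' observations) the subgroup's own draws are used.  With `map = TRUE`
#' fresh parameter values are instead generated per draw from the mixture
#' implied by that draw's hyperparameters and the subgroup's prior
#' weights, with the bridging parameter drawn from its prior -- the
#' meta-analytic predictive construction for a future subgroup outside
#' the fitted hierarchy.
#'
#' @param fit A [fit_bridge_model()] result.
#' @param subgroup Subgroup index (for `map = TRUE` it only selects the
#'   weight row and non-exchangeability prior).
#' @param doses Positive, strictly increasing dose panel, mg/kg.
#' @param map Use the predictive construction instead of the subgroup's
#'   sampled parameters.
#' @return An object of class `risk_samples`: a draws x doses matrix with
#'   attributes `doses` and `subgroup`.
#' @export
dlt_risk <- function(fit, subgroup, doses, map = FALSE) {
  stopifnot(inherits(fit, "bridge_fit"))
  if (length(doses) == 0L) stop("empty dose panel")
  if (any(doses <= 0)) stop("doses must be positive")
  if (is.unsorted(doses, strictly = TRUE)) stop("doses must be strictly increasing")
  if (subgroup < 1L || subgroup > fit$L) stop("unknown subgroup")
  d <- fit$draws; n <- nrow(d)
  dref <- fit$config$hierarchy$d_ref
  if (!map) {
    g1 <- d[, paste0("gamma1[", subgroup, "]")]
    g2 <- d[, paste0("gamma2[", subgroup, "]")]
    eps <- d[, paste0("eps[", subgroup, "]")]
  } else {
    K <- fit$K
    w <- fit$config$weights[subgroup, ]
    comp <- sample.int(K + 2L, n, replace = TRUE, prob = w)
    g1 <- numeric(n); g2 <- numeric(n)
    for (c in unique(comp)) {
      idx <- comp == c
      if (c <= K) {
        mu1 <- d[idx, paste0("muS1[", fit$config$species[c], "]")]
        mu2 <- d[idx, paste0("muS2[", fit$config$species[c], "]")]
        g <- rbvn(sum(idx), mu1, mu2, d[idx, "tau1"], d[idx, "tau2"],
                  d[idx, "rho"])
      } else if (c == K + 1L) {
        g <- rbvn(sum(idx), d[idx, "muH1"], d[idx, "muH2"],
                  d[idx, "tau3"], d[idx, "tau4"], d[idx, "eta"])
      } else {
        np <- fit$config$nonex[[subgroup]]
        g <- rbvn(sum(idx), np$mean[1L], np$mean[2L], np$sd[1L], np$sd[2L],
                  np$corr)
      }
      g1[idx] <- g[, 1L]; g2[idx] <- g[, 2L]
    }
    eps <- rtruncnorm(n, 1, fit$config$bridging$nu[subgroup],
                      fit$config$bridging$lower, fit$config$bridging$upper)
  }
  risks <- vapply(doses, function(dd) dlt_probability(g1, g2, eps, dd, dref),
                  numeric(n))
  risks <- matrix(risks, nrow = n,
                  dimnames = list(NULL, format(doses, trim = TRUE)))
  structure(risks, doses = as.numeric(doses), subgroup = subgroup,
            class = "risk_samples")
}

#' Under/target/over-dosing interval probabilities
#'
#' Per dose, the fraction of sampled DLT risks in the under-dosing
#' interval `[0, under_cut)`, the target interval `[under_cut, over_cut)`
#' and the overdosing interval `[over_cut, 1]`.  The three fractions sum
#' to one; the overdose interval is closed on the left, so a risk exactly
#' at `over_cut` counts as overdosing.
#'
#' @param risks A [dlt_risk()] result.
#' @param under_cut,over_cut Interval cut-points, `0 < under < over < 1`
#'   (defaults 0.16 and 0.33).
#' @return A data.frame with columns `dose`, `p_under`, `p_target`,
#'   `p_over`.
#' @export
interval_probabilities <- function(risks, under_cut = 0.16, over_cut = 0.33) {
  stopifnot(inherits(risks, "risk_samples"))
  if (nrow(risks) == 0L) stop("empty sample vector")
  if (!(under_cut > 0 && under_cut < over_cut && over_cut < 1))
    stop("need 0 < under_cut < over_cut < 1")
  p_under <- colMeans(risks < under_cut)
  p_over <- colMeans(risks >= over_cut)
  data.frame(dose = attr(risks, "doses"), p_under = p_under,
             p_target = 1 - p_under - p_over, p_over = p_over,
             row.names = NULL)
}

#' Posterior summaries of sampled DLT risks
#'
#' Mean, sd, median and central 95% interval per dose, computed on the
#' chains pooled together.  The (mean, sd) columns feed directly into
#' [ess_table()].
#'
#' @param risks A [dlt_risk()] result.
#' @return A data.frame with columns `dose`, `mean`, `sd`, `median`,
#'   `q2.5`, `q97.5`.
#' @export
summarize_risk <- function(risks) {
  stopifnot(inherits(risks, "risk_samples"))
  if (nrow(risks) == 0L) stop("empty sample vector")
  qs <- apply(risks, 2L, stats::quantile, probs = c(0.5, 0.025, 0.975),
              names = FALSE)
  data.frame(dose = attr(risks, "doses"),
             mean = colMeans(risks),
             sd = apply(risks, 2L, stats::sd),
             median = qs[1L, ], q2.5 = qs[2L, ], q97.5 = qs[3L, ],
             row.names = NULL)
}
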