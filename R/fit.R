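#' MCMC settings
#'
#' Defaults follow the reference analysis configuration: two parallel
#' chains of 15,000 iterations each with the first 5000 discarded as
#' burn-in.  The trial simulator substitutes its own reduced settings (see
#' [run_trial_pair()]).
#'
#' @param chains Number of chains (>= 1).
#' @param iterations Iterations per chain (post burn-in draws are
#'   `(iterations - burnin) / thin`).
#' @param burnin Burn-in iterations discarded per chain.
#' @param thin Thinning interval.
#' @param seed Optional integer seed.  When `NULL` the sampler consumes
#'   the current R random-number stream, which is what the trial simulator
#'   relies on for whole-trial reproducibility.
#' @return An object of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 2L, iterations = 15000L, burnin = 5000L,
                          thin = 1L, seed = NULL) {
  chains <- as.integer(chains); iterations <- as.integer(iterations)
  burnin <- as.integer(burnin); thin <- as.integer(thin)
  if (chains < 1L) stop("need at least one chain")
  if (burnin >= iterations) stop("burn-in must be smaller than iterations")
  if (thin < 1L) stop("thin must be >= 1")
  structure(list(chains = chains, iterations = iterations, burnin = burnin,
                 thin = thin, seed = seed), class = "mcmc_settings")
}

# coordinate layout of the compiled sampler, mirrored in R for naming
param_layout <- function(M, K, L, species = NULL) {
  nm <- character(0)
  if (M > 0) nm <- c(nm, as.vector(rbind(paste0("theta1[", 1:M, "]"),
                                         paste0("theta2[", 1:M, "]"))))
  sp <- if (is.null(species)) as.character(seq_len(K)) else species
  if (K > 0) nm <- c(nm, as.vector(rbind(paste0("muS1[", sp, "]"),
                                         paste0("muS2[", sp, "]"))))
  nm <- c(nm, "m1", "m2", "muH1", "muH2")
  if (L > 0) nm <- c(nm, as.vector(rbind(paste0("gamma1[", 1:L, "]"),
                                         paste0("gamma2[", 1:L, "]"))))
  if (L > 0) nm <- c(nm, paste0("eps[", 1:L, "]"))
  if (K > 0) nm <- c(nm, paste0("delta[", sp, "]"))
  c(nm, "tau1", "tau2", "tau3", "tau4", "sigma1", "sigma2",
    "rho", "kappa", "eta")
}

# build the length-npar fixed-value vector (NA = free) from a named list
build_fixed <- function(fix, M, K, L, species) {
  nm <- param_layout(M, K, L, species)
  fixed <- rep(NA_real_, length(nm))
  names(fixed) <- nm
  if (length(fix) == 0L) return(fixed)
  for (what in names(fix)) {
    val <- fix[[what]]
    if (what %in% c("theta", "muS", "gamma")) {
      mat <- rbind(val)
      pre <- switch(what, theta = "theta", muS = "muS", gamma = "gamma")
      ids <- switch(what, theta = as.character(seq_len(M)),
                    muS = species, gamma = as.character(seq_len(L)))
      for (i in seq_len(nrow(mat))) {
        fixed[paste0(pre, "1[", ids[i], "]")] <- mat[i, 1L]
        fixed[paste0(pre, "2[", ids[i], "]")] <- mat[i, 2L]
      }
    } else if (what == "m") {
      fixed[c("m1", "m2")] <- as.numeric(val)
    } else if (what == "muH") {
      fixed[c("muH1", "muH2")] <- as.numeric(val)
    } else if (what == "eps") {
      fixed[paste0("eps[", seq_along(val), "]")] <- as.numeric(val)
    } else if (what == "delta") {
      fixed[paste0("delta[", species, "]")] <- as.numeric(val)
    } else if (what == "tau") {
      fixed[paste0("tau", 1:4)] <- as.numeric(val)
    } else if (what == "sigma") {
      fixed[paste0("sigma", 1:2)] <- as.numeric(val)
    } else if (what %in% c("rho", "kappa", "eta")) {
      fixed[what] <- as.numeric(val)
    } else {
      stop("unknown parameter block in fix: ", what)
    }
  }
  fixed
}

#' Fit the hierarchical bridging model by MCMC
#'
#' Draws from the joint posterior implied by [joint_log_density()] using
#' the package's compiled adaptive Metropolis-within-Gibbs sampler.  With
#' no data (`prior_only = TRUE`) the draws come from the prior, which is
#' how meta-analytic predictive (MAP) priors for a not-yet-started trial
#' are formed.
#'
#' Split-R-hat is computed for every monitored parameter (subgroup
#' parameters gamma, bridging parameters eps, and the population means muH
#' and m); if any exceeds `rhat_threshold` the fit is flagged
#' `unconverged` (a warning status, not an error).
#'
#' @param config A [bridge_config()].
#' @param animal List of [animal_study()] objects (may be empty).
#' @param human List of [human_trial()] objects, at most one per subgroup
#'   (may be empty; subgroups without an entry contribute no likelihood).
#' @param settings An [mcmc_settings()].
#' @param fix Named list of parameter blocks to hold constant, e.g.
#'   `list(muS = rbind(c(-1, 0)), delta = 0.32, tau = c(.5, .25, .25, .125))`.
#'   Used for reduced-model oracle checks and for analysis model E
#'   (`eps` fixed at 1).
#' @param fix_z Optional integer vector (length L) of fixed component
#'   indicators; `0` or `NA` entries remain stochastic.
#' @param prior_only Set `TRUE` to sample with no data.
#' @param rhat_threshold Convergence flag threshold (default 1.05).
#' @return An object of class `bridge_fit` with elements `draws` (matrix
#'   of retained draws, pooled over chains, named columns), `z` (matrix of
#'   component indicators), `chain`, `rhat`, `unconverged`, `accept`, and
#'   the inputs.
#' @export
fit_bridge_model <- function(config, animal = list(), human = list(),
                             settings = mcmc_settings(), fix = list(),
                             fix_z = NULL, prior_only = FALSE,
                             rhat_threshold = 1.05) {
  stopifnot(inherits(config, "bridge_config"), inherits(settings, "mcmc_settings"))
  if (inherits(animal, "animal_study")) animal <- list(animal)
  if (inherits(human, "human_trial")) human <- list(human)
  K <- length(config$species); L <- config$n_subgroups
  M <- length(animal)

  for (st in animal) {
    if (!inherits(st, "animal_study")) stop("animal must be animal_study objects")
    if (!(st$species %in% config$species))
      stop("species '", st$species, "' not in the configured set")
  }
  subs <- vapply(human, function(h) h$subgroup, integer(1L))
  if (anyDuplicated(subs)) stop("at most one accumulated trial per subgroup")
  if (any(subs < 1L | subs > L)) stop("subgroup index out of range")
  have_data <- M > 0L || any(vapply(human, function(h) sum(h$n) > 0L, logical(1L)))
  if (!have_data && !prior_only)
    stop("no animal or human observations; use prior_only = TRUE to sample the prior")

  # flatten animal data
  asp <- integer(0); adose <- numeric(0); an <- numeric(0); ar <- numeric(0)
  aoff <- 0L
  for (st in animal) {
    asp <- c(asp, match(st$species, config$species) - 1L)
    adose <- c(adose, st$dose); an <- c(an, st$n); ar <- c(ar, st$r)
    aoff <- c(aoff, length(adose))
  }
  # flatten human data per subgroup (dose groups with n > 0 only)
  hdose <- numeric(0); hn <- numeric(0); hr <- numeric(0)
  hoff <- integer(L + 1L)
  for (l in seq_len(L)) {
    h <- human[match(l, subs)]
    if (length(h) && !is.na(match(l, subs))) {
      h <- h[[1L]]
      keep <- h$n > 0L
      hdose <- c(hdose, h$dose[keep]); hn <- c(hn, h$n[keep])
      hr <- c(hr, h$r[keep])
    }
    hoff[l + 1L] <- length(hdose)
  }

  hp <- config$hierarchy
  priors <- list(
    b1 = hp$b1, s1 = hp$s1, b2 = hp$b2, s2 = hp$s2, dref = hp$d_ref,
    z = hp$z, c_sigma = hp$c_sigma,
    delta_meanlog = as.numeric(config$translation$meanlog),
    delta_sdlog = as.numeric(config$translation$sdlog),
    nu = config$bridging$nu,
    eps_lo = config$bridging$lower, eps_hi = config$bridging$upper,
    m01 = vapply(config$nonex, function(p) p$mean[1L], numeric(1L)),
    m02 = vapply(config$nonex, function(p) p$mean[2L], numeric(1L)),
    r0sd1 = vapply(config$nonex, function(p) p$sd[1L], numeric(1L)),
    r0sd2 = vapply(config$nonex, function(p) p$sd[2L], numeric(1L)),
    r0corr = vapply(config$nonex, function(p) p$corr, numeric(1L)),
    weights = unname(config$weights))

  fixed <- build_fixed(fix, M, K, L, config$species)
  zfix <- rep(0L, L)
  if (!is.null(fix_z)) {
    fz <- as.integer(fix_z)
    fz[is.na(fz)] <- 0L
    if (any(fz < 0L | fz > K + 2L)) stop("fix_z entries must lie in 1..K+2")
    zfix[seq_along(fz)] <- fz
  }
  # degenerate mixture rows are deterministic: pin them so the indicator
  # draw reports the single admissible component even before burn-in
  for (l in seq_len(L)) {
    pos <- which(config$weights[l, ] > 0)
    if (length(pos) == 1L && zfix[l] == 0L) zfix[l] <- pos
  }

  control <- list(chains = settings$chains, iterations = settings$iterations,
                  burnin = settings$burnin, thin = settings$thin,
                  fixed = unname(fixed), zfix = zfix)

  if (!is.null(settings$seed)) set.seed(settings$seed)
  res <- .bridge_mcmc(list(M = M, K = K, L = L, asp = asp, adose = adose,
                           an = an, ar = ar, aoff = aoff, hdose = hdose,
                           hn = hn, hr = hr, hoff = hoff),
                      priors, control)

  colnames(res$draws) <- param_layout(M, K, L, config$species)
  if (L > 0) colnames(res$z) <- paste0("z[", seq_len(L), "]")

  monitored <- c(grep("^gamma", colnames(res$draws), value = TRUE),
                 grep("^eps", colnames(res$draws), value = TRUE),
                 "muH1", "muH2", "m1", "m2")
  monitored <- monitored[is.na(fixed[monitored])]
  rhat <- vapply(monitored, function(p) split_rhat(res$draws[, p], res$chain),
                 numeric(1L))
  unconverged <- any(rhat > rhat_threshold, na.rm = TRUE)

  structure(list(draws = res$draws, z = res$z, chain = res$chain,
                 accept = res$accept, rhat = rhat,
                 unconverged = unconverged, config = config,
                 animal = animal, human = human, settings = settings,
                 fixed = fixed, M = M, K = K, L = L),
            class = "bridge_fit")
}

#' @export
print.bridge_fit <- function(x, ...) {
  cat("Hierarchical bridging model fit:", nrow(x$draws), "retained draws,",
      x$settings$chains, "chain(s)\n")
  cat("  animal studies:", x$M, " subgroups:", x$L, "\n")
  cat("  max split-Rhat (monitored):",
      if (length(x$rhat)) round(max(x$rhat, na.rm = TRUE), 3) else NA,
      if (x$unconverged) " [UNCONVERGED]" else "", "\n")
  invisible(x)
}

#' Split-R-hat convergence diagnostic
#'
#' Potential scale-reduction factor computed after splitting every chain
#' in half, so it is informative even for a single chain.
#'
#' @param x Numeric vector of draws (all chains concatenated).
#' @param chain Integer vector assigning each draw to a chain.
#' @return Scalar R-hat (`NA` if the draws are degenerate).
#' @export
split_rhat <- function(x, chain) {
  pieces <- list()
  for (ch in unique(chain)) {
    xs <- x[chain == ch]
    h <- floor(length(xs) / 2L)
    if (h < 2L) return(NA_real_)
    pieces <- c(pieces, list(xs[1:h]), list(xs[(h + 1L):(2L * h)]))
  }
  m <- length(pieces); n <- length(pieces[[1L]])
  means <- vapply(pieces, mean, numeric(1L))
  vars <- vapply(pieces, stats::var, numeric(1L))
  W <- mean(vars)
  if (!is.finite(W) || W <= 0) return(NA_real_)
  B <- n * stats::var(means)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Monte-Carlo standard error of a posterior mean
#'
#' Batch-means estimate, robust to the autocorrelation of
#' Metropolis-within-Gibbs draws.  Used by the oracle-equivalence and
#' prior-recovery checks.
#'
#' @param x Numeric vector of (pooled) draws.
#' @param batches Number of batches (default 30).
#' @return Estimated standard error of `mean(x)`.
#' @export
mcse_mean <- function(x, batches = 30L) {
  n <- length(x)
  b <- max(2L, floor(n / batches))
  nb <- floor(n / b)
  bm <- vapply(seq_len(nb), function(i) mean(x[((i - 1L) * b + 1L):(i * b)]),
               numeric(1L))
  stats::sd(bm) / sqrt(nb)
}

#' Export posterior draws as a long-format table
#'
#' @param fit A [fit_bridge_model()] result.
#' @param file Optional path; when given, the table is written as
#'   tab-separated text.
#' @return A data.frame with columns `chain`, `iter`, `parameter`, `value`.
#' @export
draws_long <- function(fit, file = NULL) {
  stopifnot(inherits(fit, "bridge_fit"))
  d <- fit$draws
  iter <- stats::ave(seq_len(nrow(d)), fit$chain, FUN = seq_along)
  out <- data.frame(
    chain = rep(fit$chain, ncol(d)),
    iter = rep(iter, ncol(d)),
    parameter = rep(colnames(d), each = nrow(d)),
    value = as.vector(d))
  if (!is.null(file))
    utils::write.table(out, file, sep = "\t", row.names = FALSE, quote = FALSE)
  out
}
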