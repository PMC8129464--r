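#' Prior components of the bridging model
#'
#' Constructors for the prior blocks of [bridge_config()].
#'
#' `translation_prior()` holds, per animal species, the log-normal prior
#' LN(meanlog, sdlog^2) on the dose-translation parameter delta that maps
#' native animal doses onto an equivalent human dosing scale.  The defaults
#' are the rat and monkey priors used throughout the package's worked
#' examples: delta_rat ~ LN(-1.820, 0.323^2), delta_monkey ~
#' LN(-1.127, 0.273^2).
#'
#' `bridging_prior()` holds the truncated-normal prior
#' N(1, nu^2) I(lower <= eps <= upper) on each subgroup's bridging
#' parameter eps; with the default nu = 0.255 about 95% of the prior mass
#' lies in [0.5, 1.5].
#'
#' `hierarchy_priors()` holds the weakly-informative hyperpriors: normal
#' priors N(b1, s1^2), N(b2, s2^2) shared by the supra-species means
#' (m1, m2) and the human-population means (muH1, muH2); half-normal
#' scales z1..z4 for the between-study / between-subgroup heterogeneity
#' sds tau1..tau4 and c1, c2 for the supra-species sds sigma1, sigma2;
#' correlations rho, kappa, eta are uniform on (-1, 1).  `d_ref` is the
#' reference dose (mg/kg), conventionally the most probable human MTD.
#'
#' `nonex_prior()` is the bivariate-normal non-exchangeability prior
#' BVN(mean, R0) for a subgroup's (intercept, log-slope), parameterised by
#' component sds and a correlation.
#'
#' @param species Character vector of species labels.
#' @param meanlog,sdlog Log-normal parameters, recycled over species.
#' @param nu Prior sd of the bridging parameter (default 0.255).
#' @param lower,upper Truncation bounds (defaults 0 and 2; must bracket 1).
#' @param b1,s1,b2,s2 Normal prior means/sds for intercept and log-slope
#'   population means.
#' @param z Half-normal scales `c(z1, z2, z3, z4)` for tau1..tau4.
#' @param c_sigma Half-normal scales `c(c1, c2)` for sigma1, sigma2.
#' @param d_ref Reference dose, mg/kg (default 5).
#' @param mean,sd 2-vectors (intercept, log-slope) for `nonex_prior()`.
#' @param corr Correlation in (-1, 1) for `nonex_prior()`.
#' @name priors
NULL

#' @rdname priors
#' @export
translation_prior <- function(species = c("rat", "monkey"),
                              meanlog = c(-1.820, -1.127),
                              sdlog = c(0.323, 0.273)) {
  stopifnot(length(species) >= 1L, !anyDuplicated(species))
  meanlog <- rep_len(as.numeric(meanlog), length(species))
  sdlog <- rep_len(as.numeric(sdlog), length(species))
  if (any(sdlog <= 0)) stop("sdlog must be positive")
  structure(data.frame(species = as.character(species),
                       meanlog = meanlog, sdlog = sdlog),
            class = c("translation_prior", "data.frame"))
}

#' @rdname priors
#' @export
bridging_prior <- function(nu = 0.255, lower = 0, upper = 2) {
  nu <- as.numeric(nu)
  if (any(nu <= 0)) stop("nu must be positive")
  if (!(lower < 1 && 1 < upper)) stop("truncation bounds must bracket the prior mode 1")
  structure(list(nu = nu, lower = lower, upper = upper), class = "bridging_prior")
}

#' @rdname priors
#' @export
hierarchy_priors <- function(b1 = -1.099, s1 = 1.98, b2 = 0, s2 = 0.99,
                             z = c(0.5, 0.25, 0.25, 0.125),
                             c_sigma = c(1, 0.5), d_ref = 5) {
  stopifnot(length(z) == 4L, length(c_sigma) == 2L)
  if (any(c(s1, s2, z, c_sigma) <= 0)) stop("all prior scales must be positive")
  if (d_ref <= 0) stop("d_ref must be positive")
  structure(list(b1 = b1, s1 = s1, b2 = b2, s2 = s2,
                 z = as.numeric(z), c_sigma = as.numeric(c_sigma),
                 d_ref = as.numeric(d_ref)),
            class = "hierarchy_priors")
}

#' @rdname priors
#' @export
nonex_prior <- function(mean = c(-1.099, 0), sd = c(2, 1), corr = 0) {
  stopifnot(length(mean) == 2L, length(sd) == 2L, length(corr) == 1L)
  if (any(sd <= 0)) stop("sds must be positive")
  if (abs(corr) >= 1) stop("correlation must lie in (-1, 1)")
  structure(list(mean = as.numeric(mean), sd = as.numeric(sd),
                 corr = as.numeric(corr)),
            class = "nonex_prior")
}

#' Exchangeability / non-exchangeability weights
#'
#' Builds the L x (K+2) matrix of prior mixture weights: one column per
#' animal species, then the human-only exchangeability column `"H"`, then
#' the robust non-exchangeability column `"R"`.  Rows must sum to 1.
#'
#' @param ... One numeric vector of length K+2 per subgroup.
#' @param species Character vector of species labels (column names).
#' @return A numeric matrix with one row per subgroup.
#' @examples
#' exch_weights(c(0.2, 0.6, 0, 0.2), c(0.1, 0.5, 0.2, 0.2))
#' @export
exch_weights <- function(..., species = c("rat", "monkey")) {
  rows <- list(...)
  K <- length(species)
  w <- do.call(rbind, lapply(rows, as.numeric))
  if (ncol(w) != K + 2L)
    stop("each weight vector must have length K+2 = ", K + 2L)
  if (any(w < 0) || any(w > 1)) stop("weights must lie in [0, 1]")
  if (any(abs(rowSums(w) - 1) > 1e-12)) stop("weights must sum to 1 per subgroup")
  colnames(w) <- c(species, "H", "R")
  w
}

#' Full model configuration
#'
#' Bundles every prior block, the mixture weights and bookkeeping needed to
#' fit the hierarchical bridging model.  Use [model_preset()] for the
#' standard analysis-model presets A-E.
#'
#' @param species Character vector of animal species labels (may be empty
#'   for human-only analyses).
#' @param n_subgroups Number of human subgroups L (>= 1; trials not yet
#'   started are simply subgroups with no observations).
#' @param weights L x (K+2) matrix as from [exch_weights()].
#' @param translation [translation_prior()] covering `species`.
#' @param bridging [bridging_prior()]; `nu` is recycled across subgroups.
#' @param hierarchy [hierarchy_priors()].
#' @param nonex A single [nonex_prior()] (recycled) or a list of length L.
#' @param preset Label in `c("custom", "A", "B", "C", "D", "E")`, purely
#'   informative here; see [model_preset()].
#' @param pool_human If `TRUE` the trial simulator pools all human data
#'   into subgroup 1 with the bridging parameter fixed at 1 (analysis
#'   model E).
#'
#' @return An object of class `bridge_config`.
#' @export
bridge_config <- function(species = c("rat", "monkey"),
                          n_subgroups = 2L,
                          weights = NULL,
                          translation = translation_prior(species),
                          bridging = bridging_prior(),
                          hierarchy = hierarchy_priors(),
                          nonex = nonex_prior(),
                          preset = "custom",
                          pool_human = FALSE) {
  K <- length(species); L <- as.integer(n_subgroups)
  if (L < 1L) stop("need at least one human subgroup")
  if (is.null(weights)) {
    w <- c(rep(0, K), 0, 1)  # robust default: non-exchangeable
    weights <- matrix(rep(w, each = L), nrow = L)
    colnames(weights) <- c(species, "H", "R")
  }
  weights <- as.matrix(weights)
  if (nrow(weights) != L || ncol(weights) != K + 2L)
    stop("weights must be an L x (K+2) matrix")
  if (any(weights < 0 | weights > 1) || any(abs(rowSums(weights) - 1) > 1e-12))
    stop("weights must lie in [0,1] and sum to 1 per subgroup")
  if (K > 0L && !all(species %in% translation$species))
    stop("translation prior must cover every configured species")
  nu <- rep_len(bridging$nu, L)
  if (inherits(nonex, "nonex_prior")) nonex <- rep(list(nonex), L)
  if (length(nonex) != L) stop("nonex must supply one prior per subgroup")
  structure(
    list(species = as.character(species), n_subgroups = L,
         weights = weights,
         translation = translation[match(species, translation$species), ,
                                   drop = FALSE],
         bridging = bridging_prior(nu, bridging$lower, bridging$upper),
         hierarchy = hierarchy, nonex = nonex,
         preset = preset, pool_human = isTRUE(pool_human)),
    class = "bridge_config")
}

#' Analysis-model presets
#'
#' The five analysis models compared in the operating-characteristics
#' study, as configurations for two sequential trials T1 (subgroup 1) and
#' T2 (subgroup 2) over the rat + monkey co-data:
#'
#' * **A** - the full bridging model: T1 weights (rat 0.2, monkey 0.6,
#'   H 0, R 0.2); T2 weights (0.1, 0.5, 0.2, 0.2), leveraging animal data
#'   and the completed T1 data.
#' * **B** - discards animal data, human vectors fully exchangeable
#'   (w_H = 1).
#' * **C** - analyses each trial separately with no co-data (w_R = 1).
#' * **D** - animal data only, no borrowing across human subgroups
#'   (rat 0.2, monkey 0.6, R 0.2 for each trial analysed on its own).
#' * **E** - no co-data for T1; T2 pools the T1 observations into a single
#'   subgroup with the bridging parameter fixed at 1.
#'
#' @param preset One of `"A"`, `"B"`, `"C"`, `"D"`, `"E"`.
#' @param species Species labels (default rat + monkey).
#' @param ... Passed on to [bridge_config()] (e.g. `hierarchy`).
#' @return A `bridge_config`.
#' @export
model_preset <- function(preset = c("A", "B", "C", "D", "E"),
                         species = c("rat", "monkey"), ...) {
  preset <- match.arg(preset)
  K <- length(species)
  zero <- rep(0, K)
  w <- switch(preset,
    A = rbind(c(0.2, 0.6, 0, 0.2), c(0.1, 0.5, 0.2, 0.2)),
    B = rbind(c(zero, 1, 0), c(zero, 1, 0)),
    C = rbind(c(zero, 0, 1), c(zero, 0, 1)),
    D = rbind(c(0.2, 0.6, 0, 0.2), c(0.2, 0.6, 0, 0.2)),
    E = rbind(c(zero, 0, 1), c(zero, 0, 1)))
  if (preset %in% c("A", "D") && K != 2L)
    stop("presets A and D assume the two-species (rat, monkey) co-data")
  colnames(w) <- c(species, "H", "R")
  bridge_config(species = species, n_subgroups = 2L, weights = w,
                preset = preset, pool_human = (preset == "E"), ...)
}

#' @export
print.bridge_config <- function(x, ...) {
  cat("Bridging model configuration (preset ", x$preset, ")\n", sep = "")
  cat("  species:", if (length(x$species)) paste(x$species, collapse = ", ")
      else "(none)", "\n")
  cat("  subgroups:", x$n_subgroups, " d_ref:", x$hierarchy$d_ref, "mg/kg\n")
  cat("  mixture weights:\n")
  print(x$weights)
  invisible(x)
}

#' Serialise a configuration to JSON
#'
#' All defaults are expressible and overridable through the JSON form, so a
#' configuration can live alongside the trial protocol.
#'
#' @param config A [bridge_config()].
#' @param file Path to write to / read from.
#' @return `read_config()` returns a `bridge_config`.
#' @export
write_config <- function(config, file) {
  stopifnot(inherits(config, "bridge_config"))
  obj <- list(
    species = config$species,
    n_subgroups = config$n_subgroups,
    weights = unname(apply(config$weights, 1L, as.numeric, simplify = FALSE)),
    translation = list(species = config$translation$species,
                       meanlog = config$translation$meanlog,
                       sdlog = config$translation$sdlog),
    bridging = list(nu = config$bridging$nu, lower = config$bridging$lower,
                    upper = config$bridging$upper),
    hierarchy = unclass(config$hierarchy),
    nonex = lapply(config$nonex, unclass),
    preset = config$preset,
    pool_human = config$pool_human)
  jsonlite::write_json(obj, file, auto_unbox = TRUE, digits = NA)
  invisible(file)
}

#' @rdname write_config
#' @export
read_config <- function(file) {
  obj <- jsonlite::read_json(file, simplifyVector = TRUE)
  w <- obj$weights
  w <- if (is.matrix(w)) w else do.call(rbind, lapply(w, as.numeric))
  colnames(w) <- c(obj$species, "H", "R")
  nonex <- obj$nonex
  if (is.data.frame(nonex))
    nonex <- lapply(seq_len(nrow(nonex)), function(i)
      nonex_prior(unlist(nonex$mean[i]), unlist(nonex$sd[i]), nonex$corr[i]))
  else nonex <- lapply(nonex, function(p) nonex_prior(p$mean, p$sd, p$corr))
  bridge_config(
    species = obj$species, n_subgroups = obj$n_subgroups, weights = w,
    translation = translation_prior(obj$translation$species,
                                    obj$translation$meanlog,
                                    obj$translation$sdlog),
    bridging = bridging_prior(obj$bridging$nu, obj$bridging$lower,
                              obj$bridging$upper),
    hierarchy = hierarchy_priors(obj$hierarchy$b1, obj$hierarchy$s1,
                                 obj$hierarchy$b2, obj$hierarchy$s2,
                                 obj$hierarchy$z, obj$hierarchy$c_sigma,
                                 obj$hierarchy$d_ref),
    nonex = nonex, preset = obj$preset, pool_human = isTRUE(obj$pool_human))
}
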