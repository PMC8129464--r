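#' Escalation configuration
#'
#' Tuning constants of the trial-conduct rules: cohort structure, the
#' overdose-control criterion (the posterior probability that a dose's
#' DLT risk reaches `overdose_cut` must not exceed `feasibility`), the
#' starting-dose rule for a bridging trial (highest dose whose
#' probability of under-dosing exceeds `start_confidence`), the target
#' DLT risk for MTD declaration, and the no-skipping constraint.
#'
#' @param cohort_size Patients per cohort (default 3).
#' @param max_patients Maximum sample size; must be a multiple of
#'   `cohort_size` (default 24).
#' @param overdose_cut Overdose risk threshold (default 0.33).
#' @param feasibility Maximum allowed `P(p >= overdose_cut)` (default 0.25).
#' @param start_under_cut Under-dosing threshold of the starting rule
#'   (default 0.16).
#' @param start_confidence Required `P(p < start_under_cut)` (default 0.85).
#' @param target_risk Target DLT risk defining the MTD (default 0.25).
#' @param no_skipping Forbid skipping an untried dose during escalation
#'   (default `TRUE`).
#' @return An object of class `escalation_config`.
#' @export
escalation_config <- function(cohort_size = 3L, max_patients = 24L,
                              overdose_cut = 0.33, feasibility = 0.25,
                              start_under_cut = 0.16, start_confidence = 0.85,
                              target_risk = 0.25, no_skipping = TRUE) {
  cohort_size <- as.integer(cohort_size); max_patients <- as.integer(max_patients)
  if (cohort_size < 1L) stop("cohort_size must be >= 1")
  if (max_patients %% cohort_size != 0L)
    stop("max_patients must be a multiple of cohort_size")
  if (!(feasibility > 0 && feasibility < 1)) stop("feasibility must be in (0,1)")
  if (!(start_confidence > 0 && start_confidence < 1))
    stop("start_confidence must be in (0,1)")
  structure(list(cohort_size = cohort_size, max_patients = max_patients,
                 overdose_cut = overdose_cut, feasibility = feasibility,
                 start_under_cut = start_under_cut,
                 start_confidence = start_confidence,
                 target_risk = target_risk, no_skipping = isTRUE(no_skipping)),
            class = "escalation_config")
}

#' Trial state during escalation
#'
#' Book-keeping for one adaptive trial: the dose panel, patients and DLTs
#' accrued per dose, the highest dose administered so far, the cohort
#' counter, and the stopping flag.
#'
#' @param doses Strictly increasing dose panel, mg/kg.
#' @param n,r Optional accrued counts per dose (default all zero).
#' @return An object of class `trial_state`.
#' @export
trial_state <- function(doses, n = NULL, r = NULL) {
  doses <- as.numeric(doses)
  if (any(doses <= 0) || is.unsorted(doses, strictly = TRUE))
    stop("doses must be positive and strictly increasing")
  J <- length(doses)
  if (is.null(n)) n <- integer(J)
  if (is.null(r)) r <- integer(J)
  n <- as.integer(n); r <- as.integer(r)
  if (length(n) != J || length(r) != J || any(r > n) || any(r < 0L) || any(n < 0L))
    stop("inconsistent accrual counts")
  structure(list(doses = doses, n = n, r = r,
                 highest_given = if (any(n > 0L)) max(which(n > 0L)) else 0L,
                 cohort = 0L, stopped = FALSE,
                 stop_reason = NA_character_),
            class = "trial_state")
}

record_cohort <- function(state, dose_index, n_new, r_new) {
  state$n[dose_index] <- state$n[dose_index] + as.integer(n_new)
  state$r[dose_index] <- state$r[dose_index] + as.integer(r_new)
  state$highest_given <- max(state$highest_given, dose_index)
  state
}

check_probs <- function(p, J) {
  if (length(p) != J) stop("need one probability per panel dose")
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("probabilities must lie in [0, 1]")
  invisible(p)
}

#' Starting dose for a bridging trial
#'
#' The highest dose whose probability of under-dosing,
#' `P(p < start_under_cut | co-data)`, exceeds `start_confidence`;
#' `NA` if no dose qualifies (the trial should then not be started).
#'
#' @param under_probs Per-dose `P(p < start_under_cut)` from the co-data
#'   fit ([interval_probabilities()] column `p_under`).
#' @param cfg An [escalation_config()].
#' @return Dose index, or `NA_integer_` if no dose qualifies.
#' @export
starting_dose <- function(under_probs, cfg = escalation_config()) {
  check_probs(under_probs, length(under_probs))
  ok <- which(under_probs > cfg$start_confidence)
  if (length(ok) == 0L) NA_integer_ else max(ok)
}

#' Interim dose recommendation with overdose control
#'
#' The candidate dose is the highest panel dose whose posterior overdose
#' probability `P(p >= overdose_cut)` does not exceed `feasibility`.
#' Under the no-skipping constraint the candidate is capped at one level
#' above the highest dose administered so far.  De-escalation below the
#' current dose is permitted.  If no dose -- including the lowest --
#' satisfies the overdose constraint, `NA` is returned: the trial stops
#' for safety.
#'
#' @param over_probs Per-dose `P(p >= overdose_cut)`.
#' @param state A [trial_state()].
#' @param cfg An [escalation_config()].
#' @return Dose index to give the next cohort, or `NA_integer_` (stop for
#'   safety).
#' @export
recommend_next_dose <- function(over_probs, state, cfg = escalation_config()) {
  stopifnot(inherits(state, "trial_state"))
  if (state$stopped) stop("trial already stopped")
  check_probs(over_probs, length(state$doses))
  ok <- which(over_probs <= cfg$feasibility)
  if (length(ok) == 0L) return(NA_integer_)
  cand <- max(ok)
  if (cfg$no_skipping) cand <- min(cand, state$highest_given + 1L)
  cand
}

#' Declare the maximum tolerated dose
#'
#' On completion of a trial (all `max_patients` treated), the MTD is the
#' administered dose that satisfies the overdose criterion and whose
#' posterior median DLT risk is closest to `target_risk`; ties are broken
#' toward the lower dose.  Returns `NA` for an incomplete trial or when
#' no administered dose is eligible.
#'
#' @param medians Per-dose posterior median DLT risks.
#' @param over_probs Per-dose `P(p >= overdose_cut)`.
#' @param state A [trial_state()] carrying the final accrual.
#' @param cfg An [escalation_config()].
#' @return Dose index of the declared MTD, or `NA_integer_`.
#' @export
declare_mtd <- function(medians, over_probs, state, cfg = escalation_config()) {
  stopifnot(inherits(state, "trial_state"))
  check_probs(over_probs, length(state$doses))
  if (length(medians) != length(state$doses))
    stop("need one median per panel dose")
  if (sum(state$n) < cfg$max_patients) return(NA_integer_)
  eligible <- which(state$n > 0L & over_probs <= cfg$feasibility)
  if (length(eligible) == 0L) return(NA_integer_)
  dist <- abs(medians[eligible] - cfg$target_risk)
  eligible[which.min(dist)]  # which.min takes the first, i.e. lowest dose
}
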