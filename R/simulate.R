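#' Standard dose panel and truth scenarios
#'
#' `dose_panel()` returns the six-dose human panel \{0.1, 0.5, 1, 5, 10,
#' 20\} mg/kg shared by both regions.  `toxicity_scenarios()` returns the
#' six truth scenarios of the operating-characteristics study: per region
#' a vector of true DLT probabilities over the panel, and the index of the
#' true MTD (the dose whose truth is closest to the 25% target).
#' Scenario 1 has identical risks across regions; scenarios 2-4
#' similar-but-shifted risks; scenario 5 an overdosed lowest dose in both
#' regions; scenario 6 an incorrect bridging assumption (divergent
#' regions).
#'
#' @param id Optional scenario id 1-6; omitted returns the full list.
#' @return `toxicity_scenarios()`: a list (or single element) with
#'   components `T1`, `T2`, `true_mtd` (length-2 index vector) and `id`.
#' @export
dose_panel <- function() c(0.1, 0.5, 1, 5, 10, 20)

#' @rdname dose_panel
#' @export
toxicity_scenarios <- function(id = NULL) {
  sc <- list(
    list(id = 1L, T1 = c(0.01, 0.03, 0.10, 0.25, 0.34, 0.47),
         T2 = c(0.01, 0.03, 0.10, 0.25, 0.34, 0.47), true_mtd = c(4L, 4L)),
    list(id = 2L, T1 = c(0.01, 0.03, 0.10, 0.25, 0.34, 0.47),
         T2 = c(0.05, 0.12, 0.25, 0.37, 0.50, 0.60), true_mtd = c(4L, 3L)),
    list(id = 3L, T1 = c(0.01, 0.03, 0.10, 0.25, 0.34, 0.47),
         T2 = c(0.01, 0.03, 0.07, 0.15, 0.25, 0.37), true_mtd = c(4L, 5L)),
    list(id = 4L, T1 = c(0.01, 0.03, 0.05, 0.08, 0.15, 0.25),
         T2 = c(0.02, 0.05, 0.07, 0.12, 0.25, 0.36), true_mtd = c(6L, 5L)),
    list(id = 5L, T1 = c(0.25, 0.34, 0.47, 0.55, 0.65, 0.75),
         T2 = c(0.40, 0.50, 0.60, 0.70, 0.80, 0.90), true_mtd = c(1L, 1L)),
    list(id = 6L, T1 = c(0.01, 0.03, 0.05, 0.08, 0.15, 0.25),
         T2 = c(0.10, 0.25, 0.36, 0.50, 0.60, 0.68), true_mtd = c(6L, 2L)))
  sc <- lapply(sc, function(s) structure(s, class = "toxicity_scenario"))
  if (is.null(id)) sc else sc[[id]]
}

#' Simulate a cohort's DLT outcomes
#'
#' @param true_prob True DLT probability at the administered dose.
#' @param cohort_size Number of patients in the cohort.
#' @param seed Optional seed; by default the current RNG stream is used.
#' @return DLT count in `0..cohort_size`.
#' @export
simulate_cohort_outcome <- function(true_prob, cohort_size, seed = NULL) {
  stopifnot(true_prob >= 0, true_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  stats::rbinom(1L, as.integer(cohort_size), true_prob)
}

#' Reduced MCMC settings for in-simulation interim analyses
#'
#' One chain of 6000 iterations (1500 burn-in): a compute-budget choice
#' for the many interim refits of an operating-characteristics study,
#' sized so the split-R-hat flag (and hence the retry/abort path) trips
#' rarely; the reference 2 x 15000 / 5000 configuration of
#' [mcmc_settings()] remains available for stand-alone analyses.
#' @export
sim_mcmc_settings <- function() mcmc_settings(chains = 1L, iterations = 6000L,
                                              burnin = 1500L)

# fit, retrying once with doubled iterations if the convergence flag
# trips; NULL signals an aborted (still-unconverged) analysis
fit_with_retry <- function(config, animal, human, settings, fix = list()) {
  fit <- fit_bridge_model(config, animal, human, settings, fix = fix)
  if (!fit$unconverged) return(fit)
  settings2 <- mcmc_settings(settings$chains, 2L * settings$iterations,
                             2L * settings$burnin, settings$thin)
  fit <- fit_bridge_model(config, animal, human, settings2, fix = fix)
  if (fit$unconverged) NULL else fit
}

# one adaptive trial driven by interim refits.
# codata: list(animal = ..., human = list of completed human_trial objects)
# pool: analysis model E's pooled-subgroup mode (gamma shared, eps fixed)
run_escalation <- function(truth, doses, subgroup, config, animal,
                           other_human, esc, mcmc, start_index,
                           fix = list()) {
  state <- trial_state(doses)
  trace <- data.frame()
  current <- as.integer(start_index)
  mtd <- NA_integer_; aborted <- FALSE
  analysis_subgroup <- if (config$pool_human) 1L else subgroup

  repeat {
    dlts <- simulate_cohort_outcome(truth[current], esc$cohort_size)
    state <- record_cohort(state, current, esc$cohort_size, dlts)
    state$cohort <- state$cohort + 1L

    if (config$pool_human && length(other_human)) {
      # pool all human observations into a single subgroup
      pooled_n <- state$n; pooled_r <- state$r
      for (h in other_human) { pooled_n <- pooled_n + h$n; pooled_r <- pooled_r + h$r }
      hum <- list(human_trial(1L, doses, pooled_n, pooled_r))
    } else {
      hum <- c(other_human, list(human_trial(subgroup, doses, state$n, state$r)))
    }
    fit <- fit_with_retry(config, animal, hum, mcmc, fix = fix)
    if (is.null(fit)) { aborted <- TRUE; decision <- "abort"; }
    else {
      risks <- dlt_risk(fit, analysis_subgroup, doses)
      ip <- interval_probabilities(risks, esc$start_under_cut, esc$overdose_cut)
      if (sum(state$n) >= esc$max_patients) {
        med <- summarize_risk(risks)$median
        mtd <- declare_mtd(med, ip$p_over, state, esc)
        decision <- if (is.na(mtd)) "complete:none" else paste0("declare:", mtd)
      } else {
        rec <- recommend_next_dose(ip$p_over, state, esc)
        if (is.na(rec)) {
          state$stopped <- TRUE; state$stop_reason <- "safety"
          decision <- "stop:safety"
        } else decision <- paste0("next:", rec)
      }
    }
    trace <- rbind(trace, data.frame(
      cohort = state$cohort, dose_index = current, dose = doses[current],
      n = esc$cohort_size, dlts = dlts, decision = decision,
      stringsAsFactors = FALSE))
    if (aborted || state$stopped || sum(state$n) >= esc$max_patients) break
    current <- rec
  }

  structure(list(region = subgroup, doses = doses, n = state$n, r = state$r,
                 stopped = state$stopped, stop_reason = state$stop_reason,
                 mtd = mtd, aborted = aborted, trace = trace),
            class = "trial_result")
}

# an unstarted trial (starting rule admitted no dose): stopped at cohort 0
unstarted_trial <- function(truth, doses, subgroup) {
  structure(list(region = subgroup, doses = doses, n = integer(length(doses)),
                 r = integer(length(doses)), stopped = TRUE,
                 stop_reason = "no safe starting dose", mtd = NA_integer_,
                 aborted = FALSE, trace = data.frame()),
            class = "trial_result")
}

#' Simulate a pair of sequential bridging trials
#'
#' Runs trial T1 (region 1) to completion or safety stop, then trial T2
#' (region 2), analysing each interim with the co-data prescribed by the
#' analysis-model preset:
#'
#' * **A** - animal data throughout; T2 additionally leverages the
#'   completed T1 data and starts at the highest dose passing the
#'   starting rule given animal + T1 co-data.
#' * **B** - human data only, fully exchangeable subgroups; T2 starts by
#'   the rule given T1 data.
#' * **C** - no co-data; T2 starts at the lowest dose.
#' * **D** - animal data only, each trial analysed separately; T2 starts
#'   at the lowest dose.
#' * **E** - T1 without co-data; T2 pools the T1 observations into one
#'   subgroup with the bridging parameter fixed at 1, and starts by the
#'   rule given T1 data.
#'
#' T1 always starts at the lowest dose.  The subgroup-1 mixture weights
#' are fixed throughout: data accruing in T2 never re-weight the T1
#' analysis, which is final before T2 begins.
#'
#' @param scenario A [toxicity_scenarios()] element (or its id 1-6).
#' @param preset Analysis model `"A"`..`"E"`.
#' @param animal Animal co-data (default [default_animal_fixture()]);
#'   ignored by presets B, C and E.
#' @param esc An [escalation_config()].
#' @param mcmc Interim [mcmc_settings()] (default [sim_mcmc_settings()]).
#' @param seed Optional seed for the whole pair (trial outcomes and all
#'   interim fits); identical seeds give identical pairs.
#' @param doses Dose panel (default [dose_panel()]).
#' @return List with elements `T1` and `T2` (class `trial_result`),
#'   `preset` and `scenario_id`.
#' @export
run_trial_pair <- function(scenario, preset = "A",
                           animal = default_animal_fixture(),
                           esc = escalation_config(),
                           mcmc = sim_mcmc_settings(), seed = NULL,
                           doses = dose_panel()) {
  if (is.numeric(scenario)) scenario <- toxicity_scenarios(scenario)
  preset <- match.arg(preset, c("A", "B", "C", "D", "E"))
  if (!is.null(seed)) set.seed(seed)

  config <- model_preset(preset)
  use_animal <- preset %in% c("A", "D")
  anim <- if (use_animal) animal else list()

  # T1: always from the lowest dose; under E (and C) no co-data
  cfg_T1 <- if (preset == "E") model_preset("C") else config
  res1 <- run_escalation(scenario$T1, doses, 1L, cfg_T1, anim,
                         other_human = list(), esc, mcmc, start_index = 1L)
  t1_data <- human_trial(1L, doses, res1$n, res1$r)

  # T2 starting dose
  if (preset %in% c("C", "D")) {
    start2 <- 1L
  } else {
    if (preset == "E") {
      cfg_pool <- bridge_config(species = config$species, n_subgroups = 1L,
                                weights = matrix(c(0, 0, 0, 1), 1L,
                                                 dimnames = list(NULL, NULL)),
                                preset = "E", pool_human = TRUE)
      fit0 <- fit_with_retry(cfg_pool, list(),
                             list(human_trial(1L, doses, res1$n, res1$r)),
                             mcmc, fix = list(eps = 1))
      sg0 <- 1L; cfg0 <- cfg_pool
    } else {
      fit0 <- fit_with_retry(config, anim, list(t1_data), mcmc)
      sg0 <- 2L; cfg0 <- config
    }
    if (is.null(fit0)) return(list(T1 = res1,
                                   T2 = unstarted_trial(scenario$T2, doses, 2L),
                                   preset = preset, scenario_id = scenario$id))
    ip0 <- interval_probabilities(dlt_risk(fit0, sg0, doses),
                                  esc$start_under_cut, esc$overdose_cut)
    start2 <- starting_dose(ip0$p_under, esc)
    if (is.na(start2)) {
      res2 <- unstarted_trial(scenario$T2, doses, 2L)
      return(list(T1 = res1, T2 = res2, preset = preset,
                  scenario_id = scenario$id))
    }
  }

  # T2 conduct
  if (preset == "E") {
    cfg_pool <- bridge_config(species = config$species, n_subgroups = 1L,
                              weights = matrix(c(0, 0, 0, 1), 1L),
                              preset = "E", pool_human = TRUE)
    res2 <- run_escalation(scenario$T2, doses, 2L, cfg_pool, list(),
                           other_human = list(t1_data), esc, mcmc,
                           start_index = start2, fix = list(eps = 1))
  } else {
    other <- switch(preset, A = list(t1_data), B = list(t1_data),
                    C = list(), D = list())
    res2 <- run_escalation(scenario$T2, doses, 2L, config, anim,
                           other_human = other, esc, mcmc,
                           start_index = start2)
  }
  list(T1 = res1, T2 = res2, preset = preset, scenario_id = scenario$id)
}

#' Aggregate operating characteristics
#'
#' Summarises a set of simulated trials from one region under one
#' scenario and analysis model: the percentage of correct selection (PCS,
#' trials declaring the region's true MTD), early-stop percentage,
#' aborted-analysis percentage, completed-without-declaration percentage,
#' per-dose declaration percentages, mean patients per dose and mean DLT
#' count.  Declaration, stop, abort and no-declaration percentages
#' account for 100% of trials; allocation means include stopped trials.
#' Aborted trials count against PCS.
#'
#' @param results List of `trial_result` objects (same region/scenario).
#' @param scenario The [toxicity_scenarios()] element they were simulated
#'   under.
#' @param region Region index 1 or 2 (defaults to the results' region).
#' @return An object of class `operating_characteristics`.
#' @export
operating_characteristics <- function(results, scenario,
                                      region = results[[1L]]$region) {
  if (length(results) == 0L) stop("empty result list")
  if (is.numeric(scenario)) scenario <- toxicity_scenarios(scenario)
  true_mtd <- scenario$true_mtd[region]
  J <- length(results[[1L]]$doses)
  nres <- length(results)
  mtds <- vapply(results, function(x) as.integer(x$mtd), integer(1L))
  stopped <- vapply(results, function(x) isTRUE(x$stopped), logical(1L))
  aborted <- vapply(results, function(x) isTRUE(x$aborted), logical(1L))
  completed_none <- !stopped & !aborted & is.na(mtds)
  pct_declared <- vapply(seq_len(J),
                         function(j) 100 * sum(mtds == j, na.rm = TRUE) / nres,
                         numeric(1L))
  structure(list(
    region = region, scenario_id = scenario$id, n_trials = nres,
    true_mtd = true_mtd,
    pcs = 100 * sum(mtds == true_mtd, na.rm = TRUE) / nres,
    pct_stopped = 100 * mean(stopped),
    pct_aborted = 100 * mean(aborted),
    pct_no_declaration = 100 * mean(completed_none),
    pct_declared = pct_declared,
    mean_patients = rowMeans(vapply(results, function(x) as.numeric(x$n),
                                    numeric(J))),
    mean_dlts = mean(vapply(results, function(x) sum(x$r), numeric(1L)))),
    class = "operating_characteristics")
}

#' @export
print.operating_characteristics <- function(x, ...) {
  cat(sprintf("Scenario %d, region R%d (%d trials)\n", x$scenario_id,
              x$region, x$n_trials))
  cat(sprintf("  PCS %.1f%%  stopped %.1f%%  aborted %.1f%%  no declaration %.1f%%\n",
              x$pcs, x$pct_stopped, x$pct_aborted, x$pct_no_declaration))
  cat("  declared per dose (%):", paste(sprintf("%.1f", x$pct_declared),
                                        collapse = " "), "\n")
  cat("  mean patients per dose:", paste(sprintf("%.2f", x$mean_patients),
                                         collapse = " "), "\n")
  cat(sprintf("  mean DLTs per trial: %.2f\n", x$mean_dlts))
  invisible(x)
}

#' Replicated operating-characteristics study
#'
#' Convenience wrapper running `reps` independent trial pairs (seeds
#' `seed + 1, ..., seed + reps`) and aggregating each region.
#'
#' @inheritParams run_trial_pair
#' @param reps Number of replicate pairs.
#' @param seed Base seed.
#' @return List with `pairs` (raw results), `T1` and `T2`
#'   ([operating_characteristics()] per region).
#' @export
simulate_trials <- function(scenario, preset = "A", reps = 100L,
                            animal = default_animal_fixture(),
                            esc = escalation_config(),
                            mcmc = sim_mcmc_settings(), seed = 1L) {
  if (is.numeric(scenario)) scenario <- toxicity_scenarios(scenario)
  pairs <- lapply(seq_len(reps), function(i)
    run_trial_pair(scenario, preset, animal, esc, mcmc, seed = seed + i))
  list(pairs = pairs,
       T1 = operating_characteristics(lapply(pairs, `[[`, "T1"), scenario, 1L),
       T2 = operating_characteristics(lapply(pairs, `[[`, "T2"), scenario, 2L))
}
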