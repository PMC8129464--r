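test_that("scenario table and cohort outcomes", {
  sc <- toxicity_scenarios()
  expect_length(sc, 6L)
  for (s in sc) {
    expect_true(all(diff(s$T1) >= 0) && all(diff(s$T2) >= 0))
    expect_true(all(s$T1 > 0 & s$T1 < 1))
    # the true MTD is the dose closest to the 25% target
    expect_equal(which.min(abs(s$T1 - 0.25)), s$true_mtd[1])
    expect_equal(which.min(abs(s$T2 - 0.25)), s$true_mtd[2])
  }
  expect_equal(toxicity_scenarios(2)$true_mtd, c(4L, 3L))

  expect_equal(simulate_cohort_outcome(0, 3), 0L)
  expect_equal(simulate_cohort_outcome(1, 3), 3L)
  set.seed(3)
  draws <- replicate(5000, simulate_cohort_outcome(0.25, 3))
  expect_equal(mean(draws), 0.75, tolerance = 3 * sqrt(3 * .25 * .75 / 5000))
})

test_that("a non-toxic world escalates to the top dose; a toxic one stops", {
  clean <- list(id = 90L, T1 = rep(1e-9, 6), T2 = rep(1e-9, 6),
                true_mtd = c(6L, 6L))
  p <- run_trial_pair(clean, "C", seed = 21)
  for (res in list(p$T1, p$T2)) {
    expect_false(res$stopped)
    expect_equal(sum(res$r), 0L)
    expect_equal(sum(res$n), 24L)
    expect_equal(res$mtd, 6L)
    expect_true(all(diff(res$trace$dose_index) >= 0))      # monotone
    expect_true(all(diff(res$trace$dose_index) <= 1))      # never skips
  }

  toxic <- list(id = 91L, T1 = rep(0.95, 6), T2 = rep(0.95, 6),
                true_mtd = c(1L, 1L))
  p2 <- run_trial_pair(toxic, "C", seed = 22)
  expect_true(p2$T1$stopped)
  expect_true(p2$T2$stopped)
  expect_true(is.na(p2$T1$mtd))
  expect_lt(sum(p2$T1$n), 24L)
})

test_that("trial pairs are reproducible given a seed", {
  p1 <- run_trial_pair(1, "D", seed = 77)
  p2 <- run_trial_pair(1, "D", seed = 77)
  expect_identical(p1$T1$n, p2$T1$n)
  expect_identical(p1$T1$r, p2$T1$r)
  expect_identical(p1$T2$trace$decision, p2$T2$trace$decision)
  expect_identical(p1$T1$mtd, p2$T1$mtd)
})

test_that("operating characteristics match hand counts", {
  mk <- function(mtd, stopped = FALSE, aborted = FALSE, n = rep(4L, 6))
    structure(list(region = 1L, doses = dose_panel(), n = n,
                   r = if (all(n == 0L)) integer(6) else c(0L, 1L, 0L, 1L, 0L, 0L),
                   stopped = stopped,
                   stop_reason = NA_character_,
                   mtd = if (is.null(mtd)) NA_integer_ else mtd,
                   aborted = aborted, trace = data.frame()),
              class = "trial_result")
  sc <- toxicity_scenarios(1)  # true MTD: dose 4
  res <- list(mk(4L), mk(4L), mk(3L), mk(NULL, stopped = TRUE, n = integer(6)),
              mk(NULL, aborted = TRUE))
  oc <- operating_characteristics(res, sc, region = 1L)
  expect_equal(oc$pcs, 40)
  expect_equal(oc$pct_stopped, 20)
  expect_equal(oc$pct_aborted, 20)
  expect_equal(oc$pct_declared, c(0, 0, 20, 40, 0, 0))
  # every trial is accounted for exactly once
  expect_equal(sum(oc$pct_declared) + oc$pct_stopped + oc$pct_aborted +
                 oc$pct_no_declaration, 100)
  expect_equal(oc$mean_patients, rep(4 * 4 / 5, 6))
  expect_equal(oc$mean_dlts, 2 * 4 / 5)
  expect_error(operating_characteristics(list(), sc), "empty")
})

test_that("an overdosed lowest dose keeps patients off the high doses", {
  # lowest dose already at/above the 25% target in both regions
  set.seed(9)
  res <- simulate_trials(5, "D", reps = 6, seed = 410)
  for (oc in list(res$T1, res$T2)) {
    expect_lt(oc$mean_patients[5] + oc$mean_patients[6], 1)
    expect_gt(oc$pct_stopped, 0)
  }
})
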