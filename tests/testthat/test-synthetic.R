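test_that("designs validate and generate within their invariants", {
  expect_error(animal_design("d", "rat", c(2, 1), c(5, 5), 0), "increasing")
  expect_error(animal_design("d", "rat", c(1, 2), c(0, 5), 0), ">= 1")

  # degenerate curves
  zero <- animal_design("z", "rat", c(1, 5), c(20, 20), intercept = -40)
  one <- animal_design("o", "rat", c(1, 5), c(20, 20), intercept = 40)
  out <- generate_animal_studies(list(zero, one), seed = 1)
  expect_equal(out[[1L]]$r, c(0L, 0L))
  expect_equal(out[[2L]]$r, c(20L, 20L))
  expect_s3_class(out[[1L]], "animal_study")
})

test_that("generated DLT fractions match the design curve", {
  des <- animal_design("cal", "monkey", c(1, 10, 30, 100), rep(60L, 4),
                       intercept = -3.84)
  p_true <- plogis(-3.84 + log(c(1, 10, 30, 100)))
  set.seed(2)
  reps <- 400L
  acc <- matrix(0, reps, 4L)
  for (i in seq_len(reps))
    acc[i, ] <- generate_animal_studies(des)[[1L]]$r / 60
  se <- sqrt(p_true * (1 - p_true) / (60 * reps))
  expect_true(all(abs(colMeans(acc) - p_true) < 4 * se))
})

test_that("the default fixture is deterministic and well-formed", {
  f1 <- default_animal_fixture()
  f2 <- default_animal_fixture()
  expect_identical(f1, f2)
  expect_length(f1, 5L)
  expect_equal(sum(vapply(f1, function(s) s$species, "") == "monkey"), 2L)
  expect_equal(sum(vapply(f1, function(s) s$species, "") == "rat"), 3L)
  mk <- f1[[1L]]
  expect_equal(mk$dose, c(1, 10, 30, 100))
  expect_true(all(mk$n >= 4 & mk$n <= 12))
  for (s in f1) expect_true(all(s$r >= 0 & s$r <= s$n))
  # byte-identical serialisation
  fa <- tempfile(); fb <- tempfile()
  write_study_table(default_animal_fixture(), fa)
  write_study_table(default_animal_fixture(), fb)
  expect_identical(readLines(fa), readLines(fb))
  unlink(c(fa, fb))
  # a different seed gives different counts
  expect_false(identical(default_animal_fixture(1),
                         default_animal_fixture(2)))
})

test_that("fixture calibration: translated sources anchor 25% risk", {
  anim <- default_animal_fixture()
  s <- mcmc_settings(chains = 2, iterations = 6000, burnin = 1500, seed = 61)
  monkey_only <- bridge_config(weights = exch_weights(c(0, 1, 0, 0),
                                                      c(0, 1, 0, 0)))
  fm <- fit_bridge_model(monkey_only, anim, list(), s)
  sm <- summarize_risk(dlt_risk(fm, 1, dose_panel()))
  expect_gt(sm$median[4], 0.15)  # ~25% at 5 mg/kg from monkey data
  expect_lt(sm$median[4], 0.35)

  rat_only <- bridge_config(weights = exch_weights(c(1, 0, 0, 0),
                                                   c(1, 0, 0, 0)))
  fr <- fit_bridge_model(rat_only, anim, list(), s)
  sr <- summarize_risk(dlt_risk(fr, 1, dose_panel()))
  expect_gt(sr$median[3], 0.15)  # ~25% at 1 mg/kg from rat data
  expect_lt(sr$median[3], 0.35)

  # rat evidence projects onto low doses only: at 10 and 20 mg/kg its
  # predictions are extrapolations, wider than the monkey-informed ones
  # (log-odds scale, where the comparison is not compressed against 1)
  lw <- function(r) {
    q <- apply(qlogis(pmin(pmax(r, 1e-12), 1 - 1e-12)), 2,
               quantile, c(0.025, 0.975))
    q[2, ] - q[1, ]
  }
  wr <- lw(dlt_risk(fr, 1, dose_panel()))
  wm <- lw(dlt_risk(fm, 1, dose_panel()))
  expect_gt(wr[5], wm[5])
  expect_gt(wr[6], wm[6])
  expect_gt(wr[6], wr[4])  # rat width grows with extrapolation distance
})
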