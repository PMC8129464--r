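test_that("study constructors enforce their invariants", {
  expect_error(animal_study("a", "rat", c(1, 1, 2), c(3, 3, 3), c(0, 0, 0)),
               "increasing")
  expect_error(animal_study("a", "rat", c(1, 2), c(3, 0), c(0, 0)), "n >= 1")
  expect_error(animal_study("a", "rat", c(1, 2), c(3, 3), c(0, 4)), "r <= n")
  expect_error(animal_study("a", "rat", c(-1, 2), c(3, 3), c(0, 0)), "positive")
  expect_error(human_trial(1, c(1, 2), c(3, 3), c(4, 0)), "r <= n")
  expect_error(human_trial(1, c(1, 2), c(30, 3), c(0, 0), max_patients = 24),
               "maximum sample size")
  h <- human_trial(1, c(1, 2), c(0, 0), c(0, 0))  # empty accrual is valid
  expect_s3_class(h, "human_trial")
})

test_that("study tables round-trip through the delimited format", {
  studies <- c(toy_animal(), toy_human())
  f <- tempfile(fileext = ".tsv")
  write_study_table(studies, f)
  back <- read_study_table(f)
  expect_length(back$animal, 2L)
  expect_length(back$human, 1L)
  expect_equal(back$animal[[1L]]$dose, studies[[1L]]$dose)
  expect_equal(back$animal[[2L]]$r, studies[[2L]]$r)
  expect_equal(back$human[[1L]]$n, studies[[3L]]$n)
  expect_equal(back$human[[1L]]$subgroup, 1L)
  unlink(f)
})

test_that("configuration validation and presets", {
  expect_error(exch_weights(c(0.5, 0.5, 0.2, -0.2)), "\\[0, 1\\]")
  expect_error(exch_weights(c(0.5, 0.3, 0.1, 0.2)), "sum to 1")
  expect_error(bridging_prior(nu = -1), "positive")
  expect_error(hierarchy_priors(s1 = 0), "positive")
  expect_error(nonex_prior(corr = 1.2), "-1, 1")

  for (p in c("A", "B", "C", "D", "E")) {
    cfg <- model_preset(p)
    expect_s3_class(cfg, "bridge_config")
    expect_equal(rowSums(cfg$weights), c(1, 1), tolerance = 1e-12)
  }
  expect_equal(unname(model_preset("B")$weights[, "H"]), c(1, 1))
  expect_equal(unname(model_preset("C")$weights[, "R"]), c(1, 1))
  expect_equal(unname(model_preset("D")$weights[1, ]), c(0.2, 0.6, 0, 0.2))
  expect_equal(unname(model_preset("A")$weights[2, ]), c(0.1, 0.5, 0.2, 0.2))
  expect_true(model_preset("E")$pool_human)
})

test_that("configurations round-trip through JSON", {
  cfg <- model_preset("A", hierarchy = hierarchy_priors(d_ref = 7.5))
  f <- tempfile(fileext = ".json")
  write_config(cfg, f)
  back <- read_config(f)
  expect_equal(back$weights, cfg$weights)
  expect_equal(back$hierarchy$d_ref, 7.5)
  expect_equal(back$translation$meanlog, cfg$translation$meanlog)
  expect_equal(back$bridging$nu, cfg$bridging$nu)
  expect_equal(back$nonex[[1L]]$sd, cfg$nonex[[1L]]$sd)
  expect_equal(back$preset, "A")
  unlink(f)
})
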