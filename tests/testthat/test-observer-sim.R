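# Synthetic observer populations and trial simulation.

test_that("population sampling is deterministic and respects the spec", {
  spec <- population_spec(40, pse_intercept_ms = c(upright = 69.3),
                          aq_mean = 24.9, aq_sd = 4.3, aq_range = c(20, 36),
                          pse_resid_sd_ms = 45)
  p1 <- sample_population(spec, seed = 3)
  p2 <- sample_population(spec, seed = 3)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 40)
  expect_true(all(p1$aq == round(p1$aq)))
  expect_true(all(p1$aq >= 20 & p1$aq <= 36))
  expect_true(all(p1$omega_ms > 0))
  # sample AQ mean close to the recruited-group mean (truncation shifts the
  # parent mean up slightly; 3 SE of the sample mean comfortably covers it)
  expect_lt(abs(mean(p1$aq) - 24.9), 3 * sd(p1$aq) / sqrt(40) + 1)
})

test_that("degenerate noise collapses latent PSEs onto the intercept", {
  spec <- population_spec(10, pse_intercept_ms = c(upright = 42),
                          pse_slope_ms_per_aq = 0, pse_resid_sd_ms = 0,
                          pse_shared_sd_ms = 0)
  p <- sample_population(spec, seed = 1)
  expect_equal(vapply(p$pse_ms, `[[`, numeric(1), "upright"), rep(42, 10))
})

test_that("invalid population specs are rejected as configuration errors", {
  expect_error(population_spec(1, pse_intercept_ms = 0),
               class = "durpsych_config_error")
  expect_error(population_spec(10, pse_intercept_ms = 0,
                               aq_range = c(30, 10)),
               class = "durpsych_config_error")
  expect_error(population_spec(10, pse_intercept_ms = 0, lapse = 0.5),
               class = "durpsych_config_error")
  expect_error(population_spec(10, pse_intercept_ms = 0,
                               pse_resid_sd_ms = -1),
               class = "durpsych_config_error")
})

test_that("trait-to-PSE moment matching reproduces the target correlation", {
  spec0 <- population_spec(10000, pse_intercept_ms = c(upright = 0))
  cal <- calibrate_aq_pse(-0.40, 60, spec0)
  spec <- population_spec(10000, pse_intercept_ms = c(upright = 0),
                          pse_slope_ms_per_aq = cal$slope_ms_per_aq,
                          pse_resid_sd_ms = cal$resid_sd_ms)
  prof <- sample_population(spec, seed = 7)
  pse <- vapply(prof$pse_ms, `[[`, numeric(1), "upright")
  expect_lt(abs(cor(prof$aq, pse) - (-0.40)), 0.02)
})

test_that("the default design yields 140 trials, 20 per level, in order", {
  prof <- make_profile(c(upright = 50))
  design <- experiment_design(conditions = "upright")
  tr <- simulate_trials(prof, design, "upright", seed = 2)
  expect_equal(nrow(tr), 140)
  expect_equal(as.vector(table(tr$delta_ms)), rep(20, 7))
  expect_true(all(tr$delta_ms %in% design$levels_ms))
  expect_true(all(tr$chose_communicative_longer %in% 0:1))
  expect_true(all(tr$block %in% 1:4))
  expect_identical(tr, simulate_trials(prof, design, "upright", seed = 2))
})

test_that("choice probabilities follow the generating Boltzmann curve", {
  # at delta = pse the generating probability is exactly 0.5
  expect_equal(boltzmann(50, 50, 150), 0.5)
  # closed form at +600 with pse 0, omega 150: 1/(1+exp(-4))
  expect_equal(boltzmann(600, 0, 150), 1 / (1 + exp(-4)), tolerance = 1e-12)
  # empirical proportions converge to the curve at large reps
  prof <- make_profile(c(upright = 50))
  design <- experiment_design(reps_per_level = 10000, conditions = "upright",
                              experiment_id = "conv")
  tab <- aggregate_proportions(
    simulate_trials(prof, design, "upright", seed = 2))
  dev <- abs(tab$n_chose / tab$n_total - boltzmann(tab$delta_ms, 50, 150))
  expect_lt(max(dev), 0.02)
})

test_that("a lapse rate mixes the curve toward chance symmetrically", {
  prof <- make_profile(c(upright = 0), lapse = 0.1)
  design <- experiment_design(reps_per_level = 5000, conditions = "upright")
  tab <- aggregate_proportions(
    simulate_trials(prof, design, "upright", seed = 9))
  p600 <- tab$n_chose[tab$delta_ms == 600] / tab$n_total[tab$delta_ms == 600]
  expected <- 0.05 + 0.9 * boltzmann(600, 0, 150)
  expect_lt(abs(p600 - expected), 0.02)
})

test_that("an unknown condition is a key error", {
  prof <- make_profile(c(upright = 50))
  design <- experiment_design()
  expect_error(simulate_trials(prof, design, "inverted", seed = 1),
               class = "durpsych_key_error")
})

test_that("drug effects shift latent PSEs as configured", {
  prof <- sample_population(
    population_spec(40, pse_intercept_ms = c(pre = 10),
                    pse_resid_sd_ms = 40, drug = "saline"),
    seed = 5)

  saline <- population_spec(40, pse_intercept_ms = c(pre = 10),
                            drug = "saline", drug_shift_mean_ms = 99,
                            drug_shift_sd_ms = 0)
  expect_identical(apply_drug_effect(prof, saline, seed = 1)$pse_ms,
                   prof$pse_ms)

  oxy <- population_spec(40, pse_intercept_ms = c(pre = 10),
                         drug = "oxytocin", drug_shift_mean_ms = 36.9,
                         drug_shift_sd_ms = 0)
  shifted <- apply_drug_effect(prof, oxy, seed = 1)
  deltas <- mapply(function(a, b) b[["pre"]] - a[["pre"]],
                   prof$pse_ms, shifted$pse_ms)
  expect_equal(unname(deltas), rep(36.9, 40))

  ato <- population_spec(40, pse_intercept_ms = c(pre = 10),
                         drug = "atosiban", drug_shift_mean_ms = -31.1,
                         drug_shift_sd_ms = 50)
  shifted <- apply_drug_effect(prof, ato, seed = 2)
  deltas <- mapply(function(a, b) b[["pre"]] - a[["pre"]],
                   prof$pse_ms, shifted$pse_ms)
  expect_lt(abs(mean(deltas) - (-31.1)), 3 * 50 / sqrt(40))
  # omega untouched: the treatment is a pure bias shift
  expect_identical(shifted$omega_ms, prof$omega_ms)
})

test_that("substreams keep stages independently reproducible", {
  spec <- population_spec(5, pse_intercept_ms = c(upright = 0),
                          pse_resid_sd_ms = 40)
  design <- experiment_design(conditions = "upright")
  prof <- sample_population(spec, seed = 11)
  tr1 <- simulate_trials(prof, design, "upright", seed = 11)
  # a different population draw does not perturb the trial substream
  sample_population(spec, seed = 99)
  tr2 <- simulate_trials(prof, design, "upright", seed = 11)
  expect_identical(tr1, tr2)
  expect_true(substream_seed(11, "population") != substream_seed(11, "trials"))
})
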