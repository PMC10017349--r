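test_that("trial table layout and effect encoding follow the configuration", {
  cfg <- world_config(seed = 3, n_trials_per_class = 5, tau = 0)
  tt <- generate_trial_table(cfg)
  expect_equal(nrow(tt), 30)  # 5 trials x 6 classes
  expect_true(all(tt$n_t >= 10) && all(tt$n_c >= 10))
  expect_true(all(tt$sd_t > 0) && all(tt$sd_c > 0))
  # with tau = 0 every CBT row encodes the true effect up to the
  # small-sample correction
  smd <- compute_smd(tt[tt$intervention_class == "CBT", ])$smd
  expect_true(all(abs(smd - (-0.68)) < 0.02))
})

test_that("a null world yields mean SMD near zero", {
  cfg <- world_config(seed = 5, n_trials_per_class = 40, tau = 0.05,
                      true_effects = c(cognitive = 0, behavioural = 0, CBT = 0,
                                       psychodynamic = 0, supportive = 0,
                                       antidepressants = 0))
  smd <- compute_smd(generate_trial_table(cfg))$smd
  expect_lt(abs(mean(smd)), 0.02)
})

test_that("survey generation has valid ranges and recoverable ground truth", {
  cfg <- small_world_config(survey_n = 2000)
  sv <- generate_survey(cfg)
  s <- sv$survey
  expect_equal(nrow(s), 2000)
  expect_true(all(s$weight > 0))
  expect_true(all(s$sf12 >= 0 & s$sf12 <= 100))
  tr <- sv$truth
  expect_true(all(tr$dw_anxiety_true >= 0 & tr$dw_anxiety_true < 1))
  expect_true(all(tr$dw_cumulative_true >= 0 & tr$dw_cumulative_true < 1))
  expect_equal(sum(tr$no_treatment_severity), 1, tolerance = 1e-12)
  # non-anxiety respondents carry no anxiety disability
  expect_true(all(tr$dw_anxiety_true[s$anxiety_30day == 0] == 0))
  # cumulative = multiplicative combination of anxiety and comorbidities
  expect_equal(tr$dw_cumulative_true,
               1 - (1 - tr$dw_anxiety_true) * (1 - tr$dw_comorbidities_true),
               tolerance = 1e-12)
})

test_that("zero treatment coverage leaves SF-12 at its counterfactual", {
  cfg <- small_world_config(coverage_probs = c(CBT = 0, psychodynamic = 0,
                                               supportive = 0, antidepressants = 0))
  sv <- generate_survey(cfg)
  anx <- sv$survey$anxiety_30day == 1
  expect_equal(sv$survey$sf12[anx], sv$truth$sf12_no_treatment[anx])
})

test_that("no comorbid conditions means zero comorbid disability", {
  cfg <- small_world_config(condition_defs = data.frame(condition = character(),
                                                        prevalence = numeric(),
                                                        dw = numeric()))
  sv <- generate_survey(cfg)
  expect_true(all(sv$truth$dw_comorbidities_true == 0))
})

test_that("coverage points sit on the configured line when noiseless", {
  cfg <- small_world_config(coverage_noise_sd = 0)
  pts <- generate_coverage_points(cfg)
  expect_equal(pts$coverage,
               pmin(pmax(cfg$haqi_slope * (pts$haqi - cfg$haqi_zero_intercept), 0), 1),
               tolerance = 1e-12)
  # line evaluation: slope 0.01, intercept 44.1 at HAQI 88
  expect_equal(0.01 * (88 - 44.1), 0.439, tolerance = 1e-12)
})

test_that("country table has requested size, valid ranges, and is deterministic", {
  cfg <- small_world_config(n_countries = 195)
  ct1 <- generate_country_table(cfg)
  ct2 <- generate_country_table(cfg)
  expect_identical(ct1, ct2)
  expect_equal(nrow(ct1), 195)
  expect_true(all(ct1$prevalence > 0 & ct1$prevalence < 0.2))
  expect_true(all(ct1$population > 0))
  expect_true(all(!is.na(ct1$super_region)))
  single <- generate_country_table(small_world_config(n_countries = 1))
  expect_equal(nrow(single), 1)
})

test_that("the whole world is reproducible from its seed", {
  cfg <- small_world_config(seed = 21)
  d1 <- file.path(tempdir(), "w1"); d2 <- file.path(tempdir(), "w2")
  write_world(cfg, d1); write_world(cfg, d2)
  for (f in c("trials.csv", "survey.csv", "coverage_points.csv",
              "countries.csv", "truth.yaml"))
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
})

test_that("invalid configurations are rejected", {
  expect_error(world_config(anxiety_prevalence_survey = 1.5), "proportions")
  expect_error(world_config(no_treatment_severity = c(asymptomatic = 0.5, mild = 0.5,
                                                      moderate = 0.5, severe = 0.5)),
               "sum to 1")
  expect_error(world_config(true_effects = c(cognitive = -0.1, behavioural = -0.1,
                                             CBT = -0.5, psychodynamic = -0.4,
                                             supportive = -0.2, antidepressants = -0.3)),
               "cognitive \\+ behavioural")
  expect_error(generate_trial_table(small_world_config(), arm_sd = -1), "positive")
})
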