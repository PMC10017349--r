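mk_survey <- function(n, sessions_cbt = "none", sessions_other = "none",
                      sessions_counselling = "none", medication = 0,
                      weight = 1, stratum = 1) {
  data.frame(id = seq_len(n), weight = weight, stratum = stratum,
             anxiety_30day = 1, sf12 = 50,
             sessions_cbt = sessions_cbt,
             sessions_other_psychotherapy = sessions_other,
             sessions_counselling = sessions_counselling,
             medication = medication)
}

test_that("six or more sessions defines receipt and the hierarchy holds", {
  s <- mk_survey(4,
                 sessions_cbt = c(">10", "5", "none", "none"),
                 sessions_counselling = c(">10", "none", "6-10", "none"),
                 medication = c(0, 0, 0, 1))
  a <- assign_received_treatments(s)
  # CBT trumps counselling when both are adequate
  expect_true(a$CBT[1]); expect_false(a$supportive[1])
  # five sessions is below the minimally-adequate threshold
  expect_false(a$CBT[2])
  expect_true(a$supportive[3])
  # medication alone maps to antidepressants
  expect_equal(unname(unlist(a[4, c("CBT", "psychodynamic", "supportive",
                                    "antidepressants")])),
               c(FALSE, FALSE, FALSE, TRUE))
  expect_error(assign_received_treatments(transform(s, sessions_cbt = "lots")),
               "unknown session category")
})

test_that("other psychotherapy only counts when CBT was not received", {
  s <- mk_survey(2, sessions_cbt = c(">10", "none"),
                 sessions_other = c("6-10", "6-10"))
  a <- assign_received_treatments(s)
  expect_equal(a$psychodynamic, c(FALSE, TRUE))
})

test_that("coverage is the survey-weighted proportion", {
  s <- mk_survey(10, medication = c(1, 1, rep(0, 8)))
  cov <- estimate_coverage(assign_received_treatments(s), s, n_boot = 50)
  expect_equal(cov$coverage[cov$class == "antidepressants"], 0.20)
  # weighted: weights (3,1), only the first on medication
  s2 <- mk_survey(2, medication = c(1, 0), weight = c(3, 1))
  cov2 <- estimate_coverage(assign_received_treatments(s2), s2, n_boot = 50)
  expect_equal(cov2$coverage[cov2$class == "antidepressants"], 0.75)
  # untreated survey: zero coverage with degenerate UI
  s3 <- mk_survey(5)
  cov3 <- estimate_coverage(assign_received_treatments(s3), s3, n_boot = 50)
  expect_true(all(cov3$coverage == 0 & cov3$lower == 0 & cov3$upper == 0))
})

test_that("coverage is invariant to uniform weight rescaling", {
  cfg <- small_world_config()
  sv <- generate_survey(cfg)$survey
  a <- assign_received_treatments(sv)
  c1 <- estimate_coverage(a, sv, n_boot = 30, seed = 4)
  sv$weight <- sv$weight * 1000
  c2 <- estimate_coverage(a, sv, n_boot = 30, seed = 4)
  expect_equal(c1$coverage, c2$coverage, tolerance = 1e-12)
})

test_that("coverage recovers the configured uptake probabilities", {
  cfg <- world_config(seed = 31, survey_n = 10000, n_draws = 10)
  sv <- generate_survey(cfg)$survey
  cov <- estimate_coverage(assign_received_treatments(sv), sv, n_boot = 30)
  got <- setNames(cov$coverage, cov$class)
  expect_true(all(abs(got[names(cfg$coverage_probs)] - cfg$coverage_probs) < 0.03))
})

test_that("the coverage-adjusted effect is the weighted per-respondent sum", {
  draws <- list(CBT = rep(-0.68, 8), psychodynamic = rep(-0.48, 8),
                supportive = rep(-0.28, 8), antidepressants = rep(-0.38, 8))
  # nobody treated -> beta identically 0
  s0 <- mk_survey(4)
  b0 <- coverage_adjusted_effect(assign_received_treatments(s0), s0, draws)
  expect_true(all(b0$draws == 0))
  # full CBT coverage -> beta equals the CBT effect
  s1 <- mk_survey(4, sessions_cbt = ">10")
  b1 <- coverage_adjusted_effect(assign_received_treatments(s1), s1, draws)
  expect_equal(b1$draws, rep(-0.68, 8))
  # half on antidepressants, equal weights -> -0.19
  s2 <- mk_survey(4, medication = c(1, 1, 0, 0))
  b2 <- coverage_adjusted_effect(assign_received_treatments(s2), s2, draws)
  expect_equal(b2$draws, rep(-0.19, 8))
  # co-treatment adds effects; beta is bounded by the largest per-respondent sum
  s3 <- mk_survey(2, sessions_cbt = c(">10", "none"), medication = c(1, 0))
  b3 <- coverage_adjusted_effect(assign_received_treatments(s3), s3, draws)
  expect_equal(b3$draws, rep((-0.68 - 0.38) / 2, 8))
  expect_true(all(abs(b3$draws) <= 1.06))
  expect_error(coverage_adjusted_effect(assign_received_treatments(s3), s3,
                                        draws[-1]), "missing class draws")
})
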