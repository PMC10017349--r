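test_that("SMD matches the hand-computed Hedges value and variance", {
  eff <- data.frame(study_id = "S1", intervention_class = "CBT",
                    mean_t = 8, sd_t = 2, n_t = 50,
                    mean_c = 10, sd_c = 2, n_c = 50)
  out <- compute_smd(eff)
  # pooled SD = 2; raw d = -1; exact Hedges factor J(m) with m = 98 df
  m <- 98
  J <- exp(lgamma(m / 2) - log(sqrt(m / 2)) - lgamma((m - 1) / 2))
  expect_equal(out$smd, -1 * J, tolerance = 1e-10)
  expect_equal(out$se_smd,
               sqrt(1 / 50 + 1 / 50 + out$smd^2 / (2 * 100)), tolerance = 1e-10)

  # identical means give exactly zero; swapping arms flips the sign
  eff0 <- transform(eff, mean_t = 10)
  expect_equal(compute_smd(eff0)$smd, 0)
  swapped <- transform(eff, mean_t = 10, mean_c = 8)
  expect_equal(compute_smd(swapped)$smd, -out$smd, tolerance = 1e-12)

  expect_error(compute_smd(transform(eff, sd_t = 0, sd_c = 0)), "degenerate arms")
})

test_that("longest follow-up per study is selected", {
  eff <- data.frame(study_id = c("A", "A", "B"),
                    follow_up_weeks = c(12, 52, 8), smd = 1:3)
  out <- select_longest_followup(eff)
  expect_equal(out$smd, c(2, 3))
})

test_that("untrimmed single-class pooling equals the inverse-variance mean", {
  set.seed(42)
  smd <- rnorm(15, -0.5, 0.2)
  se <- runif(15, 0.05, 0.3)
  eff <- effects_from_smd(smd, se)
  pooled <- fit_trimmed_network(eff, trim_pct = 0, n_draws = 10, gamma = 0)
  ivw <- sum(smd / se^2) / sum(1 / se^2)
  expect_equal(unname(pooled$class_means["CBT"]), ivw, tolerance = 1e-8)
  # unanimity: identical effects pool to themselves with no heterogeneity
  una <- fit_trimmed_network(effects_from_smd(rep(-0.5, 3), rep(0.1, 3)),
                             trim_pct = 0, n_draws = 10)
  expect_equal(unname(una$class_means["CBT"]), -0.5, tolerance = 1e-10)
  expect_lt(una$gamma, 1e-4)
})

test_that("estimates agree with metafor's ML random-effects fit", {
  set.seed(7)
  k <- 40
  cls <- rep(c("CBT", "antidepressants"), each = k / 2)
  true <- ifelse(cls == "CBT", -0.7, -0.4)
  se <- runif(k, 0.08, 0.25)
  smd <- rnorm(k, true, sqrt(se^2 + 0.1^2))
  eff <- effects_from_smd(smd, se, class = cls)
  mine <- fit_trimmed_network(eff, trim_pct = 0, n_draws = 10)
  X <- cbind(cbt = as.numeric(cls == "CBT"),
             ad = as.numeric(cls == "antidepressants"))
  ref <- metafor::rma(yi = smd, sei = se, mods = ~ X - 1,
                      intercept = FALSE, method = "ML")
  expect_equal(unname(mine$class_means[c("CBT", "antidepressants")]),
               unname(ref$beta[, 1]), tolerance = 1e-4)
  expect_equal(mine$gamma, sqrt(ref$tau2), tolerance = 1e-3)
})

test_that("trimming removes the planted likelihood outlier", {
  eff <- effects_from_smd(c(rep(-0.5, 10), 2.0), rep(0.1, 11))
  pooled <- fit_trimmed_network(eff, trim_pct = 0.10, n_draws = 10)
  expect_length(pooled$trimmed_ids, floor(0.10 * 11))
  expect_equal(pooled$trimmed_ids, "S011")
  expect_lt(abs(pooled$class_means[["CBT"]] - (-0.5)), 0.05)
  untrimmed <- fit_trimmed_network(eff, trim_pct = 0, n_draws = 10)
  expect_lt(abs(pooled$class_means[["CBT"]] + 0.5),
            abs(untrimmed$class_means[["CBT"]] + 0.5))
})

test_that("trimming everything in a class is an error, as is trim_pct >= 0.5", {
  # the two supportive effects straddle their class mean so badly that both
  # carry the smallest likelihood contributions and get trimmed together
  eff <- effects_from_smd(c(rep(-0.5, 8), 3, -3),
                          rep(0.1, 10),
                          class = c(rep("CBT", 8), "supportive", "supportive"))
  expect_error(fit_trimmed_network(eff, trim_pct = 0.2), "class unidentified")
  expect_error(fit_trimmed_network(eff, trim_pct = 0.5), "trim_pct")
})

test_that("reference class draws are identically zero", {
  eff <- effects_from_smd(rnorm(6, -0.4, 0.1), rep(0.1, 6))
  pooled <- fit_trimmed_network(eff, trim_pct = 0, n_draws = 25)
  expect_identical(class_effect(pooled, "reference")$draws, rep(0, 25))
})

test_that("heterogeneity widening adds gamma spread without moving the mean", {
  eff <- effects_from_smd(rnorm(10, -0.68, 0.05), rep(0.1, 10))
  pooled <- fit_trimmed_network(eff, trim_pct = 0, n_draws = 1000, seed = 2)
  # force a known gamma and constant draws to isolate the widening step
  pooled$gamma <- 0.3
  pooled$classes$CBT <- rep(-0.68, 1000)
  wide <- widen_by_heterogeneity(pooled, "CBT", seed = 9)
  expect_equal(sd(wide$draws), 0.3, tolerance = 0.03)
  expect_lt(abs(mean(wide$draws) + 0.68), 4 * 0.3 / sqrt(1000))
  pooled$gamma <- 0
  expect_identical(widen_by_heterogeneity(pooled, "CBT")$draws, rep(-0.68, 1000))
})

test_that("the optimal combination is the draw-wise sum", {
  a <- structure(list(label = "CBT", draws = rep(-0.68, 5)), class = "effect_draws")
  b <- structure(list(label = "AD", draws = rep(-0.38, 5)), class = "effect_draws")
  expect_equal(combine_optimal(a, b)$draws, rep(-1.06, 5))
  z <- structure(list(label = "0", draws = rep(0, 5)), class = "effect_draws")
  expect_equal(combine_optimal(a, z)$draws, a$draws)
  expect_equal(combine_optimal(a, b)$draws, combine_optimal(b, a)$draws)
  short <- structure(list(label = "s", draws = 1:3), class = "effect_draws")
  expect_error(combine_optimal(a, short), "mismatch")
})

test_that("CBT loads on the cognitive and behavioural dummies jointly", {
  # cognitive-only, behavioural-only and CBT trials: the CBT class effect is
  # the sum of the two component coefficients
  cls <- c(rep("cognitive", 5), rep("behavioural", 5), rep("CBT", 10))
  true <- c(rep(-0.3, 5), rep(-0.4, 5), rep(-0.7, 10))
  set.seed(1)
  eff <- effects_from_smd(rnorm(20, true, 0.05), rep(0.05, 20), class = cls)
  pooled <- fit_trimmed_network(eff, trim_pct = 0, n_draws = 10)
  expect_equal(unname(pooled$class_means["CBT"]),
               unname(pooled$coef["cognitive"] + pooled$coef["behavioural"]),
               tolerance = 1e-12)
  expect_lt(abs(mean(class_effect(pooled, "CBT")$draws) - (-0.7)), 0.1)
  expect_lt(abs(mean(class_effect(pooled, "cognitive")$draws) - (-0.3)), 0.1)
})
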