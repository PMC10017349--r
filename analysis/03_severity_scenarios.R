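#!/usr/bin/env Rscript
# Stage 3 — treatment coverage, disability weights, scenario severity.
#
# Derives received treatments from the survey service-use items, estimates
# survey-weighted coverage with a stratified bootstrap, and converts uptake
# into the coverage-adjusted population effect beta. Cumulative disability
# weights come from SF-12 scores through the logistic crosswalk; the
# comorbidity meta-regression removes comorbid disability; the corrected
# weights are shifted into the no-treatment and full-coverage
# optimal-treatment scenarios and sorted into sequelae.

library(anxburden)

seed <- 1
n_draws <- 1000
survey <- read.csv("scratch/world/survey.csv")
eff <- readRDS("scratch/stage2_effects.rds")
cfg <- readRDS("scratch/world/truth.rds")$cfg

assignment <- assign_received_treatments(survey)
coverage <- estimate_coverage(assignment, survey, seed = seed)
beta <- coverage_adjusted_effect(assignment, survey,
                                 lapply(eff$widened, `[[`, "draws"))
write.csv(coverage, "results/coverage.csv", row.names = FALSE)

anx <- survey[survey$anxiety_30day == 1, ]
sigma <- sd(anx$sf12)
cw <- calibrate_crosswalk(cfg$sf12_anchor_points, sf12_sd = sigma)
dw_cum <- respondent_dw_draws(survey$sf12, cw, n_draws, cfg$sf12_noise_sd,
                              seed = seed)
flags <- cbind(anxiety = survey$anxiety_30day,
               as.matrix(survey[, cfg$condition_defs$condition]) * 1)
com <- fit_comorbidity_model(dw_cum, flags, seed = seed)
ix <- which(survey$anxiety_30day == 1)
dw_anx <- comorbidity_correct(dw_cum[ix, ],
                              predict_comorbid_dw(com, flags[ix, ]))

hs <- health_state_set(n_draws = n_draws, seed = seed)
cuts <- severity_cutoffs(hs)
s_anx <- sf12_from_dw(cw, dw_anx)
obs <- shift_scenario(s_anx, 0, sigma, cw)
notx <- shift_scenario(s_anx, beta$draws, sigma, cw)
fcot <- shift_scenario(notx$sf12, -eff$fcot$draws, sigma, cw)
severity <- list(observed = estimate_distribution(obs$dw, anx$weight, cuts, hs),
                 no_treatment = estimate_distribution(notx$dw, anx$weight, cuts, hs),
                 fcot = estimate_distribution(fcot$dw, anx$weight, cuts, hs))

tab <- do.call(rbind, lapply(names(severity), function(sc) {
  p <- summarise_draws(t(severity[[sc]]$proportions))
  d <- summarise_draws(severity[[sc]]$dw)
  cbind(data.frame(scenario = sc, sequela = rownames(p)), p,
        dw = d[["mean"]], dw_lower = d[["lower"]], dw_upper = d[["upper"]],
        row.names = NULL)
}))
write.csv(tab, "results/severity_scenarios.csv", row.names = FALSE)

bs <- summarise_draws(beta$draws)
message(sprintf("coverage-adjusted effect beta = %.2f (95%% UI %.2f to %.2f); sigma_SF12 = %.1f",
                bs["mean"], bs["lower"], bs["upper"], sigma))
for (sc in names(severity)) {
  d <- summarise_draws(severity[[sc]]$dw)
  message(sprintf("%-14s sequela-weighted DW %.3f (%.3f to %.3f)",
                  sc, d["mean"], d["lower"], d["upper"]))
}
saveRDS(list(severity = severity, beta = beta, sigma = sigma),
        "scratch/stage3_severity.rds")
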