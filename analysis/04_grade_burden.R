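#!/usr/bin/env Rscript
# Stage 4 — grade severity by healthcare access and account the burden.
#
# Fits the coverage-HAQI relationship (linear vs logit, smaller RMSE wins),
# locates the zero-coverage intercept HAQI0, interpolates the severity
# distribution between the no-treatment plateau and the anchor survey's
# HAQI, extrapolates to every country, and converts prevalence, population
# and sequela-weighted disability weights into YLDs and averted / avoidable
# burden shares by super-region and globally.

library(anxburden)

seed <- 1
n_draws <- 1000
stage3 <- readRDS("scratch/stage3_severity.rds")
points <- read.csv("scratch/world/coverage_points.csv")
countries <- read.csv("scratch/world/countries.csv")

haqi_model <- fit_coverage_haqi(points, n_draws = n_draws,
                                seed = stage_seed(seed, "haqi"))
print(haqi_model)

set.seed(stage_seed(seed, "haqi_anchor"))
anchor_draws <- rnorm(n_draws, 88.0, (88.5 - 87.5) / (2 * qnorm(0.975)))
interp <- build_interpolator(stage3$severity$observed,
                             stage3$severity$no_treatment,
                             anchor_draws, haqi_model$haqi0, seed = seed)

country_rows <- do.call(rbind, lapply(seq_len(nrow(countries)), function(i) {
  d <- summarise_draws(severity_at_haqi(interp, countries$haqi[i])$dw)
  data.frame(location_id = countries$location_id[i],
             super_region = countries$super_region[i],
             haqi = countries$haqi[i], dw = d[["mean"]],
             dw_lower = d[["lower"]], dw_upper = d[["upper"]])
}))
write.csv(country_rows, "results/country_severity.csv", row.names = FALSE)

burden <- country_burden(countries, interp, stage3$severity$fcot)
agg <- aggregate_regions(burden)
write.csv(agg$fractions, "results/burden_regions.csv", row.names = FALSE)

message("burden shares by region (mean of draws):")
print(transform(agg$fractions[, c("region", "averted", "avoidable_brc",
                                  "avoidable_fcot", "remaining")],
                averted = round(100 * averted, 1),
                avoidable_brc = round(100 * avoidable_brc, 1),
                avoidable_fcot = round(100 * avoidable_fcot, 1),
                remaining = round(100 * remaining, 1)), row.names = FALSE)
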