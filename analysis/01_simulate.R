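#!/usr/bin/env Rscript
# Stage 1 — simulate the study's input world.
#
# Generates the four input tables with known ground truth: a 194-effect
# trial table (111 CBT effects), a 10641-respondent survey with latent
# anxiety and comorbidity disability weights observed through a noisy SF-12
# channel, 29 treatment-coverage-vs-HAQI survey points, and a 195-country
# table. Tables go to scratch/world/ for the later stages; a short summary
# goes to results/.

library(anxburden)

seed <- 1
cfg <- world_config(seed = seed)
world <- write_world(cfg, "scratch/world")

dir.create("results", showWarnings = FALSE)
n_anx <- sum(world$survey$anxiety_30day == 1)
summary_tab <- data.frame(
  table = c("trials", "survey", "coverage_points", "countries"),
  rows = c(nrow(world$trials), nrow(world$survey),
           nrow(world$coverage_points), nrow(world$countries)),
  note = c(sprintf("%d CBT effects", sum(world$trials$intervention_class == "CBT")),
           sprintf("%d thirty-day anxiety cases", n_anx),
           sprintf("HAQI %.0f-%.0f", min(world$coverage_points$haqi),
                   max(world$coverage_points$haqi)),
           sprintf("HAQI %.0f-%.0f", min(world$countries$haqi),
                   max(world$countries$haqi))))
write.csv(summary_tab, "results/world_summary.csv", row.names = FALSE)

message("simulated world (seed ", seed, "):")
print(summary_tab, row.names = FALSE)
message("ground truth: no-treatment severity ",
        paste(sprintf("%s %.1f%%", names(cfg$no_treatment_severity),
                      100 * cfg$no_treatment_severity), collapse = ", "))
message("ground truth: zero-coverage intercept HAQI ", cfg$haqi_zero_intercept,
        "; sigma_SF12 = ", round(world$truth$sigma_sf12, 2))
saveRDS(list(cfg = cfg, truth = world$truth), "scratch/world/truth.rds")
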