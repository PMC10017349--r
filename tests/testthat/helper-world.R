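# small synthetic worlds used across tests

small_world_config <- function(seed = 11, ...) {
  args <- list(seed = seed, n_draws = 60, survey_n = 800,
               n_trials_per_class = 4, n_countries = 20)
  do.call(world_config, utils::modifyList(args, list(...)))
}

# a run_config over in-memory tables from a world config
small_run_config <- function(cfg, n_draws = cfg$n_draws, ...) {
  trials <- generate_trial_table(cfg)
  sv <- generate_survey(cfg)
  run_config(trials = trials, survey = sv$survey,
             coverage_points = generate_coverage_points(cfg),
             countries = generate_country_table(cfg),
             crosswalk_anchors = cfg$sf12_anchor_points,
             n_draws = n_draws, seed = cfg$seed, ...)
}

# effects table built directly from smd/se values (single class by default)
effects_from_smd <- function(smd, se, class = "CBT") {
  data.frame(study_id = sprintf("S%03d", seq_along(smd)),
             intervention_class = rep_len(class, length(smd)),
             smd = smd, se_smd = se, follow_up_weeks = 12)
}

# point-valued health states (degenerate draws) for arithmetic checks
point_health_states <- function(n_draws = 1,
                                dws = c(mild = 0.030, moderate = 0.133,
                                        severe = 0.523)) {
  health_state_set(data.frame(state = names(dws), mean = dws,
                              lower = dws, upper = dws),
                   n_draws = n_draws)
}
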