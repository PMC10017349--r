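#' Configuration of the synthetic world
#'
#' Bundles every parameter of the synthetic-data generator: the ground-truth
#' treatment effects and trial layout, the survey of respondents with their
#' latent anxiety and comorbidity disability weights observed through a noisy
#' SF-12 channel, the treatment-coverage-versus-HAQI relationship, and the
#' country table. Defaults emulate the study conditions of the source data:
#' class effects on the standardised-mean-difference scale of -0.68 (CBT),
#' -0.48 (psychodynamic), -0.38 (antidepressants) and -0.28 (supportive
#' therapy); 194 trial effects of which 111 are CBT; a survey of 10641
#' respondents; treatment coverages of 5.4% (CBT), 6.2% (counselling /
#' supportive) and 39.2% (medication / antidepressants); a no-treatment
#' severity mixture of 0% asymptomatic, 43.7% mild, 30.0% moderate and 26.3%
#' severe; and a linear coverage-HAQI relationship with zero-coverage
#' intercept at HAQI 44.1 anchored at HAQI 88.0.
#'
#' @param seed Integer seed; the whole world is a deterministic function of it.
#' @param n_draws Default draw count carried into downstream configuration.
#' @param true_effects Named numeric of true class effects (SMD scale, <= 0).
#'   `CBT` must equal `cognitive + behavioural` if all three are supplied.
#' @param tau Between-study SD of true trial effects (SMD scale), >= 0.
#' @param n_trials_per_class Trial count per class; a scalar or a vector named
#'   like `true_effects`.
#' @param survey_n Number of survey respondents.
#' @param anxiety_prevalence_survey 30-day anxiety prevalence in the survey.
#' @param condition_defs data.frame(condition, prevalence, dw) of comorbid
#'   chronic conditions and their true disability weights.
#' @param sf12_anchor_points data.frame(sf12, dw) anchors defining the
#'   SF-12 to disability-weight crosswalk used by the generator (and, by
#'   default, by the pipeline).
#' @param sf12_noise_sd Measurement noise SD on the SF-12 scale (points).
#' @param coverage_probs Named probabilities of receiving each effect-bearing
#'   treatment among anxiety cases: `CBT`, `psychodynamic`, `supportive`
#'   (mutually exclusive psychotherapies) and `antidepressants` (independent).
#' @param no_treatment_severity True severity mixture (asymptomatic, mild,
#'   moderate, severe) of the latent untreated anxiety disability weight;
#'   must sum to 1.
#' @param severity_band_dws Point disability weights of the mild, moderate and
#'   severe health states from which the generator's mixture bands are cut.
#' @param haqi_slope Coverage gained per HAQI unit (> 0).
#' @param haqi_zero_intercept HAQI at which treatment coverage reaches zero.
#' @param n_coverage_points Number of coverage-survey points.
#' @param coverage_noise_sd Noise SD on observed coverage proportions.
#' @param n_countries Number of countries in the country table.
#' @param country_haqi_range Range of country HAQI scores in 2019.
#' @return A validated list of class `world_config`.
#' @export
world_config <- function(seed = 1L,
                         n_draws = 1000L,
                         true_effects = c(cognitive = -0.34, behavioural = -0.34,
                                          CBT = -0.68, psychodynamic = -0.48,
                                          supportive = -0.28, antidepressants = -0.38),
                         tau = 0.1,
                         n_trials_per_class = c(cognitive = 2, behavioural = 3,
                                                CBT = 111, psychodynamic = 12,
                                                supportive = 10, antidepressants = 56),
                         survey_n = 10641L,
                         anxiety_prevalence_survey = 0.06,
                         condition_defs = data.frame(
                           condition = c("back_pain", "arthritis", "asthma",
                                         "diabetes", "depression"),
                           prevalence = c(0.15, 0.10, 0.07, 0.05, 0.06),
                           dw = c(0.06, 0.10, 0.04, 0.05, 0.15)),
                         sf12_anchor_points = NULL,
                         sf12_noise_sd = 4,
                         coverage_probs = c(CBT = 0.054, psychodynamic = 0.03,
                                            supportive = 0.062, antidepressants = 0.392),
                         no_treatment_severity = c(asymptomatic = 0, mild = 0.437,
                                                   moderate = 0.300, severe = 0.263),
                         severity_band_dws = c(mild = 0.030, moderate = 0.133,
                                               severe = 0.523),
                         haqi_slope = 0.01,
                         haqi_zero_intercept = 44.1,
                         n_coverage_points = 29L,
                         coverage_noise_sd = 0.05,
                         n_countries = 195L,
                         country_haqi_range = c(40, 95)) {
  if (is.null(sf12_anchor_points)) {
    # anchors on the logistic DW(s) = 1/(1 + exp(-3.112 + 0.0778 s))
    s <- c(20, 35, 50, 65, 80, 95)
    sf12_anchor_points <- data.frame(sf12 = s,
                                     dw = stats::plogis(-(-3.112 + 0.0778 * s)))
  }
  cfg <- list(seed = as.integer(seed), n_draws = as.integer(n_draws),
              true_effects = true_effects, tau = tau,
              n_trials_per_class = n_trials_per_class,
              survey_n = as.integer(survey_n),
              anxiety_prevalence_survey = anxiety_prevalence_survey,
              condition_defs = condition_defs,
              sf12_anchor_points = sf12_anchor_points,
              sf12_noise_sd = sf12_noise_sd,
              coverage_probs = coverage_probs,
              no_treatment_severity = no_treatment_severity,
              severity_band_dws = severity_band_dws,
              haqi_slope = haqi_slope,
              haqi_zero_intercept = haqi_zero_intercept,
              n_coverage_points = as.integer(n_coverage_points),
              coverage_noise_sd = coverage_noise_sd,
              n_countries = as.integer(n_countries),
              country_haqi_range = country_haqi_range)
  validate_world_config(cfg)
  structure(cfg, class = "world_config")
}

validate_world_config <- function(cfg) {
  stopifnot(cfg$n_draws >= 2, cfg$tau >= 0, cfg$survey_n >= 1)
  props <- c(cfg$anxiety_prevalence_survey, cfg$coverage_probs,
             cfg$no_treatment_severity, cfg$condition_defs$prevalence)
  if (any(props < 0) || any(props > 1)) stop("all proportions must lie in [0, 1]")
  if (abs(sum(cfg$no_treatment_severity) - 1) > 1e-9)
    stop("no_treatment_severity must sum to 1")
  dws <- c(cfg$condition_defs$dw, cfg$severity_band_dws)
  if (any(dws < 0) || any(dws >= 1)) stop("true disability weights must lie in [0, 1)")
  if (!all(names(cfg$no_treatment_severity) ==
           c("asymptomatic", "mild", "moderate", "severe")))
    stop("no_treatment_severity must be named asymptomatic/mild/moderate/severe")
  te <- cfg$true_effects
  if (all(c("cognitive", "behavioural", "CBT") %in% names(te)) &&
      abs(te[["CBT"]] - te[["cognitive"]] - te[["behavioural"]]) > 1e-9)
    stop("true CBT effect must equal cognitive + behavioural")
  invisible(cfg)
}

#' Generate a synthetic trial-effect table
#'
#' One row per intervention-versus-reference effect. Each trial's true effect
#' is the class effect plus a Normal(0, tau) between-study perturbation,
#' encoded in the arm means so that the standardised mean difference computed
#' downstream recovers it up to the small-sample correction.
#'
#' @param cfg A [world_config()].
#' @param arm_sd Common within-arm outcome SD on the symptom scale (> 0).
#' @return data.frame with columns `study_id`, `intervention_class`,
#'   `reference_class`, `mean_t`, `sd_t`, `n_t`, `mean_c`, `sd_c`, `n_c`,
#'   `follow_up_weeks`.
#' @export
generate_trial_table <- function(cfg, arm_sd = 10) {
  validate_world_config(cfg)
  if (arm_sd <= 0) stop("arm_sd must be positive")
  set.seed(stage_seed(cfg$seed, "trials"))
  classes <- names(cfg$true_effects)
  n_per <- cfg$n_trials_per_class
  if (length(n_per) == 1) n_per <- stats::setNames(rep(n_per, length(classes)), classes)
  n_per <- n_per[classes]
  rows <- lapply(classes, function(cl) {
    k <- n_per[[cl]]
    if (k == 0) return(NULL)
    theta <- cfg$true_effects[[cl]] + stats::rnorm(k, 0, cfg$tau)
    n_t <- sample(20:100, k, replace = TRUE)
    n_c <- sample(20:100, k, replace = TRUE)
    mean_c <- stats::runif(k, 15, 25)
    data.frame(intervention_class = cl,
               reference_class = "control",
               mean_t = mean_c + theta * arm_sd,
               sd_t = arm_sd, n_t = n_t,
               mean_c = mean_c, sd_c = arm_sd, n_c = n_c,
               follow_up_weeks = sample(c(8, 12, 26, 52), k, replace = TRUE))
  })
  out <- do.call(rbind, rows)
  out$study_id <- sprintf("S%03d", seq_len(nrow(out)))
  out[, c("study_id", "intervention_class", "reference_class",
          "mean_t", "sd_t", "n_t", "mean_c", "sd_c", "n_c", "follow_up_weeks")]
}

# draw a latent untreated anxiety disability weight per case from the
# 4-component mixture: point mass at 0, uniform within each severity band
draw_latent_anxiety_dw <- function(n, mix, band_dws, severe_upper = 0.85) {
  c1 <- (band_dws[["mild"]] + band_dws[["moderate"]]) / 2
  c2 <- (band_dws[["moderate"]] + band_dws[["severe"]]) / 2
  cat_idx <- sample.int(4, n, replace = TRUE, prob = mix)
  dw <- numeric(n)
  dw[cat_idx == 2] <- stats::runif(sum(cat_idx == 2), 1e-4, c1)
  dw[cat_idx == 3] <- stats::runif(sum(cat_idx == 3), c1, c2)
  dw[cat_idx == 4] <- stats::runif(sum(cat_idx == 4), c2, severe_upper)
  dw
}

#' Generate a synthetic survey with ground truth
#'
#' Each respondent carries a survey weight and stratum, condition flags drawn
#' at the configured prevalences, and (for 30-day anxiety cases) a latent
#' untreated anxiety disability weight drawn from the configured severity
#' mixture. Disability weights combine multiplicatively,
#' `1 - prod(1 - DW_i)`, and are observed through the crosswalk as a noisy
#' SF-12 composite score. Treated respondents (per `coverage_probs`) have
#' their SF-12 raised by the magnitude of their received effects times the
#' SD of untreated anxiety-case SF-12 scores, so the no-treatment
#' counterfactual is recoverable. Session-count categories follow the survey
#' instrument: `1..5`, `6-10`, `>10`, `none`, with effect-bearing therapy at
#' six or more sessions.
#'
#' @param cfg A [world_config()].
#' @return A list with `survey` (the respondent table) and `truth` (a
#'   `truth_record`: realised class effects, true no-treatment severity
#'   proportions, coverage intercept, sigma used for shifting, and
#'   per-respondent ground-truth vectors).
#' @export
generate_survey <- function(cfg) {
  validate_world_config(cfg)
  n <- cfg$survey_n
  set.seed(stage_seed(cfg$seed, "survey"))
  cw <- calibrate_crosswalk(cfg$sf12_anchor_points)

  weight <- stats::rlnorm(n, 0, 0.5)
  stratum <- rep_len(seq_len(13), n)
  anxiety <- stats::rbinom(n, 1, cfg$anxiety_prevalence_survey)

  conds <- cfg$condition_defs
  flags <- matrix(0L, nrow = n, ncol = nrow(conds),
                  dimnames = list(NULL, conds$condition))
  for (j in seq_len(nrow(conds)))
    flags[, j] <- stats::rbinom(n, 1, conds$prevalence[j])

  dw_anx <- numeric(n)
  idx_anx <- which(anxiety == 1)
  dw_anx[idx_anx] <- draw_latent_anxiety_dw(length(idx_anx),
                                            cfg$no_treatment_severity,
                                            cfg$severity_band_dws)
  dw_com <- if (nrow(conds)) 1 - apply(1 - sweep(flags, 2, conds$dw, `*`), 1, prod)
            else numeric(n)
  dw_cum <- 1 - (1 - dw_anx) * (1 - dw_com)

  s_true <- sf12_from_dw(cw, dw_cum)
  sf12_notx <- clamp(s_true + stats::rnorm(n, 0, cfg$sf12_noise_sd), 0, 100)

  # treatment uptake among anxiety cases
  cp <- cfg$coverage_probs
  psy_probs <- c(none = 1 - cp[["CBT"]] - cp[["psychodynamic"]] - cp[["supportive"]],
                 CBT = cp[["CBT"]], psychodynamic = cp[["psychodynamic"]],
                 supportive = cp[["supportive"]])
  psy <- rep("none", n)
  psy[idx_anx] <- sample(names(psy_probs), length(idx_anx),
                         replace = TRUE, prob = psy_probs)
  medication <- integer(n)
  medication[idx_anx] <- stats::rbinom(length(idx_anx), 1, cp[["antidepressants"]])
  medication[-idx_anx] <- stats::rbinom(n - length(idx_anx), 1, 0.05)

  received_effect <- ifelse(psy == "none", 0, cfg$true_effects[psy]) +
    ifelse(anxiety == 1 & medication == 1, cfg$true_effects[["antidepressants"]], 0)
  received_effect[anxiety == 0] <- 0

  sigma_gen <- stats::sd(sf12_notx[idx_anx])
  sf12_obs <- clamp(sf12_notx - received_effect * sigma_gen, 0, 100)

  # session-count categories: received therapy is >= 6 sessions; a fraction
  # of untreated respondents report sub-threshold sessions
  adequate <- c("6-10", ">10")
  sub <- c("1", "2", "3", "4", "5")
  session_col <- function(received_lab) {
    out <- rep("none", n)
    rec <- psy == received_lab
    out[rec] <- sample(adequate, sum(rec), replace = TRUE)
    dab <- !rec & stats::runif(n) < 0.05
    out[dab] <- sample(sub, sum(dab), replace = TRUE)
    out
  }
  sessions_cbt <- session_col("CBT")
  sessions_other <- session_col("psychodynamic")
  sessions_counselling <- session_col("supportive")

  survey <- data.frame(id = seq_len(n), weight = weight, stratum = stratum,
                       anxiety_30day = anxiety, sf12 = sf12_obs,
                       flags,
                       sessions_cbt = sessions_cbt,
                       sessions_other_psychotherapy = sessions_other,
                       sessions_counselling = sessions_counselling,
                       medication = medication,
                       check.names = FALSE)
  truth <- structure(list(
    true_effects = cfg$true_effects,
    no_treatment_severity = cfg$no_treatment_severity,
    haqi_zero_intercept = cfg$haqi_zero_intercept,
    sigma_sf12 = sigma_gen,
    sf12_no_treatment = sf12_notx,
    dw_anxiety_true = dw_anx,
    dw_comorbidities_true = dw_com,
    dw_cumulative_true = dw_cum), class = "truth_record")
  stopifnot(abs(sum(truth$no_treatment_severity) - 1) < 1e-12)
  list(survey = survey, truth = truth)
}

#' Generate synthetic treatment-coverage versus HAQI points
#'
#' Coverage follows the configured line
#' `clamp(haqi_slope * (HAQI - haqi_zero_intercept), 0, 1)` plus Gaussian
#' observation noise, clamped back to `[0, 1]`.
#'
#' @param cfg A [world_config()].
#' @return data.frame with columns `country`, `haqi`, `coverage`.
#' @export
generate_coverage_points <- function(cfg) {
  validate_world_config(cfg)
  if (cfg$haqi_slope <= 0) stop("haqi_slope must be positive")
  set.seed(stage_seed(cfg$seed, "coverage"))
  m <- cfg$n_coverage_points
  # coverage surveys come from countries with functioning (positive-coverage)
  # mental-health systems, i.e. HAQI above the zero-coverage intercept; points
  # below it would sit on the clamped flat segment and bias a straight-line fit
  haqi <- stats::runif(m, cfg$haqi_zero_intercept + 2, 95)
  cov0 <- clamp(cfg$haqi_slope * (haqi - cfg$haqi_zero_intercept), 0, 1)
  coverage <- clamp(cov0 + stats::rnorm(m, 0, cfg$coverage_noise_sd), 0, 1)
  data.frame(country = sprintf("W%02d", seq_len(m)), haqi = haqi,
             coverage = coverage)
}

#' Generate a synthetic country table
#'
#' Locations with a 2019 HAQI score, anxiety point prevalence, and
#' population. Super-region labels are assigned by HAQI ordering so that the
#' high-income label sits on the highest-access countries, mirroring the real
#' geography of healthcare access.
#'
#' @param cfg A [world_config()].
#' @return data.frame with columns `location_id`, `super_region`, `haqi`,
#'   `prevalence`, `population`.
#' @export
generate_country_table <- function(cfg) {
  validate_world_config(cfg)
  if (cfg$n_countries < 1) stop("n_countries must be >= 1")
  set.seed(stage_seed(cfg$seed, "countries"))
  n <- cfg$n_countries
  haqi <- stats::runif(n, cfg$country_haqi_range[1], cfg$country_haqi_range[2])
  regions <- c("sub_saharan_africa", "south_asia", "north_africa_middle_east",
               "latin_america_caribbean", "southeast_east_asia_oceania",
               "central_europe_eastern_europe_central_asia", "high_income")
  grp <- cut(rank(haqi, ties.method = "first"),
             breaks = seq(0, n, length.out = length(regions) + 1),
             labels = regions)
  data.frame(location_id = sprintf("C%03d", seq_len(n)),
             super_region = as.character(grp),
             haqi = haqi,
             prevalence = stats::runif(n, 0.02, 0.08),
             population = round(stats::rlnorm(n, log(1e7), 1)))
}

#' Write all four synthetic input tables plus a truth sidecar
#'
#' @param cfg A [world_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, a list with the four tables and the truth record.
#' @export
write_world <- function(cfg, dir) {
  validate_world_config(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trials <- generate_trial_table(cfg)
  sv <- generate_survey(cfg)
  coverage <- generate_coverage_points(cfg)
  countries <- generate_country_table(cfg)
  utils::write.csv(trials, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(sv$survey, file.path(dir, "survey.csv"), row.names = FALSE)
  utils::write.csv(coverage, file.path(dir, "coverage_points.csv"), row.names = FALSE)
  utils::write.csv(countries, file.path(dir, "countries.csv"), row.names = FALSE)
  tr <- sv$truth
  yaml::write_yaml(list(
    seed = cfg$seed,
    true_effects = as.list(tr$true_effects),
    no_treatment_severity = as.list(tr$no_treatment_severity),
    haqi_zero_intercept = tr$haqi_zero_intercept,
    sigma_sf12 = tr$sigma_sf12), file.path(dir, "truth.yaml"))
  invisible(list(trials = trials, survey = sv$survey, truth = tr,
                 coverage_points = coverage, countries = countries))
}
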