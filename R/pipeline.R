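#' Configuration for a full pipeline run
#'
#' @param trials,survey,coverage_points,countries The four input tables: each
#'   either a data.frame or a path to a CSV with a header row.
#' @param crosswalk_anchors data.frame(sf12, dw) of crosswalk anchors, or a
#'   path to a YAML file with `sf12` and `dw` lists. Defaults to the
#'   [world_config()] anchors.
#' @param health_states data.frame(state, mean, lower, upper) of the mild /
#'   moderate / severe health-state disability weights (defaults to the
#'   published anxiety values, see [health_state_set()]).
#' @param haqi_anchor `c(mean, lower, upper)` of the anchor survey's HAQI.
#' @param trim_pct Trimming proportion for the network meta-regression.
#' @param n_draws Draw count used in every stage.
#' @param sf12_noise_sd SF-12 measurement noise SD used to propagate
#'   disability-weight uncertainty.
#' @param seed Run seed; every stage derives its own substream from it.
#' @param out_dir Optional output directory; when given, all result tables
#'   plus a YAML run manifest are written there.
#' @return A list of class `run_config`.
#' @export
run_config <- function(trials, survey, coverage_points, countries,
                       crosswalk_anchors = NULL,
                       health_states = NULL,
                       haqi_anchor = c(mean = 88.0, lower = 87.5, upper = 88.5),
                       trim_pct = 0.1, n_draws = 1000, sf12_noise_sd = 4,
                       seed = 1, out_dir = NULL) {
  if (n_draws < 2) stop("n_draws must be >= 2")
  if (trim_pct < 0 || trim_pct >= 0.5) stop("trim_pct must lie in [0, 0.5)")
  if (is.null(crosswalk_anchors)) crosswalk_anchors <- world_config()$sf12_anchor_points
  if (is.character(crosswalk_anchors))
    crosswalk_anchors <- as.data.frame(yaml::read_yaml(crosswalk_anchors))
  if (is.null(health_states))
    health_states <- data.frame(state = c("mild", "moderate", "severe"),
                                mean = c(0.030, 0.133, 0.523),
                                lower = c(0.018, 0.091, 0.362),
                                upper = c(0.046, 0.186, 0.677))
  structure(list(trials = trials, survey = survey,
                 coverage_points = coverage_points, countries = countries,
                 crosswalk_anchors = crosswalk_anchors,
                 health_states = health_states, haqi_anchor = haqi_anchor,
                 trim_pct = trim_pct, n_draws = as.integer(n_draws),
                 sf12_noise_sd = sf12_noise_sd, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

read_input <- function(x, what, required) {
  path <- NULL
  if (is.character(x)) {
    path <- x
    if (!file.exists(path)) stop(what, ": file not found: ", path)
    x <- utils::read.csv(path, check.names = FALSE)
  }
  if (!is.data.frame(x)) stop(what, ": expected a data.frame or CSV path")
  miss <- setdiff(required, names(x))
  if (length(miss))
    stop(sprintf("%s%s: missing column(s) %s",
                 what, if (is.null(path)) "" else paste0(" (", path, ")"),
                 paste(miss, collapse = ", ")))
  for (cl in required) {
    bad <- which(is.na(x[[cl]]))
    if (length(bad))
      stop(sprintf("%s: NA in column '%s' at row %d", what, cl, bad[1]))
  }
  attr(x, "source_path") <- path
  x
}

#' Run the full severity-by-access pipeline
#'
#' Executes the whole chain: standardised mean differences and trimmed
#' network meta-regression on the trial table; survey treatment coverage and
#' the coverage-adjusted effect beta; SF-12 to disability-weight crosswalk,
#' comorbidity meta-regression and comorbidity correction; severity
#' distributions under the observed, no-treatment and full-coverage
#' optimal-treatment scenarios; the coverage-HAQI model and severity
#' interpolation to every country; and YLD-based averted and avoidable
#' burden aggregated to super-regions and globally. All stages share
#' `n_draws` index-aligned draws, and all randomness derives from the run
#' seed, so identical configurations reproduce identical results.
#'
#' @param cfg A [run_config()].
#' @return A list of class `result_bundle` with every intermediate and final
#'   object (see elements `pooled`, `coverage`, `beta`, `fcot_effect`,
#'   `crosswalk`, `comorbidity`, `severity` (observed / no_treatment / fcot),
#'   `haqi_model`, `interpolator`, `country_severity`, `burden`, `regions`).
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  D <- cfg$n_draws

  trials <- read_input(cfg$trials, "trial table",
                       c("study_id", "intervention_class", "mean_t", "sd_t",
                         "n_t", "mean_c", "sd_c", "n_c", "follow_up_weeks"))
  survey <- read_input(cfg$survey, "survey table",
                       c("id", "weight", "stratum", "anxiety_30day", "sf12",
                         "sessions_cbt", "sessions_other_psychotherapy",
                         "sessions_counselling", "medication"))
  cov_pts <- read_input(cfg$coverage_points, "coverage table",
                        c("haqi", "coverage"))
  countries <- read_input(cfg$countries, "country table",
                          c("location_id", "super_region", "haqi",
                            "prevalence", "population"))

  # 1. treatment effects
  effects <- compute_smd(select_longest_followup(trials))
  pooled <- fit_trimmed_network(effects, trim_pct = cfg$trim_pct,
                                n_draws = D,
                                seed = stage_seed(cfg$seed, "pooling"))
  cls <- c("CBT", "psychodynamic", "supportive", "antidepressants")
  widened <- lapply(stats::setNames(cls, cls), function(cl)
    widen_by_heterogeneity(pooled, cl, seed = cfg$seed))
  fcot_effect <- combine_optimal(widened$CBT, widened$antidepressants)
  fcot_effect$label <- "full_coverage_optimal_treatment"

  # 2. coverage and beta
  assignment <- assign_received_treatments(survey)
  coverage <- estimate_coverage(assignment, survey, seed = cfg$seed)
  beta <- coverage_adjusted_effect(assignment, survey,
                                   lapply(widened, `[[`, "draws"))

  # 3. disability weights
  anx <- survey[survey$anxiety_30day == 1, , drop = FALSE]
  sigma <- stats::sd(anx$sf12)
  cw <- calibrate_crosswalk(cfg$crosswalk_anchors, sf12_sd = sigma)
  dw_cum <- respondent_dw_draws(survey$sf12, cw, D, cfg$sf12_noise_sd,
                                seed = cfg$seed)
  id_cols <- c("id", "weight", "stratum", "anxiety_30day", "sf12",
               "sessions_cbt", "sessions_other_psychotherapy",
               "sessions_counselling", "medication")
  cond_cols <- setdiff(names(survey), id_cols)
  anx_ix <- which(survey$anxiety_30day == 1)
  if (length(cond_cols) == 0) {
    # no comorbid conditions recorded: nothing to correct for
    comorbidity <- NULL
    dw_com <- matrix(0, length(anx_ix), D)
  } else {
    flags <- cbind(anxiety = survey$anxiety_30day,
                   as.matrix(survey[, cond_cols, drop = FALSE]) * 1)
    comorbidity <- fit_comorbidity_model(dw_cum, flags, seed = cfg$seed)
    dw_com <- predict_comorbid_dw(comorbidity, flags[anx_ix, , drop = FALSE])
  }
  dw_anx <- comorbidity_correct(dw_cum[anx_ix, , drop = FALSE], dw_com)

  # 4. scenarios
  hs <- health_state_set(cfg$health_states, n_draws = D, seed = cfg$seed)
  cuts <- severity_cutoffs(hs)
  s_anx <- sf12_from_dw(cw, dw_anx)
  obs <- shift_scenario(s_anx, 0, sigma, cw)
  notx <- shift_scenario(s_anx, beta$draws, sigma, cw)
  fcot <- shift_scenario(notx$sf12, -fcot_effect$draws, sigma, cw)
  w_anx <- anx$weight
  severity <- list(
    observed = estimate_distribution(obs$dw, w_anx, cuts, hs),
    no_treatment = estimate_distribution(notx$dw, w_anx, cuts, hs),
    fcot = estimate_distribution(fcot$dw, w_anx, cuts, hs))

  # 5. grading by healthcare access
  haqi_model <- fit_coverage_haqi(cov_pts, n_draws = D,
                                  seed = stage_seed(cfg$seed, "haqi"))
  set.seed(stage_seed(cfg$seed, "haqi_anchor"))
  ha <- cfg$haqi_anchor
  anchor_draws <- stats::rnorm(D, ha[["mean"]],
                               (ha[["upper"]] - ha[["lower"]]) / (2 * stats::qnorm(0.975)))
  interp <- build_interpolator(severity$observed, severity$no_treatment,
                               anchor_draws, haqi_model$haqi0, seed = cfg$seed)
  country_severity <- do.call(rbind, lapply(seq_len(nrow(countries)), function(i) {
    sd_i <- severity_at_haqi(interp, countries$haqi[i])
    p <- summarise_draws(t(sd_i$proportions))
    d <- summarise_draws(sd_i$dw)
    cbind(data.frame(location_id = countries$location_id[i],
                     haqi = countries$haqi[i]),
          data.frame(sequela = rownames(p), p, row.names = NULL),
          dw = d[["mean"]], dw_lower = d[["lower"]], dw_upper = d[["upper"]])
  }))

  # 6. burden
  burden <- country_burden(countries, interp, severity$fcot)
  regions <- aggregate_regions(burden)

  bundle <- structure(list(
    config = cfg, effects = effects, pooled = pooled, widened = widened,
    fcot_effect = fcot_effect, assignment = assignment, coverage = coverage,
    beta = beta, crosswalk = cw, comorbidity = comorbidity,
    dw_anxiety = dw_anx,
    scenario_dws = list(observed = obs$dw, no_treatment = notx$dw, fcot = fcot$dw),
    severity = severity, haqi_model = haqi_model,
    interpolator = interp, country_severity = country_severity,
    burden = burden, regions = regions), class = "result_bundle")
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

#' Summarise the three scenario severity distributions as a table
#' @param bundle A `result_bundle`.
#' @return data.frame: scenario x sequela proportions (mean, lower, upper)
#'   plus the sequela-weighted DW.
#' @export
scenario_table <- function(bundle) {
  do.call(rbind, lapply(names(bundle$severity), function(sc) {
    sd_ <- bundle$severity[[sc]]
    p <- summarise_draws(t(sd_$proportions))
    d <- summarise_draws(sd_$dw)
    cbind(data.frame(scenario = sc, sequela = rownames(p)),
          p, dw = d[["mean"]], dw_lower = d[["lower"]], dw_upper = d[["upper"]],
          row.names = NULL)
  }))
}

write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(x, f) utils::write.csv(x, file.path(dir, f), row.names = FALSE)
  pooled_tab <- as.data.frame(bundle$pooled$classes)
  wcsv(pooled_tab, "pooled_effect_draws.csv")
  wcsv(bundle$coverage, "coverage.csv")
  wcsv(data.frame(draw = seq_along(bundle$beta$draws), beta = bundle$beta$draws),
       "beta_draws.csv")
  wcsv(scenario_table(bundle), "severity_scenarios.csv")
  wcsv(bundle$country_severity, "country_severity.csv")
  wcsv(bundle$regions$fractions, "burden_regions.csv")
  cb <- bundle$burden
  frac <- function(M) summarise_draws(M)
  ctab <- cbind(cb$countries,
                averted = frac(cb$averted)$mean,
                avoidable_brc = frac(cb$avoidable_brc)$mean,
                avoidable_fcot = frac(cb$avoidable_fcot)$mean)
  wcsv(ctab, "burden_countries.csv")
  cfg <- bundle$config
  manifest <- list(
    seed = cfg$seed, n_draws = cfg$n_draws, trim_pct = cfg$trim_pct,
    package_version = as.character(utils::packageVersion("anxburden")),
    r_version = R.version.string,
    inputs = lapply(cfg[c("trials", "survey", "coverage_points", "countries")],
                    function(x) {
                      if (is.character(x))
                        list(path = x, md5 = unname(tools::md5sum(x)))
                      else list(inline_rows = nrow(x))
                    }))
  yaml::write_yaml(manifest, file.path(dir, "run_manifest.yaml"))
  invisible(dir)
}

#' @export
print.result_bundle <- function(x, ...) {
  cat("Severity-by-access pipeline run (", x$config$n_draws, " draws)\n", sep = "")
  print(x$beta)
  print(x$fcot_effect)
  for (sc in names(x$severity)) {
    cat("\nscenario:", sc, "\n")
    print(x$severity[[sc]])
  }
  print(x$haqi_model)
  g <- x$regions$fractions[x$regions$fractions$region == "global", ]
  cat(sprintf("\nglobal averted %.1f%%, avoidable (BRC) %.1f%%, avoidable (FCOT) %.1f%%\n",
              100 * g$averted, 100 * g$avoidable_brc, 100 * g$avoidable_fcot))
  invisible(x)
}
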