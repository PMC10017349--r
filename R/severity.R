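#' Draws of the mild/moderate/severe anxiety health-state disability weights
#'
#' Reconstructs draw vectors from published (mean, 95% UI) triples via
#' moment-matched beta distributions ([beta_draws_from_ui()]); each state's
#' draws are sorted so the severity ordering mild < moderate < severe holds
#' draw-wise. Defaults are the anxiety health-state weights: mild 0.030
#' (0.018-0.046), moderate 0.133 (0.091-0.186), severe 0.523 (0.362-0.677).
#'
#' @param specs data.frame with columns `state` (`mild`, `moderate`,
#'   `severe`), `mean`, `lower`, `upper`.
#' @param n_draws Number of draws.
#' @param seed Integer seed.
#' @return An object of class `health_state_set`: list of sorted draw
#'   vectors `mild`, `moderate`, `severe`.
#' @export
health_state_set <- function(specs = data.frame(
                               state = c("mild", "moderate", "severe"),
                               mean = c(0.030, 0.133, 0.523),
                               lower = c(0.018, 0.091, 0.362),
                               upper = c(0.046, 0.186, 0.677)),
                             n_draws = 1000, seed = 1) {
  stopifnot(all(c("mild", "moderate", "severe") %in% specs$state))
  set.seed(stage_seed(seed, "health_states"))
  hs <- lapply(c(mild = "mild", moderate = "moderate", severe = "severe"),
               function(st) {
                 r <- specs[specs$state == st, ]
                 beta_draws_from_ui(r$mean, r$lower, r$upper, n_draws)
               })
  if (any(hs$mild >= hs$moderate) || any(hs$moderate >= hs$severe))
    stop("health states must satisfy mild < moderate < severe draw-wise")
  structure(hs, class = "health_state_set")
}

#' Per-draw sequela cutoffs from health-state disability weights
#'
#' The mild/moderate boundary is the arithmetic midpoint of the mild and
#' moderate health-state weights; the moderate/severe boundary the midpoint
#' of the moderate and severe weights, per draw.
#'
#' @param hs A `health_state_set`.
#' @return data.frame with per-draw columns `lower`, `upper`.
#' @export
severity_cutoffs <- function(hs) {
  stopifnot(inherits(hs, "health_state_set"))
  data.frame(lower = (hs$mild + hs$moderate) / 2,
             upper = (hs$moderate + hs$severe) / 2)
}

#' Sort disability weights into severity categories
#'
#' A weight of exactly 0 is asymptomatic; weights up to the lower cutoff are
#' mild, up to the upper cutoff moderate, and above it severe. A weight
#' exactly at a cutoff takes the lower category.
#'
#' @param dw Numeric vector of disability weights in `[0, 1)`.
#' @param cutoffs Numeric `c(lower, upper)` pair.
#' @return Factor with levels asymptomatic, mild, moderate, severe.
#' @export
categorize_dw <- function(dw, cutoffs) {
  stopifnot(length(cutoffs) == 2, cutoffs[1] <= cutoffs[2])
  if (any(dw < 0) || any(dw >= 1)) stop("disability weights must lie in [0, 1)")
  idx <- 1L + (dw > 0) + (dw > cutoffs[1]) + (dw > cutoffs[2])
  factor(c("asymptomatic", "mild", "moderate", "severe")[idx],
         levels = c("asymptomatic", "mild", "moderate", "severe"))
}

# category index matrix (0..3) for a respondents x draws DW matrix with
# per-draw cutoffs
categorize_matrix <- function(dw_draws, cutoffs) {
  lo <- matrix(cutoffs$lower, nrow(dw_draws), ncol(dw_draws), byrow = TRUE)
  hi <- matrix(cutoffs$upper, nrow(dw_draws), ncol(dw_draws), byrow = TRUE)
  (dw_draws > 0) + (dw_draws > lo) + (dw_draws > hi)
}

#' Survey-weighted severity distribution and sequela-weighted DW
#'
#' Per draw: the survey-weighted proportion of respondents in each severity
#' category, and the sequela-weighted disability weight
#' `sum(proportion * health-state DW)` with the asymptomatic weight fixed
#' at 0.
#'
#' @param dw_draws Matrix (respondents x draws) of anxiety-specific
#'   disability weights.
#' @param weights Survey weights (one per respondent, > 0).
#' @param cutoffs Per-draw cutoffs from [severity_cutoffs()].
#' @param hs The `health_state_set` used for the sequela weighting.
#' @return An object of class `severity_distribution`: `proportions`
#'   (draws x 4 matrix), `dw` (sequela-weighted DW draws), `hs`.
#' @export
estimate_distribution <- function(dw_draws, weights, cutoffs, hs) {
  if (!is.matrix(dw_draws) || nrow(dw_draws) == 0) stop("empty input")
  stopifnot(length(weights) == nrow(dw_draws), all(weights > 0),
            nrow(cutoffs) == ncol(dw_draws))
  idx <- categorize_matrix(dw_draws, cutoffs)
  W <- sum(weights)
  P <- vapply(0:3, function(k) colSums(weights * (idx == k)) / W,
              numeric(ncol(dw_draws)))
  P <- matrix(P, ncol = 4,
              dimnames = list(NULL, c("asymptomatic", "mild", "moderate", "severe")))
  new_severity_distribution(P, hs)
}

new_severity_distribution <- function(P, hs) {
  dw <- P[, "mild"] * hs$mild + P[, "moderate"] * hs$moderate +
    P[, "severe"] * hs$severe
  structure(list(proportions = P, dw = dw, hs = hs),
            class = "severity_distribution")
}

#' @export
print.severity_distribution <- function(x, ...) {
  cat("Severity distribution over", nrow(x$proportions), "draws\n")
  s <- summarise_draws(t(x$proportions))
  print(round(100 * s, 1))
  d <- summarise_draws(x$dw)
  cat(sprintf("sequela-weighted DW: %.3f (95%% UI %.3f to %.3f)\n",
              d["mean"], d["lower"], d["upper"]))
  invisible(x)
}

#' Shift respondent SF-12 equivalents into a counterfactual scenario
#'
#' Scenario shifts act on the SF-12 scale: per draw, the shift is the
#' scenario effect draw times sigma (the SD of SF-12 scores among anxiety
#' cases), added to each respondent's SF-12 equivalent. A negative effect
#' lowers SF-12 (health worsens, as in the no-treatment scenario); the
#' full-coverage optimal-treatment scenario subtracts the (negative) optimal
#' effect from the no-treatment scores, raising them. Scores are clamped to
#' `[0, 100]` and mapped back to disability weights with the floor at zero
#' realised at the top of the scale (a respondent pushed to SF-12 = 100
#' needs no further treatment and carries no residual disability).
#'
#' @param sf12_draws Matrix (respondents x draws) of SF-12 equivalents, e.g.
#'   `sf12_from_dw(cw, dw_anxiety_draws)`.
#' @param effect_draws Draw vector of the scenario effect (SMD scale);
#'   length must match `ncol(sf12_draws)`. Use 0 for the observed scenario,
#'   beta for no-treatment, and `-` the optimal effect applied on top of the
#'   no-treatment scores for full coverage optimal treatment.
#' @param sf12_sd Sigma, the SD of SF-12 scores among anxiety cases (> 0).
#' @param cw The `crosswalk`.
#' @return List with `sf12` (shifted score matrix) and `dw` (disability
#'   weights floored at zero).
#' @export
shift_scenario <- function(sf12_draws, effect_draws, sf12_sd, cw) {
  if (is.null(sf12_sd) || !is.numeric(sf12_sd) || sf12_sd <= 0)
    stop("missing or non-positive sigma (sf12_sd)")
  if (inherits(effect_draws, "effect_draws")) effect_draws <- effect_draws$draws
  if (length(effect_draws) == 1)
    effect_draws <- rep(effect_draws, ncol(sf12_draws))
  stopifnot(length(effect_draws) == ncol(sf12_draws))
  shift <- matrix(effect_draws * sf12_sd, nrow(sf12_draws), ncol(sf12_draws),
                  byrow = TRUE)
  s <- clamp(sf12_draws + shift, 0, 100)
  list(sf12 = s, dw = dw_from_sf12(cw, s))
}
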