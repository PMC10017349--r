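#' Derive received effect-bearing treatments from survey service-use items
#'
#' A therapy counts as received when six or more sessions were reported
#' (session categories `6-10` or `>10`). Psychotherapies follow the
#' hierarchy CBT > other psychotherapy > counselling: a lower class counts
#' only when no higher class was received. Other psychotherapy carries the
#' psychodynamic-therapy effect and counselling the supportive-therapy
#' effect; medication carries the antidepressant effect and is independent
#' of psychotherapy.
#'
#' @param survey Respondent table with columns `id`, `anxiety_30day`,
#'   `sessions_cbt`, `sessions_other_psychotherapy`, `sessions_counselling`
#'   (categories `none`, `1`..`5`, `6-10`, `>10`) and `medication` (0/1).
#' @return data.frame with one row per 30-day anxiety case: `id` and logical
#'   columns `CBT`, `psychodynamic`, `supportive`, `antidepressants`.
#' @export
assign_received_treatments <- function(survey) {
  req <- c("id", "anxiety_30day", "sessions_cbt",
           "sessions_other_psychotherapy", "sessions_counselling", "medication")
  stopifnot(all(req %in% names(survey)))
  valid <- c("none", "1", "2", "3", "4", "5", "6-10", ">10")
  cats <- c(survey$sessions_cbt, survey$sessions_other_psychotherapy,
            survey$sessions_counselling)
  bad <- setdiff(unique(cats), valid)
  if (length(bad)) stop("unknown session category: ", paste(bad, collapse = ", "))
  anx <- survey[survey$anxiety_30day == 1, , drop = FALSE]
  adequate <- c("6-10", ">10")
  cbt <- anx$sessions_cbt %in% adequate
  other <- anx$sessions_other_psychotherapy %in% adequate & !cbt
  couns <- anx$sessions_counselling %in% adequate & !cbt & !other
  data.frame(id = anx$id,
             CBT = cbt, psychodynamic = other, supportive = couns,
             antidepressants = anx$medication == 1)
}

#' Survey-weighted treatment coverage with bootstrap uncertainty
#'
#' Coverage of each treatment class is the survey-weighted proportion of
#' anxiety cases receiving it. The 95% UI comes from a stratified bootstrap
#' of respondents (resampled with replacement within strata), summarised as
#' ranked replicate values.
#'
#' @param assignment Output of [assign_received_treatments()].
#' @param survey The respondent table (provides `weight` and `stratum`).
#' @param n_boot Number of bootstrap replicates.
#' @param seed Integer seed.
#' @return data.frame with columns `class`, `coverage`, `lower`, `upper`.
#' @export
estimate_coverage <- function(assignment, survey, n_boot = 1000, seed = 1) {
  if (nrow(assignment) == 0) stop("empty survey: no anxiety cases")
  m <- merge(assignment, survey[, c("id", "weight", "stratum")], by = "id")
  cls <- c("CBT", "psychodynamic", "supportive", "antidepressants")
  A <- as.matrix(m[, cls]) * 1
  w <- m$weight
  point <- colSums(A * w) / sum(w)
  set.seed(stage_seed(seed, "coverage_boot"))
  strata <- split(seq_len(nrow(m)), m$stratum)
  reps <- matrix(NA_real_, n_boot, length(cls), dimnames = list(NULL, cls))
  for (b in seq_len(n_boot)) {
    idx <- unlist(lapply(strata, function(ix)
      ix[sample.int(length(ix), length(ix), replace = TRUE)]), use.names = FALSE)
    reps[b, ] <- colSums(A[idx, , drop = FALSE] * w[idx]) / sum(w[idx])
  }
  ui <- summarise_draws(reps, margin = 2)
  data.frame(class = cls, coverage = unname(point),
             lower = ui$lower, upper = ui$upper, row.names = NULL)
}

#' Coverage-adjusted population treatment effect (beta)
#'
#' For every draw, each anxiety case contributes the sum of the class-effect
#' draws over their received treatments (zero if untreated); beta is the
#' survey-weighted mean of these per-respondent effects. This is the
#' population treatment effect actually realised given observed uptake.
#'
#' @param assignment Output of [assign_received_treatments()].
#' @param survey The respondent table (provides `weight`).
#' @param class_draws Named list of draw vectors for `CBT`,
#'   `psychodynamic`, `supportive`, `antidepressants` (e.g. widened draws
#'   from [widen_by_heterogeneity()]), all the same length.
#' @return An `effect_draws` object holding the beta draws.
#' @export
coverage_adjusted_effect <- function(assignment, survey, class_draws) {
  cls <- c("CBT", "psychodynamic", "supportive", "antidepressants")
  if (!all(cls %in% names(class_draws)))
    stop("missing class draws: ", paste(setdiff(cls, names(class_draws)), collapse = ", "))
  dlen <- unique(vapply(class_draws[cls], length, integer(1)))
  if (length(dlen) != 1) stop("class draw vectors differ in length")
  m <- merge(assignment, survey[, c("id", "weight")], by = "id")
  A <- as.matrix(m[, cls]) * 1                      # n_anx x 4
  D <- do.call(rbind, class_draws[cls])             # 4 x n_draws
  E <- A %*% D                                      # per-respondent effect draws
  beta <- drop(crossprod(E, m$weight)) / sum(m$weight)
  structure(list(label = "coverage_adjusted", draws = beta,
                 per_respondent = E, ids = m$id), class = "effect_draws")
}
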