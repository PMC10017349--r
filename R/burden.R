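#' Years lived with disability for one location
#'
#' `YLD_d = prevalence * population * dw_d` (absolute person-years); the
#' rate variant divides out the population.
#'
#' @param prevalence Anxiety point prevalence (proportion).
#' @param population Population (persons).
#' @param dw_draws Draw vector of the sequela-weighted disability weight.
#' @return Draw vector of absolute YLDs.
#' @export
compute_ylds <- function(prevalence, population, dw_draws) {
  stopifnot(prevalence >= 0, prevalence <= 1, population > 0,
            all(dw_draws >= 0), all(dw_draws <= 1))
  prevalence * population * dw_draws
}

#' Fraction of burden averted by available treatment
#'
#' `(YLD_no_treatment - YLD_observed) / YLD_no_treatment` per draw, with 0
#' where the no-treatment YLDs are 0.
#'
#' @param ylds_notx,ylds_observed Aligned YLD draw vectors (or matrices).
#' @return Fraction draws, same shape.
#' @export
averted_fraction <- function(ylds_notx, ylds_observed) {
  stopifnot(length(ylds_notx) == length(ylds_observed))
  out <- ifelse(ylds_notx == 0, 0, (ylds_notx - ylds_observed) / ylds_notx)
  if (is.matrix(ylds_notx)) dim(out) <- dim(ylds_notx)
  out
}

#' Fraction of burden avoidable by moving to a better scenario
#'
#' `(YLD_observed - YLD_scenario) / YLD_observed` per draw, with 0 where
#' the observed YLDs are 0. The scenario is best routine care (severity at
#' the highest observed HAQI) or full coverage optimal treatment.
#'
#' @param ylds_observed,ylds_scenario Aligned YLD draw vectors (or matrices).
#' @return Fraction draws, same shape.
#' @export
avoidable_fraction <- function(ylds_observed, ylds_scenario) {
  stopifnot(length(ylds_observed) == length(ylds_scenario))
  out <- ifelse(ylds_observed == 0, 0,
                (ylds_observed - ylds_scenario) / ylds_observed)
  if (is.matrix(ylds_observed)) dim(out) <- dim(ylds_observed)
  out
}

#' Per-country burden under all four scenarios
#'
#' For every country: observed YLDs use the severity distribution at the
#' country's HAQI; no-treatment YLDs use the no-treatment distribution
#' (the plateau); best-routine-care YLDs use the distribution at the highest
#' observed HAQI in the table; full-coverage-optimal-treatment YLDs use the
#' FCOT distribution. Averted and avoidable fractions follow.
#'
#' @param countries data.frame with `location_id`, `super_region`, `haqi`,
#'   `prevalence`, `population`.
#' @param interp A `severity_interpolator`.
#' @param fcot `severity_distribution` under full coverage optimal treatment.
#' @return An object of class `burden_result`: the country table plus draw
#'   matrices (countries x draws) `ylds_observed`, `ylds_notx`, `ylds_brc`,
#'   `ylds_fcot`, `averted`, `avoidable_brc`, `avoidable_fcot`, and
#'   `averted_ylds`.
#' @export
country_burden <- function(countries, interp, fcot) {
  req <- c("location_id", "super_region", "haqi", "prevalence", "population")
  stopifnot(all(req %in% names(countries)))
  if (any(is.na(countries$super_region) | countries$super_region == ""))
    stop("unlabelled country: every location needs a super_region")
  D <- length(interp$haqi0)
  n <- nrow(countries)
  dw_notx <- interp$notx$dw
  dw_brc <- severity_at_haqi(interp, max(countries$haqi))$dw
  dw_fcot <- fcot$dw
  mk <- function() matrix(NA_real_, n, D, dimnames = list(countries$location_id, NULL))
  ylds_obs <- mk(); ylds_notx <- mk(); ylds_brc <- mk(); ylds_fcot <- mk()
  for (i in seq_len(n)) {
    dw_i <- severity_at_haqi(interp, countries$haqi[i])$dw
    ylds_obs[i, ] <- compute_ylds(countries$prevalence[i], countries$population[i], dw_i)
    ylds_notx[i, ] <- compute_ylds(countries$prevalence[i], countries$population[i], dw_notx)
    ylds_brc[i, ] <- compute_ylds(countries$prevalence[i], countries$population[i], dw_brc)
    ylds_fcot[i, ] <- compute_ylds(countries$prevalence[i], countries$population[i], dw_fcot)
  }
  structure(list(countries = countries,
                 ylds_observed = ylds_obs, ylds_notx = ylds_notx,
                 ylds_brc = ylds_brc, ylds_fcot = ylds_fcot,
                 averted = averted_fraction(ylds_notx, ylds_obs),
                 averted_ylds = ylds_notx - ylds_obs,
                 avoidable_brc = avoidable_fraction(ylds_obs, ylds_brc),
                 avoidable_fcot = avoidable_fraction(ylds_obs, ylds_fcot),
                 remaining = ifelse(ylds_notx == 0, 1, ylds_fcot / ylds_notx)),
            class = "burden_result")
}

#' Aggregate country burden to super-regions and globally
#'
#' Fractions are aggregated as population-weighted means of country
#' fractions per draw; absolute YLDs are summed.
#'
#' @param burden A `burden_result` from [country_burden()].
#' @return List with `fractions` (data.frame: region x measure summaries)
#'   and `draws` (per-region draw matrices for `averted`, `avoidable_brc`,
#'   `avoidable_fcot`) and `ylds` (summed YLD draws per region and scenario).
#' @export
aggregate_regions <- function(burden) {
  stopifnot(inherits(burden, "burden_result"))
  ct <- burden$countries
  regions <- c(sort(unique(ct$super_region)), "global")
  idx_of <- function(r) if (r == "global") seq_len(nrow(ct)) else which(ct$super_region == r)
  agg_frac <- function(M, ix) {
    w <- ct$population[ix]
    drop(crossprod(M[ix, , drop = FALSE], w)) / sum(w)
  }
  measures <- c("averted", "avoidable_brc", "avoidable_fcot", "remaining")
  draws <- lapply(stats::setNames(measures, measures), function(m) {
    t(vapply(regions, function(r) agg_frac(burden[[m]], idx_of(r)),
             numeric(ncol(burden[[m]]))))
  })
  ylds <- lapply(stats::setNames(c("ylds_observed", "ylds_notx", "ylds_brc", "ylds_fcot"),
                                 c("observed", "no_treatment", "brc", "fcot")),
                 function(m) {
    t(vapply(regions, function(r) colSums(burden[[m]][idx_of(r), , drop = FALSE]),
             numeric(ncol(burden[[m]]))))
  })
  tab <- do.call(rbind, lapply(seq_along(regions), function(i) {
    row <- data.frame(region = regions[i])
    for (m in measures) {
      s <- summarise_draws(draws[[m]][i, ])
      row[[m]] <- s[["mean"]]
      row[[paste0(m, "_lower")]] <- s[["lower"]]
      row[[paste0(m, "_upper")]] <- s[["upper"]]
    }
    row
  }))
  list(fractions = tab, draws = draws, ylds = ylds, regions = regions)
}
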