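#' Regress treatment coverage on the Healthcare Access and Quality Index
#'
#' Fits both a linear and a logit relationship between minimally-adequate
#' treatment coverage and the HAQI, keeps the form with the smaller
#' root-mean-square error on the natural (proportion) scale, and locates the
#' zero-coverage intercept HAQI0 per coefficient draw (linear form:
#' `-intercept/slope`; logit form, which has no exact zero: the HAQI where
#' fitted coverage falls to 1e-3). HAQI0 draws are clamped to `[0, 100]`.
#'
#' @param points data.frame with columns `haqi` and `coverage`; at least 3
#'   points spanning at least 10 HAQI units.
#' @param n_draws Number of coefficient draws.
#' @param seed Integer seed.
#' @return An object of class `coverage_haqi_model`: `form`, `coef`,
#'   `rmse` (named, both forms), `haqi0` draws, and the fitted `lm`.
#' @export
fit_coverage_haqi <- function(points, n_draws = 1000, seed = 1) {
  stopifnot(all(c("haqi", "coverage") %in% names(points)))
  if (nrow(points) < 2) stop("need at least 2 coverage points")
  if (diff(range(points$haqi)) < 10) stop("points must span at least 10 HAQI units")
  lin <- stats::lm(coverage ~ haqi, data = points)
  rmse_lin <- sqrt(mean(stats::residuals(lin)^2))
  lp <- stats::qlogis(clamp(points$coverage, 1e-4, 1 - 1e-4))
  lgt <- stats::lm(lp ~ haqi, data = points)
  rmse_lgt <- sqrt(mean((stats::plogis(stats::fitted(lgt)) - points$coverage)^2))
  form <- if (rmse_lin <= rmse_lgt) "linear" else "logit"
  fit <- if (form == "linear") lin else lgt
  co <- stats::coef(fit)
  if (co[2] <= 0) stop("coverage not increasing in HAQI")
  V <- suppressWarnings(stats::vcov(fit))  # perfect fits have no residual df
  if (any(!is.finite(V))) V <- matrix(0, 2, 2)   # saturated fit: no residual df
  set.seed(stage_seed(seed, "haqi_model"))
  cd <- MASS::mvrnorm(n_draws, co, V)
  cd <- matrix(cd, ncol = 2)
  slope_ok <- cd[, 2] > 0
  if (!all(slope_ok)) cd[!slope_ok, 2] <- co[2]    # degenerate tail draws
  haqi0 <- if (form == "linear") -cd[, 1] / cd[, 2]
           else (stats::qlogis(1e-3) - cd[, 1]) / cd[, 2]
  structure(list(form = form, coef = co,
                 rmse = c(linear = rmse_lin, logit = rmse_lgt),
                 coef_draws = cd, haqi0 = clamp(haqi0, 0, 100), fit = fit),
            class = "coverage_haqi_model")
}

#' @export
print.coverage_haqi_model <- function(x, ...) {
  s <- summarise_draws(x$haqi0)
  cat(sprintf("coverage ~ HAQI: %s form selected (RMSE %.4f vs %.4f)\n",
              x$form, min(x$rmse), max(x$rmse)))
  cat(sprintf("zero-coverage intercept HAQI0 = %.1f (95%% UI %.1f to %.1f)\n",
              s["mean"], s["lower"], s["upper"]))
  invisible(x)
}

#' Build the severity-by-HAQI linear interpolator
#'
#' Holds the anchor severity distribution (observed at the anchor survey's
#' HAQI) and the no-treatment distribution (attained at HAQI0 and below),
#' with draw vectors of both HAQI locations paired by index. Draw pairs
#' where the anchor HAQI does not exceed HAQI0 are resampled from the
#' remaining draws so interpolation stays well defined.
#'
#' @param anchor,notx `severity_distribution` objects with equal draw counts.
#' @param haqi_anchor Draw vector of the anchor HAQI (e.g. 88.0, UI
#'   87.5-88.5).
#' @param haqi0 Draw vector of the zero-coverage intercept from
#'   [fit_coverage_haqi()].
#' @param seed Integer seed for the resampling.
#' @return An object of class `severity_interpolator`.
#' @export
build_interpolator <- function(anchor, notx, haqi_anchor, haqi0, seed = 1) {
  stopifnot(inherits(anchor, "severity_distribution"),
            inherits(notx, "severity_distribution"))
  D <- nrow(anchor$proportions)
  if (nrow(notx$proportions) != D || length(haqi_anchor) != D ||
      length(haqi0) != D)
    stop("draw count mismatch between distributions and HAQI draws")
  set.seed(stage_seed(seed, "interpolator"))
  if (!any(haqi_anchor > haqi0))
    stop("anchor HAQI does not exceed HAQI0 in any draw")
  bad <- which(haqi_anchor <= haqi0)
  tries <- 0
  while (length(bad) > 0 && tries < 100) {
    haqi0[bad] <- sample(haqi0[haqi_anchor > haqi0], length(bad), replace = TRUE)
    haqi_anchor[bad] <- sample(haqi_anchor, length(bad), replace = TRUE)
    bad <- which(haqi_anchor <= haqi0)
    tries <- tries + 1
  }
  if (length(bad)) stop("could not resample HAQI draw pairs into order")
  structure(list(anchor = anchor, notx = notx,
                 haqi_anchor = haqi_anchor, haqi0 = haqi0),
            class = "severity_interpolator")
}

#' Severity distribution at an arbitrary HAQI score
#'
#' Per draw and per sequela, proportions are linear in HAQI between
#' (HAQI0, no-treatment proportion) and (anchor HAQI, anchor proportion).
#' At and below HAQI0 proportions plateau at the no-treatment distribution;
#' above the anchor they are linearly extrapolated, clamped to `[0, 1]` and
#' renormalised to sum to one. The sequela-weighted disability weight is
#' recomputed from the resulting proportions.
#'
#' @param interp A `severity_interpolator`.
#' @param haqi HAQI score in `[0, 100]`.
#' @return A `severity_distribution` at that HAQI.
#' @export
severity_at_haqi <- function(interp, haqi) {
  stopifnot(inherits(interp, "severity_interpolator"),
            haqi >= 0, haqi <= 100)
  t <- (haqi - interp$haqi0) / (interp$haqi_anchor - interp$haqi0)
  t <- pmax(t, 0)                                  # plateau at and below HAQI0
  Pn <- interp$notx$proportions
  Pa <- interp$anchor$proportions
  P <- Pn + t * (Pa - Pn)
  Pc <- clamp(P, 0, 1)
  # interpolation between simplexes already sums to one; renormalise only the
  # rows that extrapolation pushed out of [0, 1] and clamping altered
  changed <- rowSums(abs(Pc - P)) > 0
  if (any(changed))
    Pc[changed, ] <- Pc[changed, , drop = FALSE] / rowSums(Pc[changed, , drop = FALSE])
  new_severity_distribution(Pc, interp$anchor$hs)
}
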