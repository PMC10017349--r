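#' Calibrate an invertible SF-12 to disability-weight crosswalk
#'
#' Fits a strictly decreasing logistic curve
#' \deqn{DW(s) = 1 / (1 + \exp(a + b s)), \quad b > 0}
#' through anchor pairs of (SF-12 composite score, disability weight) by
#' least squares on the disability-weight scale, starting from the exact
#' logit-linear solution. The closed-form inverse
#' \eqn{s(DW) = -(\mathrm{logit}(DW) + a)/b} makes the map invertible to
#' machine precision, which the scenario machinery relies on.
#'
#' @param anchors data.frame with numeric columns `sf12` (0-100) and `dw`
#'   (in (0,1)); disability weights must be strictly decreasing in SF-12.
#'   At least three anchors are required.
#' @param sf12_sd Optional SD of SF-12 scores among respondents with the
#'   disorder (sigma), stored for scenario shifts.
#' @return An object of class `crosswalk` with elements `a`, `b`,
#'   `anchors`, `sf12_sd`.
#' @examples
#' cw <- calibrate_crosswalk(data.frame(sf12 = c(20, 50, 80),
#'                                      dw = c(0.8, 0.3, 0.05)))
#' cw_sf12(cw, cw_dw(cw, 50))  # 50, round trip
#' @export
calibrate_crosswalk <- function(anchors, sf12_sd = NULL) {
  stopifnot(is.data.frame(anchors), all(c("sf12", "dw") %in% names(anchors)))
  anchors <- anchors[order(anchors$sf12), ]
  if (nrow(anchors) < 3) stop("need at least 3 anchor pairs")
  if (any(anchors$dw <= 0) || any(anchors$dw >= 1))
    stop("anchor disability weights must lie in (0, 1)")
  if (any(diff(anchors$dw) >= 0))
    stop("anchors must be strictly monotone: DW decreasing in SF-12")
  # exact on the logit scale when the anchors lie on a logistic curve
  lf <- stats::lm(stats::qlogis(dw) ~ sf12, data = anchors)
  start <- c(a = -unname(stats::coef(lf)[1]), b = -unname(stats::coef(lf)[2]))
  ss <- function(p) sum((anchors$dw - stats::plogis(-(p[1] + p[2] * anchors$sf12)))^2)
  opt <- stats::optim(start, ss, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  p <- opt$par
  if (p[2] <= 0) stop("fitted crosswalk is not decreasing in SF-12")
  structure(list(a = unname(p[1]), b = unname(p[2]),
                 anchors = anchors, sf12_sd = sf12_sd),
            class = "crosswalk")
}

#' Map SF-12 scores to disability weights
#' @param cw A `crosswalk` object.
#' @param sf12 Numeric vector or matrix of SF-12 scores.
#' @return Disability weights in (0, 1), same shape as `sf12`.
#' @export
cw_dw <- function(cw, sf12) {
  stopifnot(inherits(cw, "crosswalk"))
  out <- stats::plogis(-(cw$a + cw$b * sf12))
  if (is.matrix(sf12)) dim(out) <- dim(sf12)
  out
}

#' Map disability weights back to SF-12 scores (closed-form inverse)
#' @param cw A `crosswalk` object.
#' @param dw Disability weights in (0, 1).
#' @return SF-12 scores, same shape as `dw`.
#' @export
cw_sf12 <- function(cw, dw) {
  stopifnot(inherits(cw, "crosswalk"))
  out <- -(stats::qlogis(dw) + cw$a) / cw$b
  if (is.matrix(dw)) dim(out) <- dim(dw)
  out
}

#' @export
print.crosswalk <- function(x, ...) {
  cat("SF-12 -> disability-weight crosswalk: DW(s) = 1/(1 + exp(a + b s))\n")
  cat(sprintf("  a = %.6f, b = %.6f  (%d anchors)\n", x$a, x$b, nrow(x$anchors)))
  cat(sprintf("  DW(100) = %.4f, DW(0) = %.4f\n", cw_dw(x, 100), cw_dw(x, 0)))
  if (!is.null(x$sf12_sd)) cat(sprintf("  sigma_SF12 = %.3f\n", x$sf12_sd))
  invisible(x)
}

#' SF-12 equivalent of a corrected disability weight
#'
#' The scenario machinery works on the SF-12 scale. Because the crosswalk is
#' strictly positive, a disability weight of exactly zero has no finite
#' pre-image: zero (and any weight below the weight at SF-12 = 100) is
#' represented by the top of the scale, s = 100. Conversely
#' [dw_from_sf12()] maps s at the top of the scale back to a weight of 0,
#' realising the floor on disability weights.
#'
#' @param cw A `crosswalk` object.
#' @param dw Disability weights in `[0, 1)` (vector or matrix).
#' @return SF-12 scores in `[0, 100]`.
#' @export
sf12_from_dw <- function(cw, dw) {
  floor_dw <- cw_dw(cw, 100)
  out <- cw_sf12(cw, pmax(dw, floor_dw))
  out <- clamp(out, 0, 100)
  if (is.matrix(dw)) dim(out) <- dim(dw)
  out
}

#' Disability weight of a scenario SF-12 score, floored at zero
#' @param cw A `crosswalk` object.
#' @param sf12 SF-12 scores in `[0, 100]` (vector or matrix).
#' @return Disability weights with scores at the top of the scale mapped to 0.
#' @export
dw_from_sf12 <- function(cw, sf12) {
  out <- cw_dw(cw, sf12)
  out[sf12 >= 100 - 1e-12] <- 0
  if (is.matrix(sf12)) dim(out) <- dim(sf12)
  out
}
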