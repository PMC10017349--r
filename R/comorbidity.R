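#' Draw-level cumulative disability weights from observed SF-12 scores
#'
#' Propagates SF-12 measurement uncertainty into disability weights: each
#' draw perturbs the observed composite score by Normal(0, `noise_sd`),
#' clamps to the 0-100 scale, and maps through the crosswalk.
#'
#' @param sf12 Observed SF-12 scores (one per respondent).
#' @param cw A `crosswalk` object.
#' @param n_draws Number of draws.
#' @param noise_sd SF-12 measurement noise SD (points).
#' @param seed Integer seed.
#' @return Matrix (respondents x draws) of cumulative disability weights.
#' @export
respondent_dw_draws <- function(sf12, cw, n_draws, noise_sd, seed = 1) {
  set.seed(stage_seed(seed, "dw_draws"))
  n <- length(sf12)
  s <- clamp(sf12 + matrix(stats::rnorm(n * n_draws, 0, noise_sd), n, n_draws),
             0, 100)
  cw_dw(cw, s)
}

#' Fit the comorbidity meta-regression on logit disability weights
#'
#' Respondent cumulative disability weights (clamped into the open unit
#' interval) are logit-transformed and regressed on condition dummies,
#' anxiety included as a condition. Respondent-level disability-weight
#' uncertainty is carried by refitting the regression for every draw and
#' pooling the coefficient draws; per-draw coefficient-sampling noise from
#' the asymptotic covariance is added on top. Each respondent contributes
#' one observation per draw, so the respondent-level variation is reported
#' as the residual variance.
#'
#' @param dw_draws Matrix (respondents x draws) of cumulative disability
#'   weights, e.g. from [respondent_dw_draws()].
#' @param condition_flags data.frame or matrix (respondents x conditions) of
#'   0/1 flags; must include an `anxiety` column and at least one other
#'   condition. Zero-prevalence conditions are dropped with a warning.
#' @param seed Integer seed for the coefficient-sampling noise.
#' @return An object of class `comorbidity_model`: `coef_draws`
#'   ((1 + conditions) x draws, first row the intercept), `conditions`,
#'   `respondent_var`.
#' @export
fit_comorbidity_model <- function(dw_draws, condition_flags, seed = 1) {
  F <- as.matrix(condition_flags) * 1
  if (is.null(colnames(F)) || !"anxiety" %in% colnames(F))
    stop("condition_flags must include an 'anxiety' column")
  prev <- colMeans(F)
  if (any(prev == 0)) {
    warning("dropping zero-prevalence condition(s): ",
            paste(colnames(F)[prev == 0], collapse = ", "))
    F <- F[, prev > 0, drop = FALSE]
  }
  if (ncol(F) < 2) stop("need at least 2 conditions observed (including anxiety)")
  stopifnot(nrow(F) == nrow(dw_draws))
  X <- cbind(`(Intercept)` = 1, F)
  Y <- stats::qlogis(clamp(dw_draws, 1e-6, 1 - 1e-6))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) stop("condition dummies are collinear")
  B <- qr.coef(qrX, Y)                              # (k+1) x n_draws
  resid <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  XtXinv <- chol2inv(qr.R(qrX))
  L <- chol(XtXinv)                                 # XtXinv = L'L
  set.seed(stage_seed(seed, "comorbidity_coef"))
  Z <- matrix(stats::rnorm(ncol(X) * ncol(Y)), ncol(X), ncol(Y))
  B <- B + t(L) %*% Z * rep(sqrt(sigma2), each = ncol(X))
  rownames(B) <- colnames(X)
  structure(list(coef_draws = B, conditions = colnames(F),
                 respondent_var = mean(sigma2)),
            class = "comorbidity_model")
}

#' @export
print.comorbidity_model <- function(x, ...) {
  cat("Comorbidity model on logit(DW):", ncol(x$coef_draws), "coefficient draws\n")
  s <- summarise_draws(x$coef_draws, margin = 1)
  print(cbind(round(s, 3)))
  cat(sprintf("respondent-level variance: %.4f\n", x$respondent_var))
  invisible(x)
}

#' Predict each respondent's comorbid (non-anxiety) disability weight
#'
#' Inverse-logit of the intercept plus the coefficients of the respondent's
#' comorbid conditions, per draw; the anxiety coefficient is excluded so the
#' prediction captures disability from comorbidities only.
#'
#' @param model A `comorbidity_model`.
#' @param condition_flags data.frame/matrix of 0/1 flags for the respondents
#'   to predict (columns matching the model's conditions; missing columns
#'   are treated as absent).
#' @return Matrix (respondents x draws) of comorbid disability weights.
#' @export
predict_comorbid_dw <- function(model, condition_flags) {
  stopifnot(inherits(model, "comorbidity_model"))
  F <- as.matrix(condition_flags) * 1
  conds <- setdiff(model$conditions, "anxiety")
  Xp <- matrix(0, nrow(F), length(conds), dimnames = list(NULL, conds))
  for (cl in intersect(conds, colnames(F))) Xp[, cl] <- F[, cl]
  Xp <- cbind(1, Xp)
  B <- model$coef_draws[c("(Intercept)", conds), , drop = FALSE]
  stats::plogis(Xp %*% B)
}

#' Comorbidity-correct a cumulative disability weight
#'
#' Removes the comorbid contribution from the cumulative disability weight
#' by inverting the multiplicative combination of disability:
#' \deqn{DW_{anxiety} = 1 - \frac{1 - DW_{cumulative}}{1 - DW_{comorbidities}}}
#' floored at zero.
#'
#' @param dw_cumulative,dw_comorbidities Numeric vectors or matrices (e.g.
#'   respondents x draws), both in `[0, 1)`.
#' @return The anxiety-specific disability weight, same shape, in `[0, 1)`.
#' @examples
#' comorbidity_correct(0.5, 0.2)  # 1 - 0.5/0.8 = 0.375
#' @export
comorbidity_correct <- function(dw_cumulative, dw_comorbidities) {
  if (any(dw_comorbidities >= 1 - 1e-9)) stop("saturated comorbidity")
  if (any(dw_cumulative < 0) || any(dw_cumulative >= 1) || any(dw_comorbidities < 0))
    stop("disability weights must lie in [0, 1)")
  out <- pmax(0, 1 - (1 - dw_cumulative) / (1 - dw_comorbidities))
  if (is.matrix(dw_cumulative)) dim(out) <- dim(dw_cumulative)
  out
}
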