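#' Standardised mean differences from arm summary statistics
#'
#' Computes the small-sample-corrected (Hedges) standardised mean difference
#' and its large-sample standard error for each intervention-versus-reference
#' contrast, delegating to `metafor::escalc(measure = "SMD")`, the
#' conventional implementation of this estimator.
#'
#' @param effects data.frame with columns `mean_t`, `sd_t`, `n_t`, `mean_c`,
#'   `sd_c`, `n_c` (plus any identifiers, carried through).
#' @return The input with `smd` and `se_smd` columns filled.
#' @export
compute_smd <- function(effects) {
  req <- c("mean_t", "sd_t", "n_t", "mean_c", "sd_c", "n_c")
  stopifnot(all(req %in% names(effects)))
  with(effects, {
    if (any(sd_t <= 0) || any(sd_c <= 0)) stop("degenerate arms: non-positive SD")
    if (any(n_t < 2) || any(n_c < 2)) stop("need at least 2 per arm")
  })
  pooled_sd <- sqrt(((effects$n_t - 1) * effects$sd_t^2 +
                     (effects$n_c - 1) * effects$sd_c^2) /
                    (effects$n_t + effects$n_c - 2))
  if (any(pooled_sd <= 0)) stop("degenerate arms: zero pooled SD")
  es <- metafor::escalc(measure = "SMD",
                        m1i = effects$mean_t, sd1i = effects$sd_t, n1i = effects$n_t,
                        m2i = effects$mean_c, sd2i = effects$sd_c, n2i = effects$n_c)
  effects$smd <- as.numeric(es$yi)
  effects$se_smd <- sqrt(as.numeric(es$vi))
  effects
}

#' Keep only the longest follow-up effect per study
#'
#' When a study contributes several rows, the effect at the longest
#' follow-up is retained (first row on ties).
#'
#' @param effects data.frame with `study_id` and `follow_up_weeks`.
#' @return The filtered data.frame.
#' @export
select_longest_followup <- function(effects) {
  stopifnot(all(c("study_id", "follow_up_weeks") %in% names(effects)))
  keep <- unlist(lapply(split(seq_len(nrow(effects)), effects$study_id),
                        function(ix) ix[which.max(effects$follow_up_weeks[ix])]))
  effects[sort(unname(keep)), , drop = FALSE]
}

# component sets of each intervention class: CBT loads on both the cognitive
# and behavioural dummies; the reference class is the zero vector
class_components <- function(classes) {
  known <- list(cognitive = "cognitive", behavioural = "behavioural",
                CBT = c("cognitive", "behavioural"),
                psychodynamic = "psychodynamic", supportive = "supportive",
                antidepressants = "antidepressants")
  out <- known[classes]
  miss <- classes[!classes %in% names(known)]
  if (length(miss)) {
    # unknown classes get their own dummy
    out[miss] <- as.list(miss)
    names(out) <- classes
  }
  out
}

# design matrix over component dummies; collinear duplicate columns (e.g.
# cognitive and behavioural when only CBT trials are present) are merged so
# the fit stays full rank, with class-effect patterns remapped accordingly
build_design <- function(classes) {
  comps <- class_components(unique(classes))
  all_comp <- unique(unlist(comps))
  X <- matrix(0, nrow = length(classes), ncol = length(all_comp),
              dimnames = list(NULL, all_comp))
  for (i in seq_along(classes)) X[i, comps[[classes[i]]]] <- 1
  # merge identical columns
  key <- apply(X, 2, paste, collapse = "")
  groups <- split(colnames(X), key)
  Xm <- sapply(groups, function(g) X[, g[1]])
  Xm <- matrix(Xm, nrow = length(classes),
               dimnames = list(NULL, vapply(groups, paste, "", collapse = "+")))
  patterns <- lapply(stats::setNames(names(comps), names(comps)), function(cl) {
    s <- comps[[cl]]
    p <- vapply(groups, function(g) {
      if (all(g %in% s)) 1 else if (!any(g %in% s)) 0 else NA_real_
    }, numeric(1))
    names(p) <- colnames(Xm)
    p
  })
  list(X = Xm, patterns = patterns)
}

# maximum-likelihood random-effects meta-regression: y_i ~ N(X_i b, v_i + g^2)
ml_metareg <- function(y, v, X, gamma = NULL) {
  fit_at <- function(g) {
    w <- 1 / (v + g^2)
    XtW <- t(X * w)
    A <- XtW %*% X
    b <- solve(A, XtW %*% y)
    ll <- sum(stats::dnorm(y, X %*% b, sqrt(v + g^2), log = TRUE))
    list(b = drop(b), vcov = solve(A), gamma = g, loglik = ll)
  }
  if (is.null(gamma)) {
    opt <- stats::optimize(function(g) -fit_at(g)$loglik, c(0, 2), tol = 1e-8)
    g <- opt$minimum
    # the optimizer never visits the exact boundary; snap when 0 is as good
    if (fit_at(0)$loglik >= fit_at(g)$loglik) g <- 0
  } else g <- gamma
  fit_at(g)
}

#' Pool trial effects via a trimmed random-effects network meta-regression
#'
#' Regresses standardised mean differences on intervention-class dummies
#' (CBT flags both the cognitive and behavioural dummies; the
#' placebo/waiting-list/usual-care reference is the zero vector) with an
#' additive between-study heterogeneity variance estimated by maximum
#' likelihood. Trimming iteratively excludes the `floor(trim_pct * n)`
#' effects with the smallest log-likelihood contributions under the current
#' fit, refitting until the trimmed set reaches a fixed point (at most 20
#' iterations; ties broken towards the smaller study id). Posterior-style
#' draws are taken from the asymptotic multivariate normal of the
#' coefficients.
#'
#' @param effects data.frame from [compute_smd()] with `smd`, `se_smd`,
#'   `study_id`, `intervention_class`; rows sharing a `study_id` should
#'   first be filtered with [select_longest_followup()].
#' @param trim_pct Proportion of effects to trim, in `[0, 0.5)`.
#' @param n_draws Number of coefficient draws.
#' @param seed Integer seed for the draws.
#' @param gamma Optional fixed between-study SD; `NULL` (default) estimates
#'   it by maximum likelihood.
#' @return An object of class `pooled_effects`: per-class draw matrices,
#'   coefficient estimates and covariance, `gamma`, and `trimmed_ids`.
#' @export
fit_trimmed_network <- function(effects, trim_pct = 0.1, n_draws = 1000,
                                seed = 1, gamma = NULL) {
  stopifnot(all(c("smd", "se_smd", "study_id", "intervention_class") %in%
                names(effects)))
  if (trim_pct < 0 || trim_pct >= 0.5) stop("trim_pct must lie in [0, 0.5)")
  if (any(effects$se_smd <= 0)) stop("se_smd must be positive")
  y <- effects$smd
  v <- effects$se_smd^2
  des <- build_design(effects$intervention_class)
  X <- des$X
  n <- length(y)
  k_trim <- floor(trim_pct * n)
  retained <- seq_len(n)
  fit <- NULL
  for (it in seq_len(20)) {
    fit <- ml_metareg(y[retained], v[retained], X[retained, , drop = FALSE], gamma)
    if (k_trim == 0) break
    li <- stats::dnorm(y, drop(X %*% fit$b), sqrt(v + fit$gamma^2), log = TRUE)
    ord <- order(li, effects$study_id, seq_len(n))
    new_retained <- sort(setdiff(seq_len(n), ord[seq_len(k_trim)]))
    for (cl in unique(effects$intervention_class))
      if (!any(effects$intervention_class[new_retained] == cl))
        stop(sprintf("class unidentified: all '%s' effects trimmed", cl))
    if (identical(new_retained, retained)) break
    retained <- new_retained
  }
  trimmed <- setdiff(seq_len(n), retained)
  set.seed(seed)
  co <- MASS::mvrnorm(n_draws, fit$b, fit$vcov)
  co <- matrix(co, nrow = n_draws, dimnames = list(NULL, names(fit$b)))
  class_draws <- lapply(des$patterns, function(p) {
    if (anyNA(p)) stop("class unidentified: component dummies collinear")
    drop(co %*% p)
  })
  class_draws$reference <- rep(0, n_draws)
  class_means <- vapply(des$patterns, function(p)
    if (anyNA(p)) NA_real_ else sum(p * fit$b), numeric(1))
  class_means["reference"] <- 0
  structure(list(classes = class_draws, class_means = class_means,
                 coef = fit$b, vcov = fit$vcov, gamma = fit$gamma,
                 loglik = fit$loglik,
                 design = des, n_draws = n_draws,
                 trimmed_ids = effects$study_id[trimmed],
                 retained_ids = effects$study_id[retained]),
            class = "pooled_effects")
}

#' @export
print.pooled_effects <- function(x, ...) {
  cat("Pooled treatment effects (SMD scale),",
      x$n_draws, "draws; gamma =", signif(x$gamma, 4), "\n")
  for (cl in setdiff(names(x$classes), "reference"))
    cat(sprintf("  %-16s %s\n", cl,
                paste(signif(summarise_draws(x$classes[[cl]]), 3), collapse = " / ")))
  if (length(x$trimmed_ids))
    cat("  trimmed:", paste(x$trimmed_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Extract the draw vector of one intervention class
#' @param pooled A `pooled_effects` object.
#' @param class_label Class name (or `"reference"`).
#' @return An `effect_draws` object (label + draws).
#' @export
class_effect <- function(pooled, class_label) {
  stopifnot(inherits(pooled, "pooled_effects"))
  d <- pooled$classes[[class_label]]
  if (is.null(d)) stop("unknown class: ", class_label)
  structure(list(label = class_label, draws = d), class = "effect_draws")
}

#' Re-incorporate between-study heterogeneity into a class effect
#'
#' Adds an independent Normal(0, gamma) perturbation to each draw, widening
#' the interval to reflect unexplained between-study variation while leaving
#' the mean unchanged in expectation.
#'
#' @param pooled A `pooled_effects` object (provides `gamma`).
#' @param class_label Class whose draws to widen.
#' @param seed Integer seed.
#' @return An `effect_draws` object.
#' @export
widen_by_heterogeneity <- function(pooled, class_label, seed = 1) {
  ed <- class_effect(pooled, class_label)
  if (pooled$gamma > 0) {
    set.seed(stage_seed(seed, paste0("widen_", class_label)))
    ed$draws <- ed$draws + stats::rnorm(length(ed$draws), 0, pooled$gamma)
  }
  ed$label <- paste0(class_label, "+heterogeneity")
  ed
}

#' Combine two treatment effects draw-wise (optimal-treatment combination)
#'
#' The full-coverage optimal-treatment effect is the draw-wise sum of the
#' CBT and antidepressant effects.
#'
#' @param a,b `effect_draws` objects with equal draw counts.
#' @return An `effect_draws` object with draws `a + b`.
#' @export
combine_optimal <- function(a, b) {
  stopifnot(inherits(a, "effect_draws"), inherits(b, "effect_draws"))
  if (length(a$draws) != length(b$draws)) stop("draw length mismatch")
  structure(list(label = paste(a$label, "+", b$label),
                 draws = a$draws + b$draws), class = "effect_draws")
}

#' @export
print.effect_draws <- function(x, ...) {
  s <- summarise_draws(x$draws)
  cat(sprintf("effect '%s': %.3f (95%% UI %.3f to %.3f), %d draws\n",
              x$label, s["mean"], s["lower"], s["upper"], length(x$draws)))
  invisible(x)
}
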