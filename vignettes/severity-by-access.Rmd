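---
title: "Grading anxiety-disorder severity by healthcare access: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Grading anxiety-disorder severity by healthcare access: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anxburden)
```

## The problem

Burden-of-disease accounting splits the prevalence of a disorder into
severity-specific sequelae (asymptomatic, mild, moderate, severe), each with
its own disability weight (DW, health loss on a 0–1 scale). For anxiety
disorders the severity split has historically come from a single high-income
country survey, implicitly assuming the rest of the world — with far less
access to effective treatment — shares that distribution. This package
implements a pipeline that makes the severity distribution a function of
healthcare access (the Healthcare Access and Quality Index, HAQI, 0–100) and
uses the resulting counterfactuals to account how much non-fatal burden
(years lived with disability, YLD = prevalence × sequela-weighted DW) has
been *averted* by existing treatment and how much remains *avoidable*.

The chain has six stages, each producing 1000 index-aligned Monte-Carlo
draws (95% uncertainty intervals are the 25th and 975th ranked draws):

1. **Treatment effects.** Randomised-trial effects on symptom scales,
   expressed as standardised mean differences (SMD; Hedges small-sample
   corrected, negative = improvement), are pooled in a network
   meta-regression with intervention-class dummies. CBT trials flag both the
   cognitive-therapy and behavioural-therapy dummies, so the CBT effect is
   the sum of those two coefficients; the reference (placebo, waiting list,
   usual care) is the zero vector. A trimmed maximum-likelihood estimator
   drops the 10% of effects with the smallest likelihood contributions.
2. **Coverage.** Survey service-use items define received treatment
   (≥ 6 sessions of a therapy delivered by a mental-health specialist;
   any mental-health medication). The survey-weighted mean of each
   respondent's received effects is the coverage-adjusted population effect
   β.
3. **Disability weights.** SF-12 composite scores map to cumulative DWs
   through a strictly monotone logistic crosswalk. A regression of
   logit(DW) on condition dummies predicts each anxiety case's comorbid
   DW, which is removed multiplicatively:
   DW~anxiety~ = 1 − (1 − DW~cumulative~)/(1 − DW~comorbidities~), floored
   at zero.
4. **Scenarios.** On the SF-12 scale, the no-treatment counterfactual adds
   β·σ (σ = SD of SF-12 among anxiety cases; β < 0, so scores fall and
   DWs rise); full coverage optimal treatment (FCOT) subtracts the combined
   CBT + antidepressant effect from the no-treatment scores. DWs are sorted
   into sequelae at the midpoints of the mild/moderate and moderate/severe
   health-state weights.
5. **Grading by access.** Treatment coverage regressed on HAQI (linear vs
   logit, smaller natural-scale RMSE wins) locates HAQI₀, the zero-coverage
   intercept. Severity proportions are linear in HAQI between the
   no-treatment distribution (at and below HAQI₀, where they plateau) and
   the observed distribution at the anchor survey's HAQI, and are linearly
   extrapolated above it.
6. **Burden.** Per country, YLDs under observed / no-treatment /
   best-routine-care (severity at the highest observed HAQI) / FCOT
   scenarios give averted and avoidable fractions, aggregated as
   population-weighted means to super-regions and globally.

## What the synthetic world emulates

Real inputs are restricted (survey microdata) or large (GBD country
tables), so the package ships a generator whose defaults *are* the study
conditions, with all ground truth recorded:

* 194 trial effects across six classes (111 CBT, 2 cognitive,
  3 behavioural; the remainder split across psychodynamic, supportive and
  antidepressant trials), true class effects −0.68 (CBT), −0.48
  (psychodynamic), −0.38 (antidepressants), −0.28 (supportive), between-study
  SD tau = 0.1, encoded in arm means so the SMD computation is exercised.
* A survey of 10641 respondents (round-robin strata, log-normal weights),
  6% 30-day anxiety prevalence. Anxiety cases draw a latent untreated DW
  from a four-component mixture — point mass at zero plus uniforms within
  the mild/moderate/severe bands — with mixture weights (0, 0.437, 0.300,
  0.263), the no-treatment severity distribution. Comorbid condition DWs
  combine multiplicatively; the cumulative DW is observed as
  SF-12 = crosswalk⁻¹(DW) + Normal(0, 4) noise. Treated respondents
  (coverage 5.4% CBT, 3% other psychotherapy, 6.2% counselling, 39.2%
  medication) have SF-12 raised by their received effect × σ, so the
  counterfactual is recoverable.
* 29 coverage surveys on the line coverage = 0.01·(HAQI − 44.1) with
  Gaussian noise (SD 0.05), drawn above the intercept — the surveys being
  emulated all observed positive coverage, and the intercept is found by
  extrapolation. The noise level was chosen to reproduce the substantial
  between-survey scatter such coverage estimates show; with much smaller
  noise the HAQI₀ draws would be unrealistically tight and the lowest-HAQI
  countries would sit below every draw, making their averted burden exactly
  zero.
* 195 countries with HAQI uniform on 40–95 (roughly the observed 2019
  span), prevalence 2–8%, log-normal populations, and super-region labels
  assigned by HAQI rank so the high-income label sits on the
  highest-access block.

What it does **not** emulate: the diagnostic interview and sampling design
of a real survey, dose–response in session counts, correlation between
treatment uptake and severity (uptake is independent of the latent DW),
sex/age structure, and real spatial correlation in HAQI, prevalence and
population. Passing tests therefore show the *estimators* recover a world
that satisfies the model's assumptions — not that those assumptions hold in
real data.

## Numerical and design choices

* **SMD and trimming.** SMDs use the conventional escalc implementation of
  the Hedges estimator. Trimmed estimators admit several schedules; here
  trimming iterates to a fixed point: fit, rank
  per-effect log-likelihood contributions under the current fit, drop the
  lowest floor(0.10·n), refit — at most 20 iterations, ties broken towards
  the smaller study id. Exactly floor(0.10·n) effects are always excluded.
  A class whose effects would all be trimmed stops with an error rather
  than silently losing identification.
* **Estimation.** The random-effects meta-regression is maximum likelihood
  (profile over the between-study SD γ on [0, 2]), with draws from the
  asymptotic multivariate normal of the coefficients — the large-sample
  equivalent of the Bayesian tool it stands in for; full MCMC is out of
  scope. On the default synthetic world γ is estimated at the boundary 0
  (within-study variance ≈ 0.04–0.1 dominates tau² = 0.01); an independent
  ML fit with metafor agrees exactly, and the parameter-recovery test shows
  interval coverage is preserved. Trimming additionally shrinks γ — a known
  property of trimmed estimators worth remembering when interpreting the
  widened intervals.
* **Crosswalk.** The SF-12→DW map is a logistic DW(s) = 1/(1+exp(a+bs)),
  b > 0, least-squares calibrated through anchor points (exact on the logit
  scale when the anchors lie on a logistic). Any strictly monotone
  invertible map preserves the pipeline's structure; the logistic has a
  closed-form inverse and round-trips to < 1e−9 across the whole scale.
* **The DW floor.** A logistic is strictly positive, so DW = 0 only exists
  at the top of the SF-12 scale: weights below DW(100) (≈ 0.009 with the
  default anchors) are represented by s = 100, and any scenario score at
  100 maps back to DW 0. This realises the floor on disability weights —
  a respondent pushed to the top of the scale needs no further treatment —
  and makes the zero-shift scenario an exact identity. The practical
  consequence is a small discretisation: corrected DWs below DW(100) are
  counted as asymptomatic.
* **Comorbidity model.** DW uncertainty enters by refitting the
  logit(DW)-on-conditions regression for every draw and pooling coefficient
  draws (with per-draw coefficient-sampling noise on top). Each respondent
  contributes one observation per draw, so a respondent random intercept is
  not separately identifiable; the between-respondent variation is the
  residual variance, which the model reports. DWs are clamped to
  [1e−6, 1−1e−6] before the logit (asymptomatic respondents exist by
  construction).
* **Cutoffs and ties.** Sequela cutoffs are computed per draw (midpoints of
  the health-state draws, which are beta distributions moment-matched to
  the published mean and 95% UI, sorted so mild < moderate < severe
  draw-wise). A DW exactly at a cutoff takes the lower category —
  deterministic and conservative.
* **FCOT direction.** The optimal-treatment shift is applied as a
  subtraction of the (negative) combined effect from the no-treatment
  scores — health improves. The alternative sign reading would make
  severity rise under full treatment, contradicting the scenario's own
  definition.
* **Interpolator.** Draws of the anchor HAQI and HAQI₀ are paired by
  index; pairs violating anchor > HAQI₀ are resampled from the remaining
  draws. Proportions interpolated between two simplexes already sum to 1,
  so renormalisation is applied only to rows that extrapolation pushed out
  of [0, 1] (this keeps plateau and anchor reproduction exact). For the
  logit coverage form, which has no exact zero, HAQI₀ is defined as the
  HAQI where fitted coverage falls to 1e−3; on linear-world data the linear
  form always wins the RMSE comparison.
* **Aggregation.** Region fractions are population-weighted means of
  country fractions (the literal reading of the stated aggregation), not
  ratios of summed YLDs. The `remaining` share uses the no-treatment YLDs
  as denominator so averted + avoidable + remaining stacks to one on a
  common scale.
* **Determinism.** Every stage derives its own seed from the run seed and a
  stage-name hash, so stages re-run in isolation reproduce the full-run
  results; identical configurations give byte-identical output files.

## Problem sizes used in tests and scripts

The analysis scripts and the acceptance script run the full study
conditions (194 effects, 10641 respondents, 1000 draws, 195 countries;
about ten seconds end to end). The test suite exercises the same code at
reduced sizes — typically 800–5000 respondents and 60–200 draws — which are
ample for the properties being checked (exact identities, parameter
recovery to stated tolerances) while keeping the suite fast. The end-to-end
recovery check uses 5000 respondents and 200 draws and recovers the
configured no-treatment severity proportions within five percentage points
and the coverage intercept within three HAQI units.

## Known limitations

* The coverage-adjusted effect on the default world is ≈ −0.21, smaller
  than the −0.28 reported from the emulated survey's restricted microdata;
  the generator's uptake probabilities are the published coverages, and no
  attempt is made to tune β itself.
* Treatment uptake is independent of severity in the generator, while in
  reality more severe cases are likelier to seek care; the coverage-adjusted
  shift is an average shift applied to everyone, which smooths the severity
  distribution relative to individually-shifted truth.
* The 12-month service-use recall versus 30-day diagnosis mismatch of the
  emulated survey is reproduced as-is, not corrected.
* Severity is not stratified by sex or age, and years of life lost (the
  fatal component) are out of scope: the accounting is YLD-only.
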