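Package: anxburden
Title: Grading Anxiety-Disorder Severity by Healthcare Access and Estimating Averted and Avoidable Burden
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to grade the severity distribution of anxiety disorders by
    healthcare access quality and to estimate averted and avoidable non-fatal
    burden. Treatment effects from randomised trials are pooled with a trimmed
    maximum-likelihood network meta-regression on the standardised mean
    difference scale; survey-weighted treatment coverage converts them into a
    population coverage-adjusted effect; disability weights derived from SF-12
    composite scores via an invertible crosswalk are comorbidity-corrected and
    sorted into severity sequelae; severity distributions are shifted across
    no-treatment and full-coverage-optimal-treatment counterfactuals, linearly
    interpolated along the Healthcare Access and Quality Index, and combined
    with prevalence and population to give years lived with disability under
    each scenario. A synthetic-world generator produces all input tables with
    known ground truth so the full chain is testable without restricted data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    MASS,
    metafor,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
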