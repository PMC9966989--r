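Package: mhcscreen
Title: Minor Health Complaint Scoring and Nutrient Cut-Off Screening for
    Occupational Cohorts
Version: 0.1.0
Authors@R:
    person("Cohort", "Analytics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to operationalise minor health complaints (MHCs) from the
    29 stress-reaction items of the Brief Job Stress Questionnaire and to
    relate MHC levels to dietary nutrient intake.  Provides questionnaire
    scoring, severity grading and exclusion filtering; exploratory and
    confirmatory factor analysis of the dichotomised items (maximum
    likelihood extraction, direct Oblimin rotation, Kaiser-Meyer-Olkin
    adequacy, parallel analysis and minimum-average-partial factor counts,
    CFI/TLI/SRMR fit indices); two-parameter logistic item response theory
    fitted by marginal maximum likelihood with factor-level averaged
    response curves and 0.5-probability thresholds; median-split definition
    of MHC strata; Mann-Whitney screening of 39 nutrients with a
    three-of-four selection rule, feasible-interval cut-off derivation and
    nutrient-count stratification; and a synthetic cohort generator that
    emulates the latent-trait and planted-effect structure the analysis
    assumes, so the whole pipeline is testable without access to the
    original survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
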