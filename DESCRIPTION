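Package: seqdor
Title: Discriminative Multivariate Sequential Patterns via the Diagnostic
    Odds Ratio
Version: 0.1.0
Authors@R:
    person("Iris", "Calder", email = "iris.calder@example.org",
           role = c("aut", "cre"))
Description: Mines point-based multivariate sequential patterns from daily
    clinical time series and selects the discriminative ones with criteria
    built on the diagnostic odds ratio (DOR): a plain DOR threshold, the
    differential risk/protection probability of a pattern against its
    enumeration parent (optionally with beam search), non-overlap of
    Miettinen test-based 95% confidence intervals, and the combination of
    both, with Jumping Emerging Patterns as a frequency-based baseline.
    Selected patterns become binary containment features for interpretable
    rule- and tree-based survival classifiers evaluated by stratified
    cross-validation.  Includes a synthetic intensive-care-burn-unit cohort
    generator with ground-truth motifs planted at designed per-class
    penetrances, a pluggable discretizer for continuous variables, and a
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
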