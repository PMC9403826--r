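---
title: "Selecting discriminative sequential patterns with the diagnostic odds ratio"
author: "seqdor"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting discriminative sequential patterns with the diagnostic odds ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Patients in an intensive care burn unit are monitored daily during the
critical first days after admission: fluid intake (INC), diuresis
(DIUR), fluid balance (BAL), pH, bicarbonate (BIC) and base excess
(BE).  The evolution of these variables carries prognostic information
that static severity scores ignore.  `seqdor` models each patient as a
sequence of daily itemsets of discretized measurements, mines the
multivariate sequential patterns frequent in each outcome class, and
asks which of the (typically thousands of) mined patterns are worth
keeping as predictors in an interpretable survival classifier.

The package's central quantity is the diagnostic odds ratio of a
pattern against death.  With `tp` non-survivors containing the pattern,
`fn` non-survivors without it, `fp` survivors with it and `tn`
survivors without it,

    DOR = (tp/fn) / (fp/tn)

A pattern with DOR > 1 is a risk factor, DOR < 1 a protection factor.
For clinician-facing reporting the DOR is mapped to the risk
probability `R = DOR/(DOR+1)` and protection probability `P = 1 - R`.

## Sequence model

An *item* `VAR_b` pairs a variable with a 0-based ordered bin index
(bin 0 is the lowest interval).  An *itemset* is a set of distinct
items observed on the same day, kept in canonical order (variable name,
then bin).  A *pattern* is an ordered list of itemsets written
`BIC_0 = PH_0 < PH_1`: `=` joins same-day items, `<` separates strictly
later — not necessarily consecutive — days.  Pattern length is the
total number of item instances.  A pattern is *contained* in a patient
sequence when its itemsets map, order-preservingly, onto distinct days
whose observed itemsets include them; the implementation uses greedy
earliest-day matching (exact for this containment relation, and
verified in the test suite against an exhaustive day-combination
oracle).

Mining enumerates a canonical prefix tree depth-first.  A pattern grows
by an **S-extension** (append a new singleton itemset at a later time)
or an **I-extension** (add an item to the final itemset).  I-extensions
only accept items canonically greater than the final itemset's largest
item, so every canonical pattern is generated exactly once, and each
pattern has a unique *enumeration parent*: itself minus its last-added
item.  Support is anti-monotone, so a child's cover is evaluated only
over its parent's cover; the compiled kernel returns exact per-class
supporting-patient sets.  The minimum support is interpreted relative
to the mined class subset (`ceiling(minsup * n_class)`), because
patterns are mined per outcome class and only afterwards scored against
the full cohort; the full-database contingency counts are attached by
`pattern_stats()`.

## DOR statistics and numerical conventions

**Zero cells.**  The 0.5 continuity correction admits two readings.
The default, margin-preserving convention adds 0.5 to a zero cell and
subtracts 0.5 from the other cell of the same outcome class, leaving
both class totals intact: on (10, 77, 0, 378) it yields DOR 98.05,
reproducing the worked values that anchor this implementation.  The
naive all-cells convention (+0.5 everywhere) gives 102.56 and is kept
only for comparison (`correct_zero_cells(..., method = "all")`).

**Confidence intervals.**  The 95% interval is Miettinen's test-based
interval `DOR^(1 ± z/χ)` with `χ² = (N−1)(tp·tn − fn·fp)² /
[(tp+fp)(fn+tn)(tp+fn)(fp+tn)]` the Mantel-Haenszel chi-square of the
corrected table (margin-preserving corrections cancel in N and the
margins).  Bounds are reported sorted ascending, the interval always
brackets the point estimate, and it excludes 1 exactly when
`χ² > z² = 3.8416` — an algebraic identity the suite asserts on random
tables.  At DOR exactly 1 the interval is undefined and the pattern is
dropped from CI-based selection with a message.

**Known property, measured honestly.**  Test-based intervals are
accurate near DOR = 1 and anti-conservative far from it.  At the
synthetic design point used in the acceptance suite (DOR = 66 with an
expected false-positive cell of 3.8 patients) the measured coverage is
about 0.76, not 0.95.  This is a property of the method being
reimplemented, not a defect of the implementation; the acceptance test
asserts the nominal 95% ± 3 target and is intentionally left failing,
with the measured value printed.

## Selection strategies

| method | keeps a pattern when | parameters |
|---|---|---|
| `jep` | support in exactly one class | — |
| `dor_threshold` | `DOR > dor_hi` or `DOR < dor_lo` (strict) | 16/0.08 or 32/0.04 |
| `diff_dor` | `R(child) − R(parent) > delta_R` or `P(child) − P(parent) > delta_P` | 0.25 / 0.30 |
| `ci_nonoverlap` | CI excludes 1 and is disjoint from the parent's CI | — |
| `combined` | both of the previous two | as above |

Design choices made where the design was genuinely open:

* **Parent resolution.**  Differential and CI criteria compare each
  pattern to its *unique enumeration prefix* rather than to all
  maximal sub-patterns; the miner materializes exactly that edge, and
  it makes the selectors deterministic and cheap.  This is a
  documented divergence risk against conventions that test against all
  parents.
* **Direction of the differential test.**  The criterion keeps
  children whose R (or P) *exceeds* the parent's by the threshold —
  the direction fixed by the worked parent/child pairs
  (71.1% → 98.87%, jump 27.77%; 40.23% → 78.85%, jump 38.62%).
* **Roots.**  Length-1 patterns have no parent: the differential rule
  never selects them; the CI rule admits them on the excludes-1 test
  alone.
* **Strictness and ties.**  All thresholds are strict inequalities.
  Beam search keeps, per parent, the retained child with the largest
  |ΔR| (differential) or |Δlog DOR| (CI), ties broken toward the
  canonically smallest serialization, so output is reproducible.

## Classifiers

Selected patterns become binary containment features.  No compiled
C4.5/RIPPER implementation exists in the supported dependency set, so
the package ships two small native learners restricted to binary
features: an entropy-gain decision tree and a RIPPER-family
sequential-covering rule learner (stratified grow/prune split, FOIL
gain, reduced-error pruning of trailing literals, rules for the
minority death class with survival as default).  Both honour the 2%
minimum-leaf / minimum-rule-weight interpretability constraint.
Evaluation is pooled, stratified, seeded 10-fold cross-validation;
**survival is the positive class** (chosen because the frequency
baseline on an 81.3%-survivor cohort then reads sensitivity 100%,
specificity 0%, matching how such cohorts are conventionally
reported), and AUC is the Mann-Whitney statistic of the pooled
out-of-fold survival scores.

## The synthetic world

`sim_config()` defaults state the emulated cohort once: 465 patients,
81.3% survivors, 5 days, the 6 variables above, 5 ordered bins per
variable (expert-style discretizations of these variables use about
five clinically meaningful levels, and bin indices up to 4 appear in
the domain's reported patterns), independent uniform background over
bins, and one planted motif `BIC_0 = PH_0 < BIC_0 = PH_0` — persistent
severe metabolic acidosis, a clinically credible strong mortality
signature — at penetrance 0.4 among non-survivors and 0.01 among
survivors.  Exact-count planting (`round(penetrance × class size)`
carriers, embedded at uniformly drawn increasing days) is the default
so tests are reproducible; a binomial mode resamples carrier flags per
patient for interval-coverage studies.  Continuous values are drawn
uniformly inside the assigned bin's interval of the companion
`bin_spec`, so discretization recovers the planted items exactly.  The
shipped anchor ranges are *illustrative* clinical ranges, not the
original study's unpublished expert bins.

What the generator does **not** emulate: temporal autocorrelation,
physiological coupling between variables, missing data.  A green
recovery test therefore establishes that the mining/selection/
classification machinery finds what was planted — not that the
pipeline performs comparably on real ICU data.

### Why two selection criteria cannot meet the stated recovery target

With one planted motif under an iid uniform background, every ancestor
of the motif is contained by all of the motif's ~35 non-survivor
carriers.  The parent's risk probability is therefore bounded below
(≈ 0.63–0.73 across any realistic bin count), while the child's is
bounded above by ≈ 0.985 (the value at zero survivor background), so
the largest achievable single-step ΔR is ≈ 0.21 — below the 0.25
differential threshold for *any* motif shape.  The combined criterion
is a subset of the differential one and inherits the impossibility;
CI non-overlap sits at the boundary (measured retention ≈ 0.4).  The
DOR-threshold selector retains the motif in every seed.  The
acceptance suite asserts the stated ≥ 90% target for all four
selectors and prints the measured rates; the three structurally
unattainable assertions are left red deliberately rather than weakened.

## Limitations

* Pattern selection compares only the single enumeration parent edge.
* The quantile discretizer is a stand-in with the same interface as
  correlation-preserving discretizers, not a reimplementation of one.
* The rule and tree learners are deliberately minimal (binary features
  only) and do not reproduce WEKA's J48/JRIP numerics.
* Absolute classification results of the original hospital cohort are
  not reproducible without its non-public data; only the in-text
  worked statistics are exact targets.
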