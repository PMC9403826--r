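# seqdor

Interpretable pattern-based survival classification from multivariate
clinical time series, with pattern selection driven by the **diagnostic
odds ratio (DOR)** instead of frequency alone.

Intensive-care cohorts record a handful of variables daily (here: fluid
intake `INC`, diuresis `DIUR`, fluid balance `BAL`, `PH`, bicarbonate
`BIC`, base excess `BE`).  After discretizing each variable into ordered
bins, every patient becomes a sequence of daily itemsets, and
multivariate sequential patterns such as

    BIC_0 = PH_0 < BIC_0 = PH_0

("low bicarbonate together with low pH, on two separate days") can be
mined per outcome class.  Mining produces thousands of patterns; the
package implements five selection strategies and feeds the survivors
into small, readable classifiers.

For a pattern with contingency cells `tp` (died, pattern present), `fn`
(died, absent), `fp` (survived, present), `tn` (survived, absent):

* `DOR = (tp/fn)/(fp/tn)`, with a margin-preserving 0.5 correction for
  zero cells;
* risk probability `R = DOR/(DOR+1)`, protection `P = 1 − R`;
* Miettinen test-based 95% CI `DOR^(1 ± 1.96/χ)`, `χ² ` the
  Mantel-Haenszel chi-square.

Selection strategies: Jumping Emerging Patterns (frequency baseline), a
two-sided DOR threshold, the differential `R`/`P` of a pattern against
its enumeration parent (optionally beam search), non-overlap of the
95% CIs, and the combination of the last two.  Classifiers: an
entropy-gain decision tree and a RIPPER-family rule learner over binary
pattern-containment features, evaluated by stratified 10-fold CV with
survival as the positive class.

## Worked example

```r
library(seqdor)

sim <- simulate_cohort(sim_config(), seed = 1)   # 465 patients, 87 died
db  <- apply_bins(sim$raw, sim$bin_spec)
db
#> <sequence_db> 465 patients (87 died, 378 survived), alphabet of 30 items

count_support(default_motif(), db)               # planted 35 died / 4 survived
#>     n_died n_survived
#>         35         10

st <- pattern_stats(mine_frequent(db, 0.2, "died", max_length = 4))
as.data.frame(st)[match(render_pattern(default_motif()), st$pattern),
                  c("pattern","tp","fp","dor","R","ci_low","ci_high")]
#>                         pattern tp fp   dor      R ci_low ci_high
#> 434 BIC_0 = PH_0 < BIC_0 = PH_0 35 10 24.77 0.9612  13.74   44.64

nrow(select_dor_threshold(st, 0.08, 16))         # 7 of 983 mined patterns kept

ex <- run_experiment(sim$raw, sim$bin_spec, minsup = 0.2,
                     selection = selection_config("dor_threshold"),
                     model = "rules", max_length = 4, seed = 7)
ex$summary
#>          method model minsup n_patterns total_length avg_length sensitivity
#> 1 dor_threshold rules    0.2          2            8          4       98.15
#>   specificity accuracy    auc
#> 1       28.74    85.16 0.6298
```

Reading the numbers: the planted acidosis motif is recovered with
35/87 non-survivors and 10/378 survivors (4 planted plus background
matches), giving DOR 24.8 with CI (13.7, 44.6) — a strong risk factor.
The DOR-threshold selector keeps 7 patterns; the fitted rule model uses
2 of them (8 items in total) and classifies 28.7% of non-survivors
correctly while keeping 98.2% sensitivity for survivors, against a
0%-specificity majority baseline.

The in-text worked statistics that anchor the implementation (DOR
72.30, 98.05, 87.12, 2.46, 27.93, 0.47; risk/protection 98.99%,
98.87%, 71.1%, 78.85%, 40.23%; CI bounds 24.21, 397.18, 6.71, 116.26,
0.26, 0.87; differential jumps 27.77 and 38.62 points) are all
reproduced by `verify_worked_examples()`.

## Command line

```sh
inst/cli/seqdor simulate --out cohort/ --seed 2
inst/cli/seqdor run --series cohort/series.csv --outcomes cohort/outcomes.csv \
    --bins cohort/bins.yaml --minsup 0.2 --method dor --model tree --out run/
inst/cli/seqdor verify-paper
```

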