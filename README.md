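# cews — centile-based early warning scores from vital-sign distributions

Early warning scores (EWS) condense a ward patient's vital signs into one
integer: each vital sign contributes 0–3 depending on which band it falls in,
a conscious level below Alert (AVPU) adds 3, and some systems add 2 for any
supplemental oxygen. `cews` implements the *unsupervised, centile-based*
approach to building such systems — thresholds are placed at fixed centiles
of a kernel-smoothed estimate of each vital sign's ward distribution, with
no outcome labels involved — together with everything needed to evaluate the
result against a labelled cohort.

For a vital sign with samples $x_1,\dots,x_n$ the smoothed CDF is the
Gaussian-mixture CDF $P(x) = \tfrac1n\sum_i \Phi((x-x_i)/h)$ with bandwidth
$h = 1.06\,\hat\sigma\,n^{-1/5}$. Lower thresholds sit at the 10th/5th/1st
centiles and upper thresholds at the 90th/95th/99th (scores 1/2/3); SpO₂ is
one-sided (20th/10th/2nd) and temperature, at 0.1 °C resolution, has no
score-2 bands (10th/1st and 90th/99th). Discrimination against the composite
outcome (cardiac arrest, unanticipated ICU admission, or death within *T*
hours of an observation, first event only) is measured by AUC (mid-rank
Mann–Whitney, DeLong CIs) and AUC-PR (average precision, bootstrap CIs).

The package ships three ready-made systems as code and as JSON configs
(`inst/extdata/`): the **manual CEWS** (thresholds from manually charted
observations, with the +2 oxygen score), the original **continuous CEWS**
(thresholds from bedside-monitor data), and **NEWS** as the supervised
comparator. Because the hospital databases behind the published systems are
not public, a seeded synthetic ward-cohort generator with exact marginal
quantile functions (`generate_cohort()`) stands in for them in all tests.

Audience: researchers deriving candidate track-and-trigger systems from
their own observation databases, and anyone needing a reproducible EWS
scoring/evaluation engine.

## Worked example

Generate a synthetic cohort, apply the admission and observation-set rules,
derive a CEWS from the cleaned data, and evaluate the shipped manual CEWS
against the composite outcome at 24 h:

```r
library(cews)

cohort <- generate_cohort(cohort_config(n_admissions = 4000, seed = 42))

filt <- filter_admissions(cohort$admissions, cohort$observations)
print(filt)
#> Admission filter: 3823 of 4000 admissions included
#>   excluded (underage): 33
#>   excluded (palliative_specialty): 19
#>   excluded (same_day_alive_discharge): 125
#>   excluded (no_complete_observation): 0

obs <- subset(cohort$observations, admission_id %in% filt$included_ids)
pp <- preprocess_observations(obs)   # drop >2-missing / implausible, mean-impute
pp$report
#>             kept too_many_missing      implausible
#>            45694                5               93

derived <- derive_ews(pp$observations, name = "ward CEWS")
print(derived$tables$rr)
#> Band table: Respiratory rate (breaths/min) (resolution 1)
#>  range score
#>   <= 8     3
#>   9-13     2
#>     14     1
#>  15-21     0
#>  22-24     1
#>  25-31     2
#>  >= 32     3

lab <- label_observations(pp$observations, cohort$events, horizon = 24)
scores <- score_observations(lab$labeled, cews_manual())
evaluate_scores(scores, lab$labeled$label, n_boot = 500, seed = 1)
#> Score evaluation: 962 positives / 44691 negatives
#>   AUC    0.917 (95% CI 0.906-0.928, DeLong)
#>   AUC-PR 0.514 (95% CI 0.484-0.547, bootstrap)
```

Reading the numbers: the derived respiratory-rate bands bracket the
generator's 15–21 breaths/min normal range with score-3 tails at ≤8 and ≥32
(these are the centiles of *this* cohort — the point of the method is that
thresholds follow the database). An AUC of 0.917 means a randomly chosen
pre-event observation outscores a randomly chosen event-free one 91.7% of
the time (ties half-counted); the AUC-PR of 0.514 is the average precision
over alerting cutoffs, against a positive prevalence of ~2% of observation
sets.

Which vital sign explains a performance gap between two systems? Swap one
variable's thresholds at a time:

```r
substitution_analysis(cews_continuous(), cews_manual(oxygen = FALSE),
                      lab$labeled, lab$labeled$label)
#> Substitution analysis (base AUC 0.908)
#>  variable   auc pct_change
#>        hr 0.912     +0.42%
#>        rr 0.915     +0.73%
#>      temp 0.908     +0.00%
#>       sbp 0.908     -0.05%
#>      spo2 0.908     +0.00%
```

SpO₂ changes by exactly 0 because its band tables are identical in both
systems; `pct_change` is `(AUC_hybrid − AUC_base)/AUC_base × 100`.

## Command line

Every step is also a file-based CLI subcommand
(`simulate`, `preprocess`, `derive`, `score`, `label`, `evaluate`,
`substitute`):

```sh
Rscript -e 'cews::ews_cli()' simulate --n 2000 --seed 7 --out sim/
Rscript -e 'cews::ews_cli()' preprocess --observations sim/observations.csv \
    --admissions sim/admissions.csv --out clean.csv --report prep.json
Rscript -e 'cews::ews_cli()' derive --observations clean.csv --out mycews.json
Rscript -e 'cews::ews_cli()' label --observations clean.csv \
    --events sim/events.csv --horizons 12,24,48 --out labeled.csv
Rscript -e 'cews::ews_cli()' evaluate --labeled labeled.csv \
    --ews mycews.json --horizons 24 --out metrics.json
```

## Layout

* `R/` — scoring engine and shipped definitions (`ews-model.R`,
  `definitions.R`), threshold derivation (`threshold-derivation.R`),
  preprocessing, outcome labelling, evaluation, synthetic cohort, CSV/JSON
  I/O, CLI.
* `inst/extdata/` — the three shipped system configs and the default centile
  specs, as JSON.
* `tests/testthat/` — unit, property and acceptance suites with independent
  brute-force oracles (`helper-oracles.R`).
* `vignettes/centile-ews-methods.Rmd` — the methods notes: model,
  conventions (band boundaries, rounding, tie-breaks), synthetic-world
  assumptions, and known limitations.
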