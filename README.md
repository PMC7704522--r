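# baroN1

Individual (N-of-1) baroreflex–chemoreflex interaction testing from
repeated phenylephrine boli.

## The problem

Baroreflexes buffer blood-pressure changes; peripheral chemoreflexes,
activated by hypoxia, raise sympathetic outflow and interact with them.
Individuals differ widely in how chemoreflex activation changes their
baroreflex function, and group averages hide it. When each subject receives
many identical phenylephrine boli under normoxia and under normocapnic
hypoxia, every bolus is a replicate and condition effects can be tested
*within* one person. Each bolus yields:

- **cardiovagal baroreflex sensitivity (BRS)** — the slope of the Oxford
  regression `RRI(i+1) = a + BRS · SBP(i)` over the drug-induced pressure
  rise (ms/mmHg), accepted when Pearson's *r* > 0.5;
- **pressor sensitivity (ΔSBP)** — peak minus baseline systolic pressure
  (mmHg), an inverse index of baroreflex blood-pressure buffering, with
  baseline = mean of the 10 pre-bolus beats and peak = best mean of 3
  consecutive systolic values within 60 s.

The package implements the full pipeline: a calibrated beat-to-beat
simulator, per-bolus extraction, per-subject Welch tests with
decreased/increased/unchanged classification, cohort-level paired tests on
per-subject medians, a Monte-Carlo planner for the number of bolus
repetitions, and hypoxic respiratory chemoreflex metrics. Published
per-subject summary tables from a nine-subject crossover study ship as
plain-text reference fixtures and parameterize the default simulated
cohort.

## Worked example

```r
library(baroN1)

recs <- simulate_cohort(reference_cohort_spec(), seed = 1)
resp <- extract_cohort(recs)

cmp <- compare_cohort(resp, "brs")
classify_cohort(cmp)
#> decreased increased unchanged
#>         6         0         3

cmp[cmp$subject == "08", c("mean_normoxia", "mean_hypoxia",
                           "t_statistic", "p_value", "classification")]
#>   mean_normoxia mean_hypoxia t_statistic  p_value classification
#> 8          16.3         8.85        -8.5 5.12e-10      decreased

group_analysis(resp, "brs")
#> <group_result> brs: normoxia 20.56 +/- 1.95 vs hypoxia 15.11 +/- 1.71 (n = 9)
#>   paired difference -5.45 +/- 1.39, t(8) = -3.935, p = 0.004326

sensitivity_curve(plan_spec(n_grid = c(5, 10, 15, 20), n_sim = 500), seed = 1)
#> <plan_result> method ttest_power, effect 6 +/- 3, bolus SD 6.54
#>  n_boli sensitivity  mc_se auc
#>       5       0.252 0.0194  NA
#>      10       0.510 0.0224  NA
#>      15       0.622 0.0217  NA
#>      20       0.704 0.0204  NA
#> no grid entry reaches sensitivity 0.80
```

Six of the nine simulated subjects are classified as having significantly
lower BRS in hypoxia — the same pattern as the reference summaries the
cohort was parameterized from. The group layer shows the cohort-average BRS
drop (here ≈ 5.5 ms/mmHg on per-subject medians), and the planner shows how
detection sensitivity for a 6 ± 3 ms/mmHg individual effect grows with the
number of boli.

The same tests run directly on printed summary rows:

```r
welch_t_from_summary(14.4, 0.8, 20, 8.3, 0.8, 20)$t   # 5.392
chemoreflex_response(13.66, 12.50, 15.29)              # -7.59 (l/min)/%
```

`run_pipeline(pipeline_config(seed = 1), "out/")` executes
simulate → extract → analyze → plan end to end and writes CSV tables,
forest plots and a run log (config hash, seed, rejection reasons) under
`out/`.

## Documentation

The methods vignette (`vignettes/baroreflex-n-of-1-methods.Rmd`) describes
the estimators, the simulator's calibration and its limits, the planning
methodology, and every tunable default.
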