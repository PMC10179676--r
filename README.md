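# iuiselect

Threshold-based selection of couples for intrauterine insemination (IUI).

IUI is a low-cost assisted-reproduction technique with a low per-cycle
success rate (~8-12%), so identifying couples with essentially no chance of
success — and referring them straight to IVF/ICSI — raises the realized
pregnancy rate and shortens time to pregnancy for everyone else. This
package implements, as a tested reusable pipeline, a decision-rule learning
procedure for that triage on two-period per-cycle cohort data:

1. **Discovery** — for each semen, demographic and female parameter, flag
   the extreme value beyond which *no pregnancy* occurred in the first
   recruitment period: an upper cutoff `max(P)` when
   `max(P) < max(N)` strictly (pregnancy group `P` strictly inside the
   no-pregnancy group `N`), a lower cutoff symmetrically.
2. **Validation** — keep a candidate only if the second period's cohort is
   consistent with it (its source group's extreme stays within the cutoff,
   boundary inclusive).
3. **Binarization** — each surviving rule becomes a 0/1 normal/altered flag
   per cycle (strictly beyond the cutoff = altered).
4. **GEE** — the flags are tested jointly in a binomial-logistic
   generalized estimating equation with exchangeable working correlation
   (cycles cluster within couples) and robust sandwich covariance, solving
   `sum_i D_i' V_i^-1 (y_i - mu_i) = 0` with per-term Wald (Type III)
   tests and odds ratios. Implemented from scratch and cross-checked in
   the tests against statsmodels' GEE to 1e-4.
5. **Policy** — decline IUI for a cycle when any selected rule flags it;
   evaluate retrospectively the pregnancy rate the policy would have
   achieved and the relative gain over the observed rate.

A synthetic-cohort generator (couple-level random intercepts, truncated-
normal covariates matching the published summaries, optional hard outcome
thresholds, follow-up stopping at pregnancy) makes every stage testable
without patient data.

## Worked example

Reproduce the published thresholds from the per-period group extremes
(`published_extremes()` ships the discovery/validation min-max tables):

```r
library(iuiselect)
fx  <- fixture_from_extremes(published_extremes(), n_per_group = 30, seed = 1)
per <- split_periods(fx)
rules <- validate_thresholds(discover_thresholds(per$discovery, fx$parameters),
                             per$validation)
rules[rules$status == "validated", c("parameter", "direction", "cutoff")]
#>              parameter direction cutoff
#>               male_age     upper  41.00
#>       ej_concentration     lower  10.36
#>         ej_total_count     lower  51.79
#>      ej_alkaline_comet     upper  72.00
#>            su_immotile     upper  45.00
#>      su_alkaline_comet     upper  59.00
#>       su_neutral_comet     upper  82.00
#>                    bmi     upper  45.00
#>   infertility_duration     upper 120.00
#>                     lh     upper  27.28
#>  antral_follicle_count     lower   3.00
```

Read: no pregnancy was ever observed with male age above 41 years,
ejaculate total sperm count below 51.79 million, post-swim-up alkaline
Comet above 59% affected sperm, basal LH above 27.28 mUI/mL, and so on —
consistently across both recruitment years.
`validate_thresholds(..., cutoff_policy = "validation")` re-reads the
cutoffs from the second period (swim-up neutral Comet 65, infertility
duration 84), matching the mixed-period values of the published summary.

Descriptive statistics of a cohort with the published recruitment counts:

```r
describe_cohort(published_counts_cohort())
#>      period couples cycles pregnancies rate_per_cycle
#>   discovery      93    193          18           9.33
#>  validation     104    216          25          11.57
#>      global     197    409          43          10.51
#>  cumulative_rate_per_couple multiple_pregnancies multiple_pregnancy_rate
#>                       19.35                    2                   11.11
#>                       24.04                    5                   20.00
#>                       21.83                    7                   16.28
```

(11.57% per cycle and 24.04% per couple in the validation period; 10.5%
per cycle and 21.8% per patient globally.)

Full pipeline on synthetic data, via R or the CLI:

```r
cfg <- pipeline_config(synthetic = synthetic_config(seed = 101),
                       seed = 101, outdir = "out")
res <- run_pipeline(cfg)   # rules.json, gee_report.csv, policy_report.json, ...
```

```sh
Rscript -e 'iuiselect::iui_cli()' run --seed 101 --outdir out
Rscript -e 'iuiselect::iui_cli()' discover --cohort cohort.csv --params params.csv --out cand.json
```

## A note on the GEE and separation

A validated threshold flags only never-pregnant cycles *by construction*,
so its binary flag predicts failure deterministically and has no finite
log-odds: `fit_gee()` raises an explicit separation error by default,
while the pipeline uses `on_separation = "drop"`, which removes such
columns from the fit and treats them as selected by construction. See the
methods vignette (`vignettes/iui-threshold-algorithm.Rmd`) for the full
rationale and the other numerical conventions.
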