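---
title: "Threshold discovery, consistency validation and GEE modelling of IUI outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Threshold discovery, consistency validation and GEE modelling of IUI outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Intrauterine insemination (IUI) has a low success rate per cycle (roughly
8-12%), and couples with very low chances are better referred directly to
IVF/ICSI. `iuiselect` implements a decision-rule learning procedure for
that referral: in a first recruitment period (the *discovery* year) it
finds, for each male and female parameter, the extreme value beyond which
no pregnancy was ever observed; it then checks in a second period (the
*validation* year) that the pregnancies of an independent cohort stay
within those limits; the surviving thresholds are turned into binary
normal/altered covariates, tested jointly in a binomial-logistic
generalized estimating equation (GEE), and the resulting rule — *decline
IUI if any selected parameter is altered* — is evaluated retrospectively
by the pregnancy rate it would have achieved.

The unit of analysis is the cycle, the cluster is the couple (up to four
cycles; follow-up ends at the first clinical pregnancy), and the outcome
is binary clinical pregnancy per cycle.

## Threshold discovery and validation

For a parameter with values $x$ and outcome groups $P$ (pregnancy) and
$N$ (no pregnancy) in the discovery period, an **upper** candidate rule is
emitted when $\max(P) < \max(N)$ strictly, and a **lower** candidate when
$\min(P) > \min(N)$ strictly: there must exist cycles beyond the pregnancy
group's extreme, and none of them may be pregnant. Ties defeat the
condition (a shared maximum means pregnancies *were* observed at the
boundary region).

Two conventions interact here:

* **Direction policy.** Each parameter is scanned in one clinically
  coherent direction only (counts and motility: lower; age, immotile
  fraction, DNA fragmentation, BMI, infertility duration, LH: upper;
  estradiol and antral follicle count: lower). Scanning both directions
  everywhere would flag strictly-contained extremes (e.g. semen volume)
  that carry no clinical meaning; the shipped reproduction parameter file
  (`published_parameters()`) excludes those parameters from flagging
  altogether.
* **Source group.** The cutoff is the extreme of the parameter's
  `source_group`. For male parameters this is the pregnancy group (the
  cutoff is the largest/smallest value at which a pregnancy still
  occurred); for female parameters the published convention places the
  cutoff at the **no-pregnancy** group's extreme (the most extreme value
  observed at all, e.g. BMI 45). The emission condition is the strict
  containment of the pregnancy extreme in either case; only the value
  used as the cutoff changes.

**Validation** re-reads the source group in the second period: an upper
rule survives iff that group's maximum does not exceed the cutoff
(boundary inclusive — a validation pregnancy at exactly the cutoff is
consistent with "no pregnancies above it"); a lower rule symmetrically.

**Cutoff policy.** Validated rules keep the discovery cutoff by default.
The published final cutoffs mix periods (the swim-up neutral Comet 65%
and the infertility duration 84 months are second-period extremes, while
male age 41 and LH 27.28 are first-period values), so
`validate_thresholds(cutoff_policy =)` offers `"discovery"` (default),
`"validation"` and `"tighter"` — the last keeps whichever cutoff flags
more cycles (the smaller upper cutoff, the larger lower cutoff), which is
the conservative reading of "no pregnancies beyond either period's
extreme".

**Binarization** flags a cycle as altered (1) when its value is strictly
beyond the cutoff; a value exactly at the cutoff is normal (a pregnancy
occurred there); a missing value yields a missing flag.

```{r}
library(iuiselect)
fx <- fixture_from_extremes(published_extremes(), n_per_group = 30, seed = 1)
per <- split_periods(fx)
rules <- validate_thresholds(discover_thresholds(per$discovery, fx$parameters),
                             per$validation, cutoff_policy = "discovery")
rules[rules$status == "validated", c("parameter", "direction", "cutoff")]
```

## The GEE

Cycles of one couple are correlated, so the binary flags are tested with
a marginal logistic model estimated by generalized estimating equations:

$$\sum_i D_i^\top V_i^{-1} (y_i - \mu_i) = 0, \qquad
  \mu = \mathrm{logit}^{-1}(X\beta),\; D_i = A_i X_i,\;
  V_i = \phi A_i^{1/2} R(\alpha) A_i^{1/2},$$

with $A_i = \mathrm{diag}(\mu(1-\mu))$ and $R(\alpha)$ exchangeable: any
two cycles of a couple share the association $\alpha$. Numerical choices:

* $\phi$ (dispersion) and $\alpha$ are re-estimated each quasi-scoring
  step by Pearson-residual moment estimators, both with an $N - p$
  degrees-of-freedom correction ($\phi = \sum e^2/(N-p)$; $\alpha$ from
  all within-cluster residual pairs over $(\#\text{pairs} - p)\,\phi$).
  $\alpha$ is clamped to its admissible exchangeable range
  $(-1/(n_{\max}-1),\, 1)$.
* Iteration starts at the independence GLM estimate and stops when the
  largest coefficient change drops below `tol` ($10^{-6}$ by default,
  100 iterations maximum). The exchangeable inverse is applied in closed
  form ($R^{-1} = aI + bJ$), so each step is a handful of vectorized
  cluster reductions and the fit scales to thousands of clusters.
* Standard errors are the robust sandwich $B^{-1} M B^{-1}$; inference
  (Wald $z$, normal reference, 1.96-quantile CIs on the odds-ratio scale)
  is valid even when the working correlation is misspecified. No
  small-sample correction is applied, matching the conventions of the
  statistical environment the procedure was designed in. For this binary
  main-effects design the per-coefficient Wald test *is* the Type III
  test of each term.
* Rows with a missing flag are excluded (complete case) with a logged
  count. Collinear columns raise an error naming the offending columns.

The implementation is cross-checked in the test suite against an
independent reference GEE implementation (Python statsmodels) to
$10^{-4}$ relative on coefficients and robust SEs, against ordinary
logistic regression in the singleton-cluster/independence limit, and by a
robust-CI coverage simulation.

### Separation: the structural caveat

A threshold rule that survived validation flags, by construction, only
cycles that never ended in pregnancy — in *both* periods. Its binary flag
is therefore a deterministic failure predictor on the very cohort that
produced it: the flag's log-odds is $-\infty$, no finite Wald statistic
exists, and the quasi-scoring iteration diverges. `fit_gee()` detects the
divergence ($|\beta| > 30$) and errors by default. The pipeline instead
calls `fit_gee(on_separation = "drop")`: diverging columns are removed
from the fit, reported in `$separated`, and treated as *selected by
construction* — a parameter whose alteration is perfectly associated
with failure needs no test at the 5% level. The published odds ratios
for these flags (finite, with narrow CIs) cannot be reconstructed from a
binary main-effects model for exactly this reason; this package reports
the deterministic association honestly instead of reproducing those
numbers.

Two further degeneracies are handled before the fit: validated rules that
flag no cycle at all (their column is constant; common when a cutoff sits
at the global data boundary, as the published female cutoffs do) are
dropped as uninformative, and exactly identical flag columns are merged
into one representative whose selection outcome the aliases inherit.

## The decision policy

`recommend_iui()` declines a cycle when at least `k` (default 1) selected
rules flag it; missing values abstain, and an empty rule set recommends
everything. `evaluate_policy()` partitions all cycles by
(recommended × pregnant), reports the four fractions as percentages of
all cycles, the predicted rate
$100 \cdot \text{retained pregnant} / \text{retained}$, and the relative
increase $(\text{predicted}/\text{observed} - 1) \cdot 100$. Because a
validated rule never declines a pregnant cycle of its source group, the
predicted rate can only move up; the strict-gain property is asserted in
the tests. Percentages are printed to 1 decimal and rates to 2, matching
the precision of the published report; the unrounded values are always
carried in the objects and the JSON artifacts.

`describe_cohort()` computes the descriptive surface per period and
globally: pregnancies, cycles, couples, per-cycle rate, cumulative rate
per couple, pregnancies by cycle index, multiple-pregnancy rate.

## The synthetic generator

No patient-level data are distributed, so `generate_cohort()` states the
world the analysis assumes and makes every stage testable:

* **Cohort shape.** Two periods of 93 and 104 couples, up to 4 cycles
  each. A non-pregnant couple returns for a further cycle with
  probability `continuation = 0.64`; with the ~10.5% per-cycle rate this
  yields the observed ~2.08 cycles/couple (without dropout a 4-cycle
  follow-up would average ~3.4).
* **Covariates** are drawn once per couple from truncated normals whose
  mean/SD/bounds reproduce the published per-parameter summaries
  (`published_covariates()`). Ages, BMI and basal hormones genuinely are
  per-couple constants; treating semen parameters the same way is a
  simplification — real per-cycle semen variability is *not* modelled.
  The joint correlation between the 25 covariates is not modelled either.
* **Outcome.** Per-cycle pregnancy is Bernoulli with
  $p = \mathrm{logit}^{-1}(\beta_0 + b_i + x^\top\beta)$ and a couple
  random intercept $b_i \sim N(0, \sigma^2)$, $\sigma = 0.8$ by default
  (moderate heterogeneity; the implied within-couple outcome correlation
  is small, which is what the data's ~10% rate can support). The default
  intercept solves the logit-probit marginalization approximation so the
  *marginal* rate is ~0.105.
* **Hard rules** force $p = 0$ beyond a cutoff, emulating parameter
  regions from which no pregnancy is obtained; discovery then recovers
  the pregnancy-group extreme exactly (the sample extreme approaches the
  hard cutoff from the feasible side).

A green test on this generator establishes that the machinery is correct
under the stated world — it does not establish that real IUI cohorts
satisfy the world's assumptions (couple-constant semen quality,
logistic-linear effects, a single latent intercept).

Because the realized cycle counts of a stochastic generator cannot equal
193 and 216 exactly, `cohort_from_counts()` / `published_counts_cohort()`
build the published recruitment counts deterministically (couples,
cycles, pregnancies by cycle index, multiples) for the descriptive
checks. The published first-period by-cycle split (8/4/2/3) sums to 17 of
18 pregnancies; the unplaced pregnancy is put in cycle 1. The published
first-period rate "10.1%" is not reproducible from 18/193 = 9.33%; the
package reports the computed value.

## Worked-example fixtures

`fixture_from_extremes()` realizes a table of per-period, per-group
min/max values exactly: the first record of each block carries every
parameter's group minimum, the second its maximum, interior records draw
uniformly between them. Discovered cutoffs depend only on the placed
extremes, so the worked example is deterministic under any seed. The male
validation-period no-pregnancy block is not published; the shipped table
(`published_extremes()`) fills it from the all-patient ranges and marks those
rows `synthetic = TRUE` — they cannot affect any male threshold, which
uses the pregnancy group in both periods.

## Known limitations

* The decision thresholds are in-sample extremes; no uncertainty is
  attached to them (no bootstrap, no ROC-style optimization — out of
  scope by design).
* The GEE cannot test deterministic flags (above); on cohorts where every
  validated rule separates, the model reduces to the intercept and the
  selection is driven entirely by the separation rule.
* The boundary semantics of the antral-follicle-count rule follow the
  "< 3 is altered" wording: the rule is stored with cutoff 3 and flags
  strictly-below values.
* Missing covariates are never imputed: rules abstain per cycle, the GEE
  is complete-case.
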