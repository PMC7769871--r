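---
title: "Defined-daily-dose AMU monitoring: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Defined-daily-dose AMU monitoring: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pigamu)
```

## The quantification model

Monitoring systems based on defined daily doses estimate *potential
treatment days* from prescribed amounts. For every prescribed product the
package resolves the active ingredients and converts each ingredient mass
into a number of Swiss defined daily doses:

$$
\mathrm{nDDD_{ch}} \;=\; \sum_{\text{ingredients}}
\frac{\text{amount (mg)}}
     {\mathrm{DDD_{ch}}\ (\mathrm{mg/kg}) \times \text{standard weight (kg)}}
$$

with the ESVAC standard weights 4 kg (piglet), 12 kg (weaner), 50 kg
(fattener) and 220 kg (sow). The calculation runs separately per ingredient
and the terms are added, so a combination product (e.g. a
sulfonamide–trimethoprim premix) contributes one term per active
ingredient. Dividing a farm-and-category total by the denominator animals —
sows *kept*, other categories *produced per year* — yields
nDDDch/animal/year, and the farm total is the plain (unweighted) sum of the
four category values. The formula block defining the farm summary admits a
weighted alternative; we implement the plain sum because the per-animal
values are already normalised within category and the summary is meant to
be read next to the category values it adds up.

Assumptions inherited from the metric:

* Prescribed amount is a proxy for administered amount; on-farm dosing may
  deviate (the classical defined-dose caveat, as opposed to "used daily
  dose" systems).
* Allocation of records to age categories happens at the source (farmer and
  herd veterinarian); the package never re-ages animals.
* A category with zero animals but recorded usage is a data defect: the
  per-animal value is reported as missing (`NA`), never 0 or infinity.
* Farms with zero usage are legitimate observations and stay in every
  denominator and statistic.

## The formulary

All reference data live in a validated registry (`new_formulary()`): the
standard weights, the DDDch values keyed by *(ingredient, route/form)*, the
product compositions and the HPCIA class set (default: cephalosporins,
fluoroquinolones, macrolides, polypeptides). Two deliberate rigidities:

* **No route fallback.** National defined doses differ between injectables,
  premixes and other oral forms; a missing *(ingredient, route)* key is an
  error, because silently substituting the dose of another formulation
  would corrupt the metric.
* **No IU conversion.** Ingredients dosed in international units (e.g.
  colistin) must be entered already converted to mg/kg by the formulary
  author; conversion factors are product-specific and out of scope.

The shipped demo formulary is synthetic and illustrative; real analyses
must load the national registry. Long-acting injectables with duration
factors can only be represented as distinct route entries — the schema
deliberately has no duration multiplier, since none is defined for the
DDDch system used here.

## Descriptive layer

Distribution tables are computed on unrounded totals under both metrics
(nDDDch and kg of active ingredient); unrounded shares always sum to 100%.
Display rounding is *half away from zero* to integer percent, which matches
every cross-checkable published monitoring table we reproduce. Descriptive
statistics use type-7 (linear interpolation) quartiles by default — the
most common convention, with type 6 available because published tables
rarely state theirs — and a t-based 95% CI for the mean,
$\bar x \pm t_{n-1,0.975}\, s/\sqrt n$.

## Inferential layer

* **Between categories:** Kruskal–Wallis with midranks and the standard
  tie-correction divisor, p from the $\chi^2_{k-1}$ approximation. For
  pooled $N \le 10$ an exact permutation p is available by full enumeration
  of all distinct rank assignments (the same enumeration serves as the
  oracle in the test suite, against an independently sampled permutation
  distribution). All-identical data yield $H = 0$, $p = 1$.
* **Post-hoc:** two-sided pairwise tests with the Bonferroni multiplier
  $k(k-1)/2$, capped at 1. The default flavour is the unpaired rank-sum
  test; because the four categories are observed on the *same* farms a
  paired signed-rank flavour is provided as an option. The published
  description does not say which was used; we default to the unpaired test
  as the weaker (more conservative about the pairing assumption) choice and
  expose the alternative.
* **Regressions:** ordinary least squares with the slope t-test,
  $R^2$ and $\mathrm{adj}\,R^2 = 1-(1-R^2)(n-1)/(n-2)$. The suite runs the
  six within-herd pairs (sows–piglets, sows–weaners, sows–fatteners,
  piglets–weaners, piglets–fatteners, weaners–fatteners; the older category
  is the predictor) plus farm-total usage on herd size (sows kept).
* **Diagnostics:** Shapiro–Wilk for residual normality and the studentized
  Breusch–Pagan statistic (auxiliary regression of squared residuals on the
  predictor, $LM = nR^2_{aux} \sim \chi^2_1$) for homoscedasticity —
  advisory only; they never alter estimates. Residuals that are zero to
  double precision make the tests "not assessable".

Significance is fixed at $\alpha = 0.05$ throughout.

## The synthetic cohort generator

Real monitoring records are confidential, so the generator emulates the
statistical structure the analysis assumes, for a default population of 71
farrow-to-finish farms:

* **Herd sizes** (sows kept): truncated lognormal, `meanlog log(70)`,
  `sdlog 0.55` on [10, 220], giving a mean near 79 and SD near 40.
  Produced animals scale the sow count by 30.3 (piglets), 26.1 (weaners)
  and 11.8 (fatteners) per sow and year with 20% lognormal noise — ratios
  consistent with Swiss production figures.
* **Per-animal usage:** zero-inflated lognormal per category. Zeros are
  real (some farms treat a category not at all) and the positive part is
  strongly right-skewed (category maxima an order of magnitude above the
  medians). Parameters were fitted to the published quantile structure;
  each category is capped at its observed maximum (11.5, 13.3, 9.9, 13.8
  nDDDch/animal/year). A lognormal cannot match all five published
  quantiles of every category simultaneously — the simulated sow median
  (≈1.9) and overall median (≈4.7) sit slightly below the published 2.1
  and 5.2 — which we accept, since the calibration targets are the effect
  sizes below, not the exact quantiles.
* **Linkage:** piglet usage is linear in sow usage plus zero-inflated
  lognormal noise (`piglet = 0.10 × sow + ε`, with the zero indicator
  switching off the whole linked value). This encodes the biological story
  that sow health around farrowing (e.g. postpartum dysgalactia, reduced
  colostrum) drives piglet treatments. Weaner and fattener usage are left
  unlinked: the corresponding published relationships are reported as not
  significant.
* **Herd-size effect:** a multiplicative tilt `(sows/70)^0.5` applied to
  all four category values, i.e. on the farm-total scale that the herd-size
  regression analyses.
* **Calibration:** slope 0.10 and tilt exponent 0.5 were chosen by a grid
  search over 200 replicate cohorts so that the *recovered* mean adjusted
  R² is ≈0.19 for the piglet-on-sow regression and ≈0.06 for the herd-size
  regression, with the piglet usage median ≈0.5. `analysis/04_calibration.R`
  re-runs this check (100 cohorts, mean adj R² 0.184 and 0.059).

Record emission inverts the dose formula exactly: for each farm × category
with a positive target the class mix is drawn from configurable weights
(penicillin-dominated everywhere except weaners, where sulfonamide and
tetracycline premixes dominate — the oral-group-treatment signature), and
product quantities are computed as
`quantity = nDDDch × dose × weight / concentration`. Quantification of the
emitted records therefore reproduces the latent targets to floating-point
accuracy; this round trip is the pipeline's end-to-end test.

**What the generator does not emulate** — and hence what passing tests do
*not* show about real data: treatment indications and course structure,
seasonality, within-year dynamics, farm management and biosecurity
covariates, dependence between weaner/fattener usage and the rest, and
reporting artefacts of real monitoring programmes (late entries, unit
typos). It provides distributional realism for exercising the pipeline,
not an epidemiological model of Swiss pig farming.

## Numerical choices

* Aggregation runs in double precision; R's summation uses extended
  (long-double) accumulators, and order-independence of `quantify()` is
  asserted by test.
* Determinism: every stochastic step takes an explicit seed
  (`withr::with_seed`), cohorts are bit-reproducible under
  `(config, seed)`, and `run_pipeline()` writes byte-identical outputs for
  identical inputs.
* Exact permutation p-values compare statistics with a `1e-10` slack to
  absorb rank-sum rounding; quantile and CI computations defer to
  `stats::quantile`/`qt`.
* Year filtering drops off-year records with a logged count; unresolvable
  products or missing DDDch keys fail loudly by default, with an explicit
  opt-in (`on_error = "exclude"`) that records the exclusions — mirroring a
  monitoring programme's completeness rule.

## Problem sizes

The shipped analyses use cohorts of 71 farms; replicate-based checks use
100 (calibration script) and 200 (acceptance script) cohorts, and the
familywise-error simulation uses 2000 null datasets. These sizes give
Monte-Carlo standard errors comfortably below the tolerances they are
compared against (e.g. ≈0.01 for the mean adjusted R² over 200 cohorts).

## Known limitations

* DDDch values are inputs; the package neither derives them from dosing
  leaflets nor validates them against a national registry.
* No used-daily-dose (UDD), treatment-incidence or mg/PCU metrics; the
  defined-dose metric is the single supported currency.
* The farm-total summary assumes the plain category sum (see above).
* Exact pairwise tests inherit `stats::wilcox.test` conventions (exact
  only for small tie-free samples; otherwise normal approximation with
  continuity correction).
* Single-species, four fixed age categories; no multi-site or
  multi-species extensions.
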