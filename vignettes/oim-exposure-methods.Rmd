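---
title: "Chronic dietary exposure with OIM, sOIM and wsOIM"
author: "oimtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chronic dietary exposure with OIM, sOIM and wsOIM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oimtools)
```

## The estimation problem

Chronic dietary exposure to a food contaminant combines two very
different sources of variation. Consumption surveys capture the
*variability* axis: individuals differ in how much of a food category
they eat and in body weight. Chemical monitoring captures the
*uncertainty* axis: a category's mean contaminant concentration (its
"mean occurrence") is estimated from a finite, often small, set of
analysed samples. The Observed Individual Means (OIM) methodology is the
standard first-tier probabilistic treatment of this problem: the
exposure of individual $i$ is

$$
E_i \;=\; \frac{\sum_c \bar{C}_{i,c} \cdot \bar{O}_c}{bw_i}
\quad \left[\mu\mathrm{g\,kg^{-1}\,bw\,day^{-1}}\right],
$$

where $\bar{C}_{i,c}$ is $i$'s mean daily consumption of category $c$
(g/day), $\bar{O}_c$ the category mean occurrence (µg/g) and $bw_i$ the
body weight (kg). Percentiles of the exposure distribution over
individuals — in particular an upper tail percentile (UTP), here the
95th — are the deterministic estimates (DEs). Uncertainty is propagated
by the non-parametric bootstrap: consumers are resampled with
replacement (one RNG stream) and, independently, occurrence samples are
resampled with replacement (a second stream); replicate $b$ pairs
consumer resample $b$ with the bootstrap mean occurrence $b$, and the
percentile method applied to the $B$ replicate UTPs gives the
probabilistic estimates (PEs), i.e. confidence intervals.

Two implicit OIM assumptions often fail in practice:

1. occurrence values within a category are i.i.d. — violated whenever
   subgroups with clearly different expected contamination exist within
   the category (the distribution is then a mixture);
2. every analysed sample contributes equally to the category mean —
   which ignores how much of each subgroup people actually eat.

`oimtools` implements the two refinements that address these
violations:

* **sOIM** replaces the standard occurrence bootstrap by the
  *stratified* bootstrap: values are resampled with replacement within
  each subcategory, and every subcategory keeps exactly its observed
  sample size in every replicate. The position of the bootstrap mean
  occurrence is unchanged, but its spread shrinks, because
  between-stratum variation is no longer resampled.
* **wsOIM** additionally replaces the arithmetic category mean by a
  weighted mean of subcategory means,
  $\bar{O}_c = \sum_s w_s \bar{O}_{c,s}$ with $w_s \ge 0$,
  $\sum_s w_s = 1$. Two uses are distinguished by the weight source:
  the consumption-aware scheme (*wsOIM\**), where $w_s$ is subcategory
  $s$'s share of the total mean daily consumption of the category; and
  hypothetical sensitivity schemes (*wsOIM°*), deliberately more
  extreme than the consumption-aware one, used to probe the robustness
  of a risk conclusion.

## The case-study design

The package ships the simulation design of a vegetable-oil /
3-monochloropropane-1,2-diol (3-MCPD) case study with three strata:
Seed Oils (SO), Olive Oil (OO) and Extra-Virgin Olive Oil (EVOO).
`simulation_config()` holds its parameters:

* SO occurrence is lognormal with meanlog $\hat\mu = -1.48$. This
  meanlog was fitted to analysed seed-oil samples together with
  $\hat\sigma = 1.20$; the config records both, but generation uses
  `gen_sdlog = 1` for all strata. We read the design's
  "lognorm($\hat\mu$; 1)" literally as sdlog = 1; the fitted
  $\hat\sigma$ remains available for fitting checks, and the ambiguity
  is surfaced as two separate config fields rather than hard-coded.
* OO occurrence is lognormal with meanlog
  $\alpha = \log(1.5 + e^{\hat\mu})$, derived (never stored
  independently), so the OO median sits exactly 1.5 µg/g above the SO
  median ($e^\alpha - e^{\hat\mu} = 1.5$).
* EVOO occurrence is lognormal with meanlog $\log(\mathrm{LOD})$ with
  LOD = 0.035 µg/g, so exactly half of the draws fall below the limit
  of detection.
* Draws below the LOD are flagged censored and substituted at LOD/2
  (the middle-bound scenario), uniformly across strata — censoring is a
  property of the measurement process, not of the stratum, so SO and OO
  draws below the LOD (rare but possible) are treated identically.
* Default sizes: 1000 values per stratum per dataset, 1000 datasets,
  B = 1000 bootstrap replicates; TDI = 2 µg/kg bw/day.
* Weight schemes: the sensitivity scenarios
  $w_{SO} = \{8/10, 1/10, 1/10\}$, $w_{OO} = \{1/10, 8/10, 1/10\}$,
  $w_{EVOO} = \{1/10, 1/10, 8/10\}$ (order SO, OO, EVOO) and the
  consumption-aware $w^* = \{0.07, 0.77, 0.16\}$.

```{r design}
cfg <- simulation_config()
cfg
occ <- simulate_occurrence(cfg, rng_seed = 1)
tapply(occ$value, occ$subcategory, median)
```

## Left-censored data

Two distinct mechanisms handle values below the LOD, and they are
deliberately kept apart:

* **Substitution** (`apply_lod_scenario()`) replaces censored values by
  0, LOD/2 or LOD (lower/middle/upper bound) for use in exposure
  computation. Middle bound is the package default and the only
  scenario used by the shipped study design; the other two exist for
  sensitivity use.
* **Fitting** (`fit_censored()`) never uses substituted values: it
  maximizes the censored likelihood, with density contributions for
  detected values and the CDF at the LOD for censored ones. Censored
  normal, lognormal, gamma and Weibull families are supported (all
  two-parameter, so AIC $= 4 - 2\log L$ exactly), and
  `select_best_fit()` picks the lowest AIC, breaking exact ties by the
  canonical family order with a warning. Optimization is delegated to
  `fitdistrplus::fitdistcens()`; if its default starting values fail,
  moment-based starts and up to three jittered restarts are tried. The
  normal family is fitted untruncated even though concentrations are
  non-negative; with occurrence data far from zero this support
  mismatch is immaterial, and it is noted here rather than silently
  corrected.

## Numerical conventions

* **Quantiles.** Every percentile in the package — DEs, bootstrap
  percentile CIs, eCDF summaries — uses linear interpolation between
  order statistics (R's type 7). The choice is arbitrary but fixed at a
  single definition point so DEs and PEs cannot drift apart.
* **Two RNG streams.** `probabilistic_estimate()` takes a pair of
  seeds: one stream drives consumer resampling, the other occurrence
  resampling, reflecting that the two datasets are bootstrapped
  independently. Replicate $b$ of consumers is paired one-to-one with
  occurrence replicate $b$; this pairing is the minimal-assumption
  reading of "merging" the two bootstrap arrays, and it keeps $B$
  aligned across both axes.
* **Stratum resample sizes** are the observed stratum sizes, not a
  proportional reallocation — controlling each subcategory's sample
  size is the point of the stratified bootstrap. The stratified
  bootstrap must not be used to compensate for inadequate within-stratum
  sample sizes.
* **Degenerate inputs.** A single consumer and a single occurrence
  value yield zero-width CIs rather than errors; empty strata,
  all-censored fitting inputs, weight schemes whose keys do not match
  the strata, and zero total category consumption raise specific
  errors.

## The study runner

`run_study()` evaluates the full grid — OIM, sOIM, wsOIM\* and the
three wsOIM° scenarios — against a common consumer table. Its
replication design follows the simulation study: bootstrap replicate
$b$ draws a *fresh* occurrence dataset from the design, takes one
resample of it (standard for OIM, stratified for the rest), computes
each cell's mean occurrence, and pairs it with consumer resample $b$.
Three sharing choices keep between-method contrasts free of independent
resampling noise, and are choices of this implementation (the design
itself does not pin them down):

* all cells share the same consumer bootstrap stream;
* all cells share the same simulated occurrence datasets;
* all stratified cells share the same stratified resample per
  replicate (they differ only in how they weight it).

DEs for all cells are computed on one common reference dataset drawn
from the same design. Because the case study has a single category,
exposure is linear in the mean occurrence, and the runner computes each
replicate's exposure percentile as (mean occurrence) × (percentile of
the resampled consumption/body-weight ratios); this is exact, not an
approximation. `scale` shrinks $B$ and the number of datasets for
exploratory runs (scaled counts below 10 are rejected).

```{r study}
cons <- simulate_consumers(300, rng_seed = 2)
sr <- run_study(cfg, cons, scale = 0.05, seed = 3)
sr
```

The qualitative behaviour expected from the estimators, and verified by
the test suite, is visible here: sOIM reproduces the OIM DE with a
narrower UTP CI; weighting towards the olive-oil stratum ($w_{OO}$,
$w^*$) shifts the exposure distribution up and widens the CI; weighting
towards SO or EVOO shifts it down.

## Risk characterization and robustness

The UTP is compared with the tolerable daily intake (TDI; 2 µg/kg
bw/day for 3-MCPD). "Not statistically different from the TDI at the
0.05 level" is operationalized as *CI inclusion*: the verdict is
`below_tdi` if the CI's upper bound is below the TDI, `above_tdi` if
its lower bound exceeds it, and `not_different` if the TDI lies inside
the 95% CI. No formal test is defined for this comparison in the
methodology; CI inclusion is our reading, and it is labelled a
heuristic wherever it surfaces. The same caveat applies to
`estimates_differ()`, which declares two estimates different only under
mutual CI exclusion.

`robustness_assessment()` implements the tipping-point-style rule: a
primary conclusion is robust if no sensitivity scenario (wsOIM°) points
to *strictly higher* risk under the ordering
`below_tdi < not_different < above_tdi`; scenarios that do are listed
as tipping schemes. The rule is monotone: adding scenarios can only
break robustness, never restore it.

```{r risk}
primary <- risk_characterization(sr$cells[["sOIM"]], tdi = cfg$tdi)
scen <- lapply(sr$cells[c("wsOIM(w_SO)", "wsOIM(w_OO)", "wsOIM(w_EVOO)")],
               risk_characterization, tdi = cfg$tdi)
robustness_assessment(primary, scen)
```

## What the synthetic consumers emulate — and what they do not

`simulate_consumers()` stands in for an adult food-diary survey of
vegetable-oil consumers. It generates day-level records (so the
`read_consumption()` averaging path is exercised end to end): body
weights are normal(70, 12) kg truncated at 35 kg, ages uniform on
18–80, and each subject consumes each oil subcategory on a given day
with a fixed probability, in a lognormal amount. The default profile
puts about 25 g/day of vegetable oil on the average adult, split
7% / 77% / 16% across SO / OO / EVOO in expectation so that the
consumption-aware weights recover $w^*$. These profile values are
invented, plausible stand-ins — they are not survey estimates.

The generator deliberately does not emulate household sampling
structure, intra-week correlation of diary days, covariates beyond age
and body weight, non-consumers of the category as a distinct mixture
component, or food-classification hierarchies beyond a flat
category/subcategory pair. Tests passing on these synthetic data
therefore demonstrate the correctness and the qualitative behaviour of
the estimators, not the exposure of any real population; the synthetic
seed-oil fixture (`seed_oil_fixture()`) is likewise a synthetic
stand-in, not laboratory data.

## Problem sizes used by the shipped checks

The test suite runs the distributional checks at reduced but still
informative sizes, chosen as the smallest sizes at which the effects
under test are comfortably larger than their Monte Carlo noise:
100,000 draws per stratum for the generator's median-separation and
censoring-rate checks; 100 repeats at B = 1000 for the bootstrap-mean
variance comparison; 50 repeats at B = 500 (300 consumers) for the
CI-narrowing check; 20 repeats of the study grid at `scale = 0.1` for
the UTP ordering checks; 5000 draws with 20% censoring for parameter
recovery. The full-size design (B = 1000 over 1000 datasets) is the
`run_study()` default.

## Known limitations

* OIM's structural drawbacks are inherited, not fixed: intra- and
  inter-individual variation are not separated, and covariates cannot
  be modelled. The refinements correct the occurrence-side assumptions
  only.
* Upper percentiles remain conservative, a property of OIM itself.
* The between-estimate and estimate-versus-TDI comparisons are CI
  heuristics, not calibrated tests.
* wsOIM° conclusions depend on expert-designed weighting schemes;
  schemes more imbalanced than any plausible consumption pattern should
  be treated as implausible by construction.
* Multi-category assessments are supported by summing per-category
  contributions in `probabilistic_estimate()`, but the shipped study
  design and `run_study()` address a single category.
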