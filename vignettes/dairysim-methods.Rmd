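---
title: "Modelling dairy substitution scenarios in preschool diets"
author: "dairysim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dairy substitution scenarios in preschool diets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dairysim)
```

## The problem

Preschool children in China consume far less dairy than the recommended
350 g/day of liquid milk, and dairy is a principal vehicle for several
nutrients that are chronically under-consumed at that age (calcium,
vitamin A, B vitamins, vitamin D). A standard way to quantify what a
change in dairy habits would buy is a *dietary substitution simulation*:
take observed multi-day diet diaries, compute each child's nutrient
intake, then recompute it under a counterfactual in which the dairy
portion of the diet is replaced or topped up with a candidate product —
soymilk, plain cow's milk, or a micronutrient-fortified formulated milk
powder for preschool children (FMP-PSC) — and compare nutrient adequacy
before and after with paired statistics.

`dairysim` implements that pipeline end to end: validated readers for
diet diaries, supplement records, food composition tables and dietary
reference intake (DRI) rules; an intake engine; a scenario engine for
the five standard models; the reporting statistics; and a seeded
synthetic cohort generator so the whole pipeline is testable without
access to any survey microdata.

## Intake model

Each child contributes a 4-day diary (2 working days, 2 weekend days) of
`(food, grams)` records. With a composition table giving nutrient
content per 100 g edible portion, the diet-only intake is the plain
4-day mean

$$\mathbf{y}_i = \frac{1}{4}\sum_{d=1}^{4}\sum_{r \in \text{day } d}
  \frac{a_r}{100}\,\mathbf{c}_{f(r)},$$

and supplements declared on any diary day are averaged over the same
four days and added. No usual-intake (within-person variance)
adjustment is applied: classification uses the observed 4-day mean,
which is the convention of the survey analyses this package mirrors.
Amounts are grams of edible raw weight; for dairy liquids grams and
millilitres are treated as interchangeable (no density correction).

### Liquid milk equivalents

Dairy items are heterogeneous (liquid milk, milk powder, yogurt, cheese
and other solids), so dairy quantity is expressed in *liquid milk
equivalents* (LME): liquid milk counts at face value, every other dairy
subtype is converted by protein ratio,

$$\mathrm{LME} = \text{grams} \times \frac{\text{protein}/100\,\mathrm{g}}
  {\text{reference milk protein}},$$

with a configurable reference of 3.0 g protein per 100 g liquid milk.
The reference is explicit configuration (`ref_milk_protein`) because the
protein-ratio principle does not by itself fix the constant.

### Adequacy rules

Inadequacy and surplus are classified per child against a DRI rule
table with half-open age bands `[min, max)` in months:

* **EAR / AI** rules: inadequate iff intake is *strictly below* the
  threshold;
* **fiber density**: inadequate iff fiber per 1000 kcal is strictly
  below 10 g;
* **AMDR upper bound**: fat is in surplus iff the percent of energy from
  fat (9 kcal/g) is strictly above the bound.

Boundary values therefore count as adequate / non-surplus, matching the
"below x" phrasing of the underlying definitions; the strict comparison
is applied uniformly. Nutrients with no rule for a child's age emit no
flag (the fat bound, for instance, only applies from 49 months in the
shipped defaults). The bundled rule file
(`dairysim_extdata("dri")`) carries 2013 Chinese-DRI-style values as
*editable placeholders marked user-verify*: the engine never hard-codes
thresholds, and analyses of real data should substitute verified
values.

## The five scenario models

Two scenario families are simulated on the child-level mean dairy
contribution:

| model | mode | substitute |
|---|---|---|
| 1 | substitute all dairy at matching volume | soymilk |
| 2 | substitute all dairy at matching volume | cow's milk |
| 3 | substitute all dairy at matching volume | FMP-PSC |
| 4 | top up dairy to 350 g/d | cow's milk |
| 5 | top up dairy to 350 g/d | FMP-PSC |

Substitution removes the child's entire mean daily dairy nutrient
contribution and adds `LME/100 ×` the substitute composition — dairy
volume is conserved exactly. Top-up adds `max(0, 350 − LME)/100 ×` the
substitute: children at or above the recommendation are returned
bit-identically, and nothing is ever removed. Supplements are never
altered by any scenario. FMP-PSC amounts are expressed per 100 g of
*reconstituted liquid equivalent*, so "matching volume" and "reach
350 g/day" live on the same axis for all three substitutes.

Because the intake computation is linear in the records, operating on
the child-level mean is equivalent to rebuilding the diary record by
record; the package ships the slow record-level path
(`simulate_scenario_records()`) and the test suite verifies agreement
to below 1e-9 relative on small cohorts.

The bundled substitute compositions
(`dairysim_extdata("substitutes")`) are synthetic placeholders at
typical label magnitudes — the genuine product values are not public.
The cow's-milk and FMP-PSC energy densities (62 and 79 kcal/100 g) were
fixed once so that a top-up of the median shortfall (176 g/d) yields
median energy increments of ~109 and ~139 kcal/d, the magnitudes
reported for these scenarios; all other components are ordinary label
values. Users analysing real data should supply verified label
compositions.

## Statistical conventions

All reporting conventions reproduce the behaviour of SPSS, the
environment in which the reference analyses were run, because the
published numbers are only reproducible under the exact convention:

* **Quartiles**: type-6 linear interpolation (SPSS "HAVERAGE") by
  default; type 7 selectable.
* **Rounding**: half-up (away from zero) at 2 decimals, not banker's
  rounding.
* **Percentage-point changes** (`pp_change`) are formed from the
  *already-rounded* percentages. This matters: a calcium inadequacy
  drop from 619/676 to 510/676 is 16.12 points on raw counts but
  16.13 under the rounded-operand convention, and only the latter
  matches the published arithmetic.
* **Wilcoxon signed-rank**: zero differences dropped, midranks for
  ties, tie-corrected variance, no continuity correction, two-sided
  normal p. An exact mode enumerates all sign patterns (n ≤ 24).
* **McNemar**: exact two-sided binomial when the discordant count is
  below 25, else the continuity-corrected chi-square — the SPSS dual
  convention.
* **Mann–Whitney**: exact when `n_a · n_b ≤ 400` (tail doubling via the
  exact U distribution without ties, complete enumeration with ties),
  else the tie-corrected normal approximation without continuity
  correction.
* **Kruskal–Wallis** (tie-corrected H) and uncorrected Pearson
  chi-square delegate to the standard R implementations, which already
  match the SPSS definitions.

For n = 8 untied pairs the normal approximations deviate from the exact
enumeration by at most about 0.07 (signed-rank) and 0.13 (Mann–Whitney
4 vs 4) in two-sided p — the documented tolerance the test suite
asserts; with heavy ties or fewer than ~5 effective pairs the
approximation is unreliable and the exact modes should be preferred.
Significance is two-sided at 0.05 with no multiplicity adjustment,
matching the reporting scheme (letters a–i marking model-vs-baseline
and between-model contrasts).

## The synthetic cohort generator

`generate_cohort()` emulates the *structure* of a 676-child diet survey
(strata 224/226/226 at 37–48, 49–60 and 61–72 months), so that every
pipeline stage has realistic, fully labelled input:

* Dairy consumption is Bernoulli per stratum (~92–94%); each consumer
  receives at least one of four dairy subtypes. The subtype draw uses
  base probabilities solved by fixed-point iteration so that, *after*
  conditioning on "at least one subtype", the marginal consumption
  rates equal the stratum targets — naive rejection sampling would
  inflate them by several points.
* Consumer LME follows a lognormal calibrated to cohort-wide quartiles
  of 84.61 / 174.00 / 255.70 g/d with ~8% zeros from non-consumers:
  target probabilities are mapped to the consumer scale, the median is
  pinned exactly and sigma is the least-squares slope through the
  log-quantiles. The fit trades some IQR fidelity (recovered IQR about
  97–297 g/d) for an exact median. Draws are quantile-balanced (a Latin
  hypercube over the probability strata rather than iid), so the sample
  quartiles sit tightly on the calibration targets; the marginal
  distribution is unchanged but draws are exchangeable rather than
  independent.
* Each child's LME is split across consumed subtypes and diary days
  with gamma weights; solid-dairy grams invert the protein-ratio
  conversion exactly, so recomputing LME from the emitted diary
  reproduces the latent truth to numerical precision (a test
  invariant).
* The non-dairy background diet draws 8–15 foods/day from a generated
  60-food pool of archetypes (grains, vegetables, fruit, meat, egg,
  fish, legumes, oil, snacks) and scales each day to a lognormal
  background energy target (median 880 kcal/d) — together with dairy
  this lands baseline energy near 1000 kcal/d. Dietary vitamin D is
  zero-inflated (only fortified milk powder, a rare fatty-fish food and
  supplements carry it) and iodine is a two-component mixture (a
  high-iodine household food consumed by ~30% of children) to mimic the
  heavy-tailed spread seen in iodine intakes.
* 41.1% of children take a daily supplement with label-scale amounts of
  calcium, vitamin D, vitamin C, iron, zinc, vitamin A, B12 and/or DHA.
* A single seed drives one RNG stream; output is byte-identical across
  runs.

What the generator does *not* emulate: real food-composition values
(per-nutrient baseline medians are only of plausible magnitude, not
calibration targets), correlations between subtypes and background diet
quality, day-of-week effects, and seasonal or regional structure.
Passing tests on synthetic cohorts therefore demonstrate the
correctness of the *pipeline arithmetic and conventions*, not
nutritional conclusions about any real population.

## Numerical and design choices

* Substitution clips components in `(-tol, 0)` to zero with
  `tol = 1e-9` of the operand magnitude; a negative beyond that is an
  internal consistency error, never silently truncated.
* Age bands are half-open in months (`[37,49)`, `[49,61)`, `[61,73)`),
  so stratum membership is unambiguous at the boundaries.
* Supplements contribute on the day declared and are averaged over 4
  days even if taken once; scenarios never touch them.
* All-zero difference vectors make the signed-rank test undefined — the
  analysis layer treats an identity substitution as "no evidence of
  change" (p = 1) rather than an error, while the low-level function
  raises.
* Problem sizes in the test suite: unit tests run cohorts of 20–120
  children; the null-calibration study uses 2000 replicates per test;
  marginal-recovery checks run ten full 676-child cohorts. The whole
  suite completes in well under a minute.

## Worked example

```{r example, eval = FALSE}
co <- generate_cohort(cohort_spec(seed = 1))
cohort <- compute_cohort_intake(co$diet, co$compositions, co$children,
                                co$supplements)
dri <- load_dri_table(dairysim_extdata("dri"))
results <- analyze_cohort(cohort, dri)
render_table(results, 2)   # energy before/after the five models
render_table(results, 5)   # minerals
```

## Limitations

The placeholder composition and DRI files must be replaced with
verified values before any substantive use; the engine is convention-
faithful, but its defaults are structural stand-ins. Mixed-portfolio
scenarios (combinations of yogurt, cheese and liquid milk) and
usual-intake distribution modelling are out of scope, as are portion
estimation and compound-dish decomposition — inputs are assumed
pre-decomposed to component foods.
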