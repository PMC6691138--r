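---
title: "Food-level dairy-fat substitution: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Food-level dairy-fat substitution: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dairyswap)
```

## What the package models

`dairyswap` asks a food-level question: if the food sources of dairy fat
were taken out of people's actual 24-hour recalls — wholly, or up to 5% of
each person's energy — and optionally replaced with the unsaturated-fat
foods that similar people eat on similar occasions, what would happen to
population nutrient intakes and to two composite diet-quality scores?

The analysis chain is: recipe expansion to locate dairy fat in every food;
food metrics (energy density, percent energy from fat, replacement
eligibility); stratum-specific replacement profiles; four modeled diets;
NRF 9.3 and HEI-2015 scoring; survey-weighted estimation.  This vignette
records the modeling assumptions and the places where a design decision had
to be made.

## Dairy fat by recipe expansion

A recipe row states how many grams of an ingredient enter 100 g of a parent
food.  Dairy fat per 100 g is the sum over all dairy-flagged ingredients
reachable through nested recipes of (product of proportions along the path)
× (ingredient fat per gram).  Expansion is linear in the recipe
proportions, depth-capped at 10 with explicit cycle detection — real
food-survey recipe graphs are shallow, so the cap only guards malformed
inputs.  When a recipe implies more dairy fat than the food's stated total
fat (possible with rounded composition data), the value is clamped to total
fat and reported; the clamp never fires on internally consistent tables.

## Food metrics and eligibility

* Energy density is stated kcal per 100 g.
* Percent energy from fat uses the Atwater factor of 9 kcal/g of fat.
  Zero-energy, zero-fat foods (water, diet beverages) are assigned 0 %E so
  they remain classifiable in the lowest fat sextile; zero-energy foods
  with positive fat cannot be given a percentage and are flagged and
  excluded from fat-sextile assignment.
* A food is **replacement-eligible** iff it carries no dairy fat and is not
  saturated-fat dominant.  A tie (SFA exactly equal to MUFA + PUFA) counts
  as eligible: the exclusion rule targets foods with *more* saturated than
  unsaturated fat.

## Strata and replacement profiles

Consumption events are stratified by consumer age group (4–19, 20–39,
40–64, 65+ years), meal type (breakfast; lunch/dinner; snack, including
beverage-only occasions; dessert), and sextiles of food energy density and
percent energy from fat — 576 cells.  Conventions:

* Sextile cutpoints are **left-continuous weighted quantiles**: the
  smallest observed value whose cumulative normalized weight reaches the
  probability.  This definition is exact and directly checkable against a
  cumulative-sum oracle; interpolating definitions differ negligibly at
  survey scale.
* Cutpoints are lower bounds of categories 2–6, so a value exactly on a
  cutpoint falls in the upper category.
* "Frequency of consumption" weighting is survey weight × grams eaten per
  event.  Whether grams, energy, or event counts is the right mass is not
  settled; it is a config switch (`consumption_weighting`), grams by
  default, consistent with using weighted *consumption* for the quantile
  cutpoints.
* Published survey cutpoints can be supplied as fixed config
  (`nhanes_ed_cutpoints()`, `nhanes_fat_cutpoints()`), bypassing
  recomputation.

A stratum's replacement profile is the consumption-weighted average of the
per-gram nutrient vectors of the eligible foods eaten in it.  Profiles are
convex combinations, so every profile nutrient lies within the range of the
contributing foods, and profiles contain exactly zero dairy fat by
construction.  Strata in which no eligible food was eaten have no profile;
`resolve_profile()` falls back by marginalizing fat sextile, then energy-
density sextile, then meal type, then age group, recomputing the weighted
composite at each level and reporting the level used.  The order drops the
most granular axes of the stratification first; the choice matters little
in practice because fallbacks are rare at survey scale (in the worked
example, 562 of 576 strata have direct profiles).

## The four modeled diets

Substitution operates on whole consumed items: a cheese sandwich leaves the
diet as a sandwich, not as its cheese grams.  This matches the large energy
reductions that food-level removal produces and distinguishes the model
from nutrient arithmetic.

* **Model 1 (remove)**: every item whose food carries dairy fat is removed;
  residual dairy-fat energy is exactly zero.
* **Model 2 (remove)**: dairy items are visited in a uniformly random order
  and removed while cumulative removed dairy-fat energy stays within 5% of
  the person's observed total energy.  The random order prevents one meal
  (breakfast, say) from being systematically the removed one.  The first
  item that would cross the cap is partially removed, its grams scaled so
  the removal hits the cap exactly ("up to but not exceeding").  An
  alternative policy that skips the boundary item and leaves removal below
  the cap is available (`partial = "skip"`); the exact-cap policy is the
  default because it makes the cap a sharp, testable invariant.  The cap is
  evaluated against *observed* (pre-substitution) energy.  People whose
  dairy-fat energy is within the cap lose all dairy items, as in Model 1.
* **Swap variants**: each removed item (or partial grams) is replaced by
  equal grams of the profile resolved for the consumer's age group, the
  occasion at which the item was eaten, and the removed food's energy-
  density and fat sextiles.  Grams are conserved exactly; energy is not
  constrained but lands near observed because the replacement shares the
  removed food's energy-density stratum.

Randomization uses one seeded stream per participant (keyed by global seed
and participant id) over a canonically sorted item list, so results do not
depend on row order and single days can be re-run in isolation.

## Scores

**NRF 9.3.**  Intakes are adjusted to 2,000 kcal, expressed as percent of
daily values (protein 50 g, fiber 28 g, vitamin A 900 RAE, vitamin C 90 mg,
vitamin D 20 mcg, calcium 1,300 mg, iron 18 mg, potassium 4,700 mg,
magnesium 420 mg), truncated at 100, and summed to NR (0–900).  The
limiting side interpolates proportionally between minimum and maximum
thresholds — added sugars 6→26 %E, saturated fat 8→16 %E, sodium
1,100→2,000 mg — giving a fraction per nutrient (so 12 %E saturated fat
earns 0.5 limiting points); LIM is 100 × the sum of fractions (0–300),
which reconciles the per-nutrient "0.5 points" scale with the 300-point
maximum.  NRF 9.3 = NR − LIM.  Sodium is thresholded on the 2,000 kcal
energy-adjusted amount by default, consistent with adjusting all intakes;
`sodium_energy_adjusted = FALSE` thresholds raw milligrams instead.

**HEI-2015.**  Thirteen components with maxima (5, 5, 5, 5, 10, 10, 5, 5,
10, 10, 10, 10, 10) summing to 100.  Adequacy components score densities
per 1,000 kcal against the published standards stored in
`hei2015_standards()`; moderation components score inversely between their
best and worst standards; the fatty-acid component scores
(MUFA + PUFA)/SFA between 1.2 and 2.5, with zero saturated fat defined as
the maximum.  All components are densities or %E, so the total is invariant
to uniformly rescaling a day's intake.  Zero-energy days cannot be scored
and are flagged and excluded.

## Survey estimation

Means are ratio estimators Σwx/Σw.  Variances use Taylor linearization:
residuals are totalled per PSU and the variance is the stratum sum of
n_h/(n_h−1) × squared deviations of PSU totals, which reduces exactly to
s²/n for a single stratum of equally weighted singleton PSUs.  Confidence
intervals use the normal 1.96 multiplier (survey degrees-of-freedom
corrections would subtract one interval width class at these sizes and are
not applied).  Dairy-fat consumers are an estimation **domain**: non-
consumers contribute zero residual but their PSUs stay in the variance, so
subgroup SEs reflect the full design.

Because large surveys make trivial differences "significant", a
modeled-versus-observed change is flagged only when the relative change
strictly exceeds 10% *and* a Wald test that the absolute difference exceeds
10% of the observed mean (combined SE, normal reference) rejects at 0.05.
This is a defined operationalization of a hybrid rule, not a claim about
how any particular published analysis computed its asterisks.

## The synthetic survey generator

The generator exists so that the full pipeline is exercisable and testable
without restricted survey files.  Its defaults are the study conditions:

* population mean dairy-fat energy share calibrated to **5.6 %E**, with a
  per-person gamma propensity, ~16% zero consumers, and mild age (+15%
  below 20 y) and ethnicity gradients whose population expectation stays at
  ~1 so the calibration target is preserved;
* ages 4–85 y, lognormal survey weights, configurable strata with two PSUs
  each (the minimum for variance estimation), every stratum × PSU cell
  guaranteed occupied;
* mean energy 2,080 kcal/day; eating occasions drawn as breakfast 20%,
  lunch/dinner 50%, snack 25%, dessert 5% (no published frequencies exist;
  these are plausible and configurable), with within-person occasion counts
  exposed as behavior of the generator rather than asserted facts;
* foods spanning energy density ~0–680 kcal/100 g and fat share ~1–98 %E,
  including zero-energy beverages; a quarter of foods carry dairy fat,
  reached through one- to three-level recipes (pure dairy foods, mixed
  dishes, nested sauce/custard preparations);
* eligible foods are laid out on a dense lattice over (log energy density,
  %fat), with a near-fat-free row at the bottom and damped popularity for
  near-zero-energy items, so that every energy-density × fat sextile cell —
  whether defined by the reference cutpoints or recomputed from the
  generated consumption — contains at least one replacement-eligible food;
* nutrient vectors are internally consistent (energy equals Atwater energy
  of the macronutrients; fat subtypes never exceed total fat; dairy fat
  never exceeds total fat), with micronutrient levels drawn lognormally per
  archetype and dairy-linked bonuses (calcium, vitamins A, D, B12,
  riboflavin) tied to dairy-fat content.

What the generator does **not** emulate: true survey weighting and
nonresponse adjustment, the multi-pass recall instrument, day-to-day
within-person variation, realistic food co-occurrence structure, and the
real beverage share of intake mass (kept small so that consumption-derived
energy-density sextiles describe caloric foods).  Passing tests therefore
demonstrate the correctness and invariances of the machinery under
controlled conditions, not empirical claims about any real population.

## Problem sizes and numerical tolerances

The test suite runs the full pipeline at 250 and 5,000 synthetic
participants with a 400-food database; the 5,000-person run verifies the
calibration target within ±0.5 percentage points (the Monte-Carlo spread of
the weighted mean at that size), the exact Model 1 and Model 2 invariants
(tolerances 1e−6 kcal against floating-point accumulation), gram
preservation of the swaps (1e−9), and approximate iso-caloricity (within
5% of observed mean energy).  Oracle tests compare weighted quantiles,
profile composites, and survey means/SEs against independent brute-force
implementations on 100 random instances of size ≤ 50.

## Limitations

The models are accounting exercises, not behavioral predictions: nobody
claims that people who drop cheese would eat the stratum-average eligible
food.  Single-day recalls identify population means, not the distribution
of usual intake, so threshold shares (e.g., calcium ≥ 1,000 mg) describe
the modeled day, not prevalence of inadequacy.  Replacement profiles
substitute a composite, not named foods, and the 5%-cap boundary policy,
the consumption-weighting mass, and the sodium-adjustment switch are
documented conventions where the underlying methodology is ambiguous.
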