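# dairyswap

Food-level substitution modeling of dairy fat replacement in 24-hour
dietary-recall surveys.

## The problem

Nutrient-based dietary guidance ("replace 5% of energy from dairy fat with
unsaturated fat") is usually evaluated by swapping regression coefficients.
In real diets, dairy fat arrives inside foods — milk, cheese, butter, and a
long tail of mixed dishes that reach dairy ingredients through recipes — and
removing those foods removes everything else they carry: calcium, vitamins
A, D and B12, riboflavin, energy.  `dairyswap` implements the food-level
alternative for analysts of NHANES-style surveys: identify the dairy fat in
every consumed food by recipe expansion, remove the foods that carry it
(entirely, or up to a per-person cap of 5% of energy), optionally replace
them gram for gram with what comparable people actually eat in comparable
situations, and measure what happens to nutrient intakes and diet-quality
scores at the population level.

## The model

* **Dairy fat per 100 g** of food _f_ is the recursive recipe sum
  `D(f) = Σ_i (g_i / 100) · [ is_dairy(i) · fat_i + D(i) ]`
  over ingredients _i_ entering at `g_i` grams per 100 g of parent.
* **Replacement eligibility**: a food may replace dairy fat only if it
  contains no dairy fat and is not saturated-fat dominant
  (`SFA ≤ MUFA + PUFA`).
* **Strata**: consumption events are classified by age group (4–19, 20–39,
  40–64, 65+ y) × meal type (breakfast, lunch/dinner, snack, dessert) ×
  sextile of food energy density (kcal/100 g) × sextile of percent energy
  from fat — 4 × 4 × 6 × 6 = **576 patterns**.  Sextile cutpoints come from
  consumption-weighted quantiles of the survey itself (or can be fixed to
  published values).
* **Replacement profile** of a stratum: the composite per-gram nutrient
  vector of the eligible foods eaten there, weighted by survey weight ×
  grams consumed.  Because the replacement matches the removed food's
  energy-density stratum, the swap is approximately iso-caloric.
* **Model 1** removes every dairy-fat food; **Model 2** removes dairy-fat
  foods, visited in seeded random order, until exactly 5% of the person's
  observed energy has been removed as dairy-fat energy (the boundary item is
  partially removed).  Each model is run removal-only and as a
  gram-for-gram swap.
* **Scores**: NRF 9.3 = NR − LIM, where NR is the sum of nine percent-DV
  components truncated at 100 (0–900) and LIM is 100 × the sum of three
  proportional limiting components for added sugars (6–26 %E), saturated
  fat (8–16 %E) and sodium (1,100–2,000 mg) (0–300); and HEI-2015, thirteen
  density-standard components summing to 0–100.
* **Estimation**: survey-weighted means with Taylor-linearized SEs under a
  stratified design with ≥2 PSUs per stratum; dairy-fat consumers are
  analyzed as an estimation domain, not a filtered dataset; modeled-versus-
  observed differences are flagged only when the relative change exceeds
  10% *and* a Wald test against that margin rejects at α = 0.05.

A synthetic-data module generates a food database (with recipes and
food-pattern equivalents), a two-PSU-per-stratum survey population, and
24-h recalls calibrated so that dairy fat contributes a target share of
population energy (default 5.6 %E) — so every stage is testable without
restricted survey data.

## Worked example

```r
library(dairyswap)
study <- run_substitution_study(synthetic_config(n_participants = 2000, seed = 7))
print(study)
```

```
Dairy-fat substitution study
  participants: 2000 (dairy-fat consumers: 1698)
  foods: 400, intake items: 12887, strata with profiles: 562 of 576
  Model 2 cap: 5% of observed energy (scale boundary policy)

Survey-weighted means, total population:
                observed M1_remove M2_remove M1_swap M2_swap
energy_kcal      2063.66   1702.84   1833.55 2076.88 2070.34
dairy_fat_pct_e     5.53      0.00      2.56    0.00    2.12
sat_fat_pct_e      10.40      7.56      8.88    7.60    8.67
nrf93             386.35    358.46    371.19  379.36  383.10
hei_total          53.63     53.65     53.68   55.52   55.31
```

Reading the columns: the observed synthetic diet draws 5.53% of energy from
dairy fat.  Removing all dairy-fat foods (Model 1) drops ~360 kcal/day and
27 NRF points; the capped Model 2 removes less.  The gram-for-gram swaps
restore energy to within 1% of observed (approximately iso-caloric) and
recover part, but not all, of the nutrient-density loss, while HEI-2015
barely moves — the saturated-fat and fatty-acid components improve while
the dairy component collapses.  `summary(study)` returns the full
outcome × version tables with CIs and significance flags for the total
population and for dairy-fat consumers;
`study$calcium_share` reports the share of persons at or above 1,000 mg of
energy-adjusted calcium under each diet version.

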