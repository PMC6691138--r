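Package: dairyswap
Title: Food-Level Substitution Modeling of Dairy Fat Replacement in Diet Surveys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the population-level dietary consequences of removing food
    sources of dairy fat from 24-hour dietary recalls and replacing them,
    gram for gram, with consumption-weighted composites of foods rich in
    monounsaturated and polyunsaturated fat. Dairy fat is identified per
    100 g of food by recursive recipe expansion; replacement composites are
    built within 576 strata defined by age group, meal occasion, food energy
    density sextile and percent-energy-from-fat sextile; modified diets are
    scored with the NRF 9.3 nutrient density index and the Healthy Eating
    Index 2015; and population changes are estimated with survey-weighted
    means and Taylor-linearized variances under a stratified two-PSU design.
    Includes a synthetic dietary-survey generator so the full pipeline can be
    exercised and tested without access to restricted survey extracts.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite, knitr, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
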