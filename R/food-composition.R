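# Dairy fat identification by recipe expansion, food-level metrics, and the
# replacement-eligibility rule.

#' Dairy fat per 100 g of a food via recursive recipe expansion
#'
#' Walks the recipe graph of a food and sums the fat contributed by every
#' dairy-flagged ingredient that can be reached.  A recipe row states how many
#' grams of an ingredient enter 100 g of the parent food; nested recipes
#' (a dish containing a sauce containing cream) multiply through, so the
#' effective contribution of a dairy ingredient is the product of the
#' grams-per-100 g proportions along the path times the ingredient's fat
#' content per gram.
#'
#' @param food_code Food (parent) code to expand.
#' @param recipes Data frame with columns `parent_code`, `ingredient_code`,
#'   `grams_per_100g_parent`, `is_dairy`.
#' @param ingredient_fat Data frame with columns `ingredient_code` and `fat_g`
#'   (fat per 100 g of the ingredient).  Every dairy-flagged ingredient must
#'   have a row here.
#' @param max_depth Maximum recipe nesting depth before expansion aborts
#'   (recipes in dietary databases are shallow; the cap guards against
#'   malformed graphs).
#' @return Grams of dairy fat per 100 g of the food (0 for foods whose recipe
#'   reaches no dairy ingredient, including foods with no recipe at all).
#' @examples
#' recipes <- data.frame(parent_code = "F1", ingredient_code = "BUTTER",
#'                       grams_per_100g_parent = 10, is_dairy = TRUE)
#' fats <- data.frame(ingredient_code = "BUTTER", fat_g = 81)
#' compute_dairy_fat_per_100g("F1", recipes, fats)  # 10/100 * 81 = 8.1
#' @export
compute_dairy_fat_per_100g <- function(food_code, recipes, ingredient_fat,
                                       max_depth = 10) {
  stopifnot(is.data.frame(recipes), is.data.frame(ingredient_fat))
  fat_lookup <- stats::setNames(ingredient_fat$fat_g,
                                ingredient_fat$ingredient_code)
  expand <- function(code, depth, path) {
    if (code %in% path) {
      stopf("recipe cycle detected: %s", paste(c(path, code), collapse = " -> "))
    }
    if (depth > max_depth) {
      stopf("recipe expansion for '%s' exceeds maximum depth %d",
            food_code, max_depth)
    }
    rows <- recipes[recipes$parent_code == code, , drop = FALSE]
    if (nrow(rows) == 0) return(0)
    total <- 0
    for (k in seq_len(nrow(rows))) {
      ing  <- rows$ingredient_code[k]
      prop <- rows$grams_per_100g_parent[k] / 100
      if (isTRUE(rows$is_dairy[k])) {
        if (!ing %in% names(fat_lookup)) {
          stopf("dairy ingredient '%s' has no fat content record", ing)
        }
        total <- total + prop * fat_lookup[[ing]]
      } else if (ing %in% recipes$parent_code) {
        total <- total + prop * expand(ing, depth + 1, c(path, code))
      }
      # non-dairy leaf ingredients contribute no dairy fat
    }
    total
  }
  expand(food_code, 1L, character(0))
}

#' Dairy fat per 100 g for a vector of foods
#'
#' @inheritParams compute_dairy_fat_per_100g
#' @param food_codes Character vector of food codes.
#' @return Named numeric vector of dairy fat grams per 100 g.
#' @export
dairy_fat_table <- function(food_codes, recipes, ingredient_fat,
                            max_depth = 10) {
  vapply(food_codes, compute_dairy_fat_per_100g, numeric(1),
         recipes = recipes, ingredient_fat = ingredient_fat,
         max_depth = max_depth)
}

#' Attach recipe-derived dairy fat to a food composition table
#'
#' Recomputes `dairy_fat_g` for every food from the recipe and ingredient
#' tables and clamps the result to the food's total fat (a recipe can imply
#' slightly more dairy fat than the food's stated total fat when composition
#' data are rounded; the clamp is reported).
#'
#' @param foods Food composition table (one row per food, per-100 g columns).
#' @inheritParams compute_dairy_fat_per_100g
#' @return `foods` with a recomputed `dairy_fat_g` column.
#' @export
add_dairy_fat <- function(foods, recipes, ingredient_fat, max_depth = 10) {
  df <- dairy_fat_table(foods$food_code, recipes, ingredient_fat, max_depth)
  over <- df > foods$fat_g + 1e-9
  if (any(over)) {
    warning(sprintf(
      "dairy fat clamped to total fat for %d food(s): %s",
      sum(over), paste(utils::head(foods$food_code[over], 5), collapse = ", ")))
    df[over] <- foods$fat_g[over]
  }
  foods$dairy_fat_g <- unname(df)
  foods
}

#' Food-level metrics: energy density, percent energy from fat, eligibility
#'
#' Energy density is the stated kcal per 100 g.  Percent energy from fat uses
#' the Atwater factor of 9 kcal per gram of fat.  Foods with zero energy and
#' zero fat are assigned 0 %E from fat so they remain classifiable (water,
#' diet beverages); foods with zero energy but positive fat cannot be given a
#' percent and are flagged `fat_unclassifiable` (excluded from fat-sextile
#' assignment).
#'
#' @param foods Food composition table with at least `food_code`,
#'   `energy_kcal`, `fat_g`, `sfa_g`, `mufa_g`, `pufa_g`, `dairy_fat_g`.
#' @return Data frame with columns `food_code`, `energy_density`,
#'   `pct_energy_fat`, `fat_unclassifiable`, `replacement_eligible`.
#' @export
derive_food_metrics <- function(foods) {
  stopifnot(all(foods$energy_kcal >= 0))
  ed <- foods$energy_kcal
  pct <- ifelse(ed > 0, pmin(100, 100 * 9 * foods$fat_g / ed), 0)
  unclass_fat <- ed == 0 & foods$fat_g > 0
  pct[unclass_fat] <- NA_real_
  if (any(unclass_fat)) {
    message(sprintf("%d food(s) have fat but no energy; excluded from fat-sextile assignment",
                    sum(unclass_fat)))
  }
  data.frame(
    food_code = foods$food_code,
    energy_density = ed,
    pct_energy_fat = pct,
    fat_unclassifiable = unclass_fat,
    replacement_eligible = is_replacement_eligible(
      foods$dairy_fat_g, foods$sfa_g, foods$mufa_g, foods$pufa_g),
    stringsAsFactors = FALSE)
}

#' Replacement eligibility of a food
#'
#' A food may serve as a replacement only if it contains no dairy fat and does
#' not have more saturated fat than unsaturated fat (MUFA + PUFA).  A tie
#' (saturated equal to unsaturated) is eligible: the rule excludes only
#' strictly saturated-dominant foods.
#'
#' @param dairy_fat_g,sfa_g,mufa_g,pufa_g Per-100 g amounts (vectorized).
#' @return Logical vector.
#' @export
is_replacement_eligible <- function(dairy_fat_g, sfa_g, mufa_g, pufa_g) {
  dairy_fat_g == 0 & !(sfa_g > mufa_g + pufa_g)
}

#' Validate the internal consistency of a food composition table
#'
#' Checks the invariants every composition table must satisfy: non-negative
#' amounts, dairy fat no greater than total fat, fat subtypes summing to at
#' most total fat (with 5% rounding slack), and stated energy within 10% of
#' the Atwater energy of the macronutrients (4/4/9 kcal per g).
#'
#' @param foods Food composition table.
#' @return Invisibly `TRUE`; stops with an informative error otherwise.
#' @export
validate_food_db <- function(foods) {
  cols <- composition_columns()
  missing <- setdiff(cols, names(foods))
  if (length(missing)) stopf("food table lacks columns: %s",
                             paste(missing, collapse = ", "))
  m <- as.matrix(foods[cols])
  if (any(m < -1e-9)) stopf("negative nutrient amounts in food table")
  if (any(foods$dairy_fat_g > foods$fat_g + 1e-9))
    stopf("dairy fat exceeds total fat for: %s",
          paste(foods$food_code[foods$dairy_fat_g > foods$fat_g + 1e-9],
                collapse = ", "))
  if (any(foods$sfa_g + foods$mufa_g + foods$pufa_g > foods$fat_g * 1.05 + 1e-9))
    stopf("fat subtypes exceed total fat beyond rounding slack")
  atwater <- 4 * foods$protein_g + 4 * foods$carb_g + 9 * foods$fat_g
  pos <- foods$energy_kcal > 5  # tiny-energy foods are exempt from the ratio check
  bad <- pos & abs(foods$energy_kcal - atwater) > 0.10 * foods$energy_kcal
  if (any(bad)) stopf("stated energy departs >10%% from macronutrient energy for: %s",
                      paste(utils::head(foods$food_code[bad], 5), collapse = ", "))
  invisible(TRUE)
}
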