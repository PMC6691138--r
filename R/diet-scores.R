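# Daily nutrient totals, 2,000 kcal energy adjustment, NRF 9.3 (NR - LIM),
# and HEI-2015 total and component scores.

#' HEI-2015 component standards
#'
#' The thirteen components of the Healthy Eating Index 2015 with their maximum
#' points and scoring standards.  Adequacy components score proportionally
#' from 0 at zero intake to the maximum at or above `std_max` (densities per
#' 1,000 kcal: cup equivalents for fruit/vegetable/dairy groups, ounce
#' equivalents for grain/protein groups).  Moderation components score the
#' maximum at or below `std_min` and 0 at or above `std_max` (densities per
#' 1,000 kcal, %E for added sugars and saturated fat, grams for sodium).  The
#' fatty-acids component scores the (MUFA+PUFA)/SFA ratio: 0 at or below 1.2,
#' maximum at or above 2.5.
#'
#' @return Data frame with columns `component`, `max_points`, `type`,
#'   `std_min`, `std_max`.
#' @export
hei2015_standards <- function() {
  data.frame(
    component = c("total_fruits", "whole_fruits", "total_veg", "greens_beans",
                  "whole_grains", "dairy", "total_protein",
                  "seafood_plant_prot", "fatty_acids", "refined_grains",
                  "sodium", "added_sugars", "sat_fat"),
    max_points = c(5, 5, 5, 5, 10, 10, 5, 5, 10, 10, 10, 10, 10),
    type = c(rep("adequacy", 8), "ratio", rep("moderation", 4)),
    std_min = c(rep(0, 8), 1.2, 1.8, 1.1, 6.5, 8),
    std_max = c(0.8, 0.4, 1.1, 0.2, 1.5, 1.3, 2.5, 0.8, 2.5, 4.3, 2.0, 26, 16),
    stringsAsFactors = FALSE)
}

#' Diet-quality scoring configuration
#'
#' Bundles the reference values behind the NRF 9.3 and HEI-2015 scores: the
#' nine qualifying-nutrient daily values (DVs), the 2,000 kcal adjustment
#' basis, the minimum/maximum thresholds of the three limiting nutrients, and
#' the HEI-2015 component standards.
#'
#' @param dv Named numeric vector of daily values for the nine qualifying
#'   nutrients (names must be nutrient columns).
#' @param energy_basis Energy-adjustment basis in kcal.
#' @param lim_added_sugar,lim_sat_fat Two-element `c(min, max)` thresholds in
#'   %E for the limiting added-sugar and saturated-fat components.
#' @param lim_sodium Two-element `c(min, max)` thresholds in mg.
#' @param sodium_energy_adjusted Evaluate the sodium LIM threshold on the
#'   energy-adjusted (per `energy_basis`) amount (default) or on raw mg.
#' @param hei HEI-2015 standards table, see [hei2015_standards()].
#' @return An object of class `score_config`.
#' @export
score_config <- function(dv = c(protein_g = 50, fiber_g = 28, vit_a_mcg = 900,
                                vit_c_mg = 90, vit_d_mcg = 20,
                                calcium_mg = 1300, iron_mg = 18,
                                potassium_mg = 4700, magnesium_mg = 420),
                         energy_basis = 2000,
                         lim_added_sugar = c(6, 26),
                         lim_sat_fat = c(8, 16),
                         lim_sodium = c(1100, 2000),
                         sodium_energy_adjusted = TRUE,
                         hei = hei2015_standards()) {
  stopifnot(all(dv > 0), energy_basis > 0,
            lim_added_sugar[1] < lim_added_sugar[2],
            lim_sat_fat[1] < lim_sat_fat[2],
            lim_sodium[1] < lim_sodium[2],
            sum(hei$max_points) == 100)
  structure(list(dv = dv, energy_basis = energy_basis,
                 lim_added_sugar = lim_added_sugar, lim_sat_fat = lim_sat_fat,
                 lim_sodium = lim_sodium,
                 sodium_energy_adjusted = sodium_energy_adjusted, hei = hei),
            class = "score_config")
}

#' Daily nutrient totals for one participant-day
#'
#' Sums grams times per-gram nutrients over every consumed item, plus any
#' replacement contributions from a swap model (replacement rows carry their
#' composite per-gram nutrient vectors directly).
#'
#' @param day Data frame of items with `food_code` and `grams`.
#' @param foods Food composition table (per 100 g).
#' @param replacements Optional data frame of replacement contributions with
#'   `grams` and per-gram columns named as [composition_columns()].
#' @return Named numeric vector over [composition_columns()].
#' @export
daily_totals <- function(day, foods, replacements = NULL) {
  cols <- composition_columns()
  tot <- stats::setNames(numeric(length(cols)), cols)
  if (nrow(day)) {
    idx <- match(day$food_code, foods$food_code)
    if (anyNA(idx)) stopf("unresolvable food code(s): %s",
                          paste(unique(day$food_code[is.na(idx)]), collapse = ", "))
    tot <- colSums(as.matrix(foods[idx, cols]) / 100 * day$grams)
  }
  if (!is.null(replacements) && nrow(replacements)) {
    tot <- tot + colSums(as.matrix(replacements[cols]) * replacements$grams)
  }
  tot
}

#' Daily nutrient totals for a whole population
#'
#' Vectorized version of [daily_totals()]: one row per participant (including
#' participants with no items that day, whose totals are zero).
#'
#' @param intakes Intake table with `participant_id`, `food_code`, `grams`.
#' @param foods Food composition table.
#' @param participant_ids Participants to report (row order of the result).
#' @param replacements Optional replacement table with `participant_id`,
#'   `grams` and per-gram nutrient columns.
#' @return Numeric matrix, participants x [composition_columns()].
#' @export
population_totals <- function(intakes, foods, participant_ids,
                              replacements = NULL) {
  cols <- composition_columns()
  out <- matrix(0, length(participant_ids), length(cols),
                dimnames = list(as.character(participant_ids), cols))
  if (nrow(intakes)) {
    idx <- match(intakes$food_code, foods$food_code)
    if (anyNA(idx)) stopf("unresolvable food code(s) in intake table")
    contrib <- as.matrix(foods[idx, cols]) / 100 * intakes$grams
    agg <- rowsum(contrib, intakes$participant_id)
    out[rownames(agg), ] <- out[rownames(agg), , drop = FALSE] + agg
  }
  if (!is.null(replacements) && nrow(replacements)) {
    contrib <- as.matrix(replacements[cols]) * replacements$grams
    agg <- rowsum(contrib, replacements$participant_id)
    out[rownames(agg), ] <- out[rownames(agg), , drop = FALSE] + agg
  }
  out
}

#' Energy-adjust nutrient totals to a common kcal basis
#'
#' Scales every nutrient by `basis / energy`, expressing intake per
#' `basis` kcal (2,000 by default).  Zero-energy days cannot be adjusted and
#' come back as `NA` rows; downstream scoring excludes them.
#'
#' @param totals Named vector or matrix of daily totals (rows = persons).
#' @param basis Energy basis in kcal.
#' @return Adjusted totals of the same shape.
#' @export
energy_adjust <- function(totals, basis = 2000) {
  if (is.matrix(totals)) {
    e <- totals[, "energy_kcal"]
    f <- ifelse(e > 0, basis / e, NA_real_)
    if (anyNA(f)) message(sprintf("%d zero-energy day(s) excluded from energy adjustment",
                                  sum(is.na(f))))
    totals * f
  } else {
    if (totals[["energy_kcal"]] <= 0) {
      message("zero-energy day excluded from energy adjustment")
      return(totals * NA_real_)
    }
    totals * (basis / totals[["energy_kcal"]])
  }
}

# %E helpers: Atwater 4/4/9 kcal per gram
pct_energy <- function(grams, kcal_per_g, energy) {
  ifelse(energy > 0, 100 * grams * kcal_per_g / energy, NA_real_)
}

#' NR score: sum of nine truncated percent-DV components
#'
#' Each qualifying nutrient contributes `min(100, 100 * adjusted intake / DV)`
#' points, so an excess of one nutrient cannot compensate for inadequacy of
#' another; the total lies in \[0, 900\].
#'
#' @param adjusted Energy-adjusted totals: named vector or matrix.
#' @param config A [score_config()].
#' @return Numeric vector of NR points with a `"components"` attribute
#'   (matrix of per-nutrient points).
#' @export
nr_score <- function(adjusted, config = score_config()) {
  if (!is.matrix(adjusted)) adjusted <- t(as.matrix(adjusted))
  dv <- config$dv
  comp <- sweep(adjusted[, names(dv), drop = FALSE], 2, dv, "/") * 100
  comp <- pmin(comp, 100)
  out <- rowSums(comp)
  attr(out, "components") <- comp
  out
}

#' Proportional limiting-nutrient component
#'
#' 0 at or below the minimum threshold, 1 at or above the maximum, linear in
#' between: an intake halfway between the thresholds earns 0.5 limiting
#' points.
#'
#' @param value Intake (vectorized): %E for added sugars and saturated fat,
#'   mg for sodium.
#' @param min_t,max_t Thresholds, `min_t < max_t`.
#' @return Fraction in \[0, 1\].
#' @export
lim_component <- function(value, min_t, max_t) {
  stopifnot(min_t < max_t)
  pmin(1, pmax(0, (value - min_t) / (max_t - min_t)))
}

#' LIM score over added sugars, saturated fat and sodium
#'
#' Each limiting nutrient contributes 100 times its proportional component,
#' so the total lies in \[0, 300\] (0 optimal, 300 sub-optimal).
#'
#' @param added_sugar_pct_e,sat_fat_pct_e %E from added sugars / saturated
#'   fat (vectorized).
#' @param sodium_mg Sodium in mg (energy-adjusted or raw, per the
#'   configuration used upstream).
#' @param config A [score_config()].
#' @return Numeric vector of LIM points with a `"components"` attribute.
#' @export
lim_score <- function(added_sugar_pct_e, sat_fat_pct_e, sodium_mg,
                      config = score_config()) {
  comp <- cbind(
    added_sugars = lim_component(added_sugar_pct_e, config$lim_added_sugar[1],
                                 config$lim_added_sugar[2]),
    sat_fat = lim_component(sat_fat_pct_e, config$lim_sat_fat[1],
                            config$lim_sat_fat[2]),
    sodium = lim_component(sodium_mg, config$lim_sodium[1],
                           config$lim_sodium[2]))
  out <- 100 * rowSums(comp)
  attr(out, "components") <- comp
  out
}

#' NRF 9.3 = NR - LIM
#'
#' @param nr,lim NR and LIM points.
#' @return NRF 9.3 points in \[-300, 900\].
#' @export
nrf93 <- function(nr, lim) as.numeric(nr) - as.numeric(lim)

#' HEI-2015 total and component scores
#'
#' Scores a day's totals against the thirteen HEI-2015 standards (see
#' [hei2015_standards()]).  Adequacy components use food-group densities per
#' 1,000 kcal; moderation components score inversely between their
#' best/worst standards; the fatty-acids component scores the
#' (MUFA+PUFA)/SFA ratio, with zero saturated fat earning the defined
#' maximum.  The total is the sum of the components, in \[0, 100\].
#'
#' @param totals Daily totals: named vector or matrix (raw, not
#'   energy-adjusted -- all components are densities or %E, hence scale-free).
#' @param config A [score_config()].
#' @return Data frame with one column per component plus `hei_total`.
#' @export
hei2015_score <- function(totals, config = score_config()) {
  if (!is.matrix(totals)) totals <- t(as.matrix(totals))
  e <- totals[, "energy_kcal"]
  if (any(e <= 0, na.rm = TRUE))
    message(sprintf("%d zero-energy day(s): HEI-2015 undefined (NA)", sum(e <= 0)))
  dens <- function(col, per = 1000) ifelse(e > 0, totals[, col] / e * per, NA_real_)
  std <- config$hei
  g <- function(comp) std[std$component == comp, ]

  adequacy <- function(comp, col) {
    s <- g(comp)
    s$max_points * pmin(1, dens(col) / s$std_max)
  }
  moderation <- function(comp, value) {
    s <- g(comp)
    s$max_points * pmin(1, pmax(0, (s$std_max - value) / (s$std_max - s$std_min)))
  }

  sfa <- totals[, "sfa_g"]
  unsat <- totals[, "mufa_g"] + totals[, "pufa_g"]
  ratio <- ifelse(sfa > 0, unsat / sfa, Inf)
  if (any(sfa == 0 & e > 0, na.rm = TRUE))
    message(sprintf("%d day(s) with zero saturated fat: fatty-acid ratio set to its maximum",
                    sum(sfa == 0 & e > 0, na.rm = TRUE)))
  s_fa <- g("fatty_acids")
  fa_pts <- s_fa$max_points *
    pmin(1, pmax(0, (ratio - s_fa$std_min) / (s_fa$std_max - s_fa$std_min)))
  fa_pts[is.infinite(ratio)] <- s_fa$max_points
  fa_pts[e <= 0] <- NA_real_

  out <- data.frame(
    total_fruits = adequacy("total_fruits", "fped_total_fruit"),
    whole_fruits = adequacy("whole_fruits", "fped_whole_fruit"),
    total_veg = adequacy("total_veg", "fped_total_veg"),
    greens_beans = adequacy("greens_beans", "fped_greens_beans"),
    whole_grains = adequacy("whole_grains", "fped_whole_grains"),
    dairy = adequacy("dairy", "fped_dairy"),
    total_protein = adequacy("total_protein", "fped_protein"),
    seafood_plant_prot = adequacy("seafood_plant_prot", "fped_seafood_plant_prot"),
    fatty_acids = fa_pts,
    refined_grains = moderation("refined_grains", dens("fped_refined_grains")),
    sodium = moderation("sodium", dens("sodium_mg") / 1000),  # g per 1,000 kcal
    added_sugars = moderation("added_sugars",
                              pct_energy(totals[, "added_sugar_g"], 4, e)),
    sat_fat = moderation("sat_fat", pct_energy(sfa, 9, e)))
  out$hei_total <- rowSums(out)
  rownames(out) <- rownames(totals)
  out
}

#' Score a population of daily totals with NRF 9.3 and HEI-2015
#'
#' Convenience wrapper used by the pipeline: computes %E macronutrients,
#' 2,000 kcal energy-adjusted amounts, NR, LIM, NRF 9.3 and the HEI-2015
#' components for every person-day.  Zero-energy days are flagged
#' (`scored = FALSE`) and carry `NA` scores.
#'
#' @param totals Matrix from [population_totals()].
#' @param config A [score_config()].
#' @return Data frame, one row per person.
#' @export
score_diet_days <- function(totals, config = score_config()) {
  e <- totals[, "energy_kcal"]
  adj <- energy_adjust(totals, config$energy_basis)
  nr <- nr_score(adj, config)
  sugar_pe <- pct_energy(totals[, "added_sugar_g"], 4, e)
  sfa_pe <- pct_energy(totals[, "sfa_g"], 9, e)
  sodium_for_lim <- if (config$sodium_energy_adjusted)
    adj[, "sodium_mg"] else totals[, "sodium_mg"]
  lim <- lim_score(sugar_pe, sfa_pe, sodium_for_lim, config)
  hei <- hei2015_score(totals, config)
  data.frame(
    participant_id = rownames(totals),
    energy_kcal = e,
    scored = e > 0,
    nr = as.numeric(nr), lim = as.numeric(lim),
    nrf93 = nrf93(nr, lim),
    hei, stringsAsFactors = FALSE, row.names = NULL)
}
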