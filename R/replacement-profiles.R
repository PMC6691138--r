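# Stratum assignment (age x meal x energy-density sextile x %fat sextile) and
# consumption-weighted composite replacement profiles.

#' Energy-density sextile cutpoints estimated from NHANES 2013-2016
#'
#' Published consumption-weighted cutpoints (kcal/100 g) splitting food energy
#' density at the 10th, 25th, 50th, 75th and 90th percentiles.  Usable as
#' fixed cutpoints in [stratification_config()] to bypass recomputation.
#' @return Numeric vector of five increasing cutpoints.
#' @export
nhanes_ed_cutpoints <- function() c(49.8, 70.7, 151.5, 235.6, 308.8)

#' Percent-energy-from-fat sextile cutpoints estimated from NHANES 2013-2016
#' @return Numeric vector of five increasing cutpoints (%E).
#' @rdname nhanes_ed_cutpoints
#' @export
nhanes_fat_cutpoints <- function() c(16.4, 24.9, 38.4, 48.3, 63.5)

#' Default mapping from eating-occasion labels to the four meal types
#'
#' Meal types are indexed 1 = breakfast, 2 = lunch/dinner, 3 = snack
#' (including beverage-only occasions), 4 = dessert.
#' @return Named integer vector mapping occasion labels to meal-type index.
#' @export
default_meal_map <- function() {
  c(breakfast = 1L, lunch = 2L, dinner = 2L, lunch_dinner = 2L,
    snack = 3L, beverage = 3L, dessert = 4L)
}

#' Configuration of the substitution strata
#'
#' Defines the four stratification axes: age group (default 4-19, 20-39,
#' 40-64, 65+ years), meal type (via `meal_map`), and sextiles of food energy
#' density and percent energy from fat.  Sextile cutpoints may be fixed (for
#' example the published survey values from [nhanes_ed_cutpoints()]) or left
#' `NULL` to be recomputed from weighted consumption at `quantile_probs`.
#'
#' @param age_breaks Lower bounds of the age groups in years.
#' @param meal_map Named integer vector mapping occasion labels to meal types
#'   1-4; see [default_meal_map()].
#' @param quantile_probs Probabilities defining the sextiles when cutpoints
#'   are recomputed.
#' @param ed_cutpoints,fat_cutpoints Optional fixed cutpoints (five strictly
#'   increasing values each).
#' @param consumption_weighting How consumption events are weighted when
#'   computing cutpoints and composite profiles: survey weight times grams
#'   (`"grams"`, default), times food energy (`"kcal"`), or survey weight
#'   alone (`"events"`).
#' @return An object of class `stratification_config`.
#' @export
stratification_config <- function(age_breaks = c(4, 20, 40, 65),
                                  meal_map = default_meal_map(),
                                  quantile_probs = c(0.10, 0.25, 0.50, 0.75, 0.90),
                                  ed_cutpoints = NULL,
                                  fat_cutpoints = NULL,
                                  consumption_weighting = c("grams", "kcal", "events")) {
  consumption_weighting <- match.arg(consumption_weighting)
  check_cuts <- function(x, what) {
    if (!is.null(x)) {
      if (length(x) != 5 || any(diff(x) <= 0))
        stopf("%s must be 5 strictly increasing cutpoints", what)
    }
  }
  check_cuts(ed_cutpoints, "ed_cutpoints")
  check_cuts(fat_cutpoints, "fat_cutpoints")
  stopifnot(length(age_breaks) == 4, !is.unsorted(age_breaks),
            all(meal_map %in% 1:4),
            length(quantile_probs) == 5, all(diff(quantile_probs) > 0),
            all(quantile_probs > 0 & quantile_probs < 1))
  structure(list(age_breaks = age_breaks, meal_map = meal_map,
                 quantile_probs = quantile_probs,
                 ed_cutpoints = ed_cutpoints, fat_cutpoints = fat_cutpoints,
                 consumption_weighting = consumption_weighting),
            class = "stratification_config")
}

#' Weighted quantile cutpoints (left-continuous inverse CDF)
#'
#' For each probability p, returns the smallest observed value whose
#' cumulative normalized weight reaches p.  This exact definition (no
#' interpolation) is easy to verify against a brute-force cumulative sum and
#' differs negligibly from interpolating definitions at survey scale.
#'
#' @param values Numeric measurements.
#' @param weights Non-negative weights, same length.
#' @param probs Strictly increasing probabilities in (0, 1).
#' @return Numeric vector of cutpoints, one per probability (nondecreasing).
#' @export
weighted_quantile_cutpoints <- function(values, weights,
                                        probs = c(0.10, 0.25, 0.50, 0.75, 0.90)) {
  keep <- !is.na(values) & !is.na(weights)
  values <- values[keep]; weights <- weights[keep]
  if (length(values) == 0 || sum(weights) <= 0)
    stopf("weighted_quantile_cutpoints: no data with positive weight")
  stopifnot(all(weights >= 0), all(diff(probs) > 0),
            all(probs > 0 & probs < 1))
  o <- order(values)
  v <- values[o]
  cw <- cumsum(weights[o]) / sum(weights)
  vapply(probs, function(p) v[which(cw >= p - 1e-12)[1]], numeric(1))
}

#' Assign consumption events to substitution strata
#'
#' Deterministically maps (consumer age, eating occasion, food energy
#' density, food %energy from fat) to the four stratum indices.  Cutpoints
#' are lower bounds of categories 2-6, so a value exactly on a cutpoint falls
#' in the upper category.
#'
#' @param age Consumer age in years (vectorized).
#' @param occasion Eating-occasion label (must appear in `config$meal_map`).
#' @param energy_density Food energy density, kcal/100 g.
#' @param pct_energy_fat Food percent energy from fat (`NA` not allowed here;
#'   unclassifiable foods must be excluded upstream).
#' @param config A [stratification_config()].  Its `ed_cutpoints` and
#'   `fat_cutpoints` must be set (fixed or precomputed).
#' @return Data frame with integer columns `age_group`, `meal_type`,
#'   `ed_category`, `fat_category`.
#' @export
assign_stratum <- function(age, occasion, energy_density, pct_energy_fat,
                           config) {
  stopifnot(inherits(config, "stratification_config"))
  if (is.null(config$ed_cutpoints) || is.null(config$fat_cutpoints))
    stopf("assign_stratum requires cutpoints; set them or compute them first")
  if (any(age < config$age_breaks[1]))
    stopf("age below the first age group (%g y)", config$age_breaks[1])
  unknown <- setdiff(unique(occasion), names(config$meal_map))
  if (length(unknown))
    stopf("occasion label(s) not in meal_map: %s", paste(unknown, collapse = ", "))
  if (anyNA(pct_energy_fat))
    stopf("pct_energy_fat contains NA; exclude fat-unclassifiable foods first")
  categ <- function(x, cuts) 1L + rowSums(outer(x, cuts, `>=`))
  data.frame(
    age_group = findInterval(age, config$age_breaks),
    meal_type = unname(config$meal_map[occasion]),
    ed_category = categ(energy_density, config$ed_cutpoints),
    fat_category = categ(pct_energy_fat, config$fat_cutpoints))
}

#' Full stratum key space
#'
#' All combinations of the four stratum axes under a configuration; with the
#' defaults this is 4 x 4 x 6 x 6 = 576 keys.
#' @param config A [stratification_config()].
#' @return Data frame of all stratum keys.
#' @export
stratum_key_space <- function(config = stratification_config()) {
  expand.grid(age_group = seq_along(config$age_breaks),
              meal_type = sort(unique(unname(config$meal_map))),
              ed_category = 1:6, fat_category = 1:6)
}

# Event weight under the configured consumption weighting
event_weight <- function(weighting, survey_weight, grams, energy_density) {
  switch(weighting,
         grams  = survey_weight * grams,
         kcal   = survey_weight * grams * energy_density / 100,
         events = survey_weight)
}

#' Build consumption-weighted replacement profiles per stratum
#'
#' For every stratum with at least one eligible consumption event, computes
#' the composite per-gram nutrient vector of the replacement-eligible foods
#' eaten there: the average of the foods' per-gram nutrient vectors weighted
#' by survey weight times frequency of consumption (grams eaten, by default).
#' Only foods that carry no dairy fat and are not saturated-fat dominant
#' contribute; strata in which no eligible food was eaten are simply absent
#' (see [resolve_profile()] for the fallback).
#'
#' If the configuration does not fix the sextile cutpoints they are computed
#' here from the weighted consumption distribution of all classifiable
#' consumed foods, and the cutpoints used are stored in the result's
#' `"cutpoints"` attribute (also mirrored in `"config"`).
#'
#' @param intakes Intake table: `participant_id`, `food_code`, `grams`,
#'   `occasion`.
#' @param participants Participant table: `participant_id`, `age`, `weight`.
#' @param foods Food composition table (per 100 g) including `dairy_fat_g`.
#' @param config A [stratification_config()].
#' @param metrics Optional precomputed [derive_food_metrics()] table.
#' @return Data frame keyed by the four stratum indices with `total_weight`,
#'   `n_foods`, and one per-gram column for every [composition_columns()]
#'   entry; attributes `cutpoints` and `config`.
#' @export
build_replacement_profiles <- function(intakes, participants, foods,
                                       config = stratification_config(),
                                       metrics = NULL) {
  if (is.null(metrics)) metrics <- derive_food_metrics(foods)
  pidx <- match(intakes$participant_id, participants$participant_id)
  fidx <- match(intakes$food_code, foods$food_code)
  if (anyNA(fidx)) stopf("intake references unknown food code(s)")
  if (anyNA(pidx)) stopf("intake references unknown participant(s)")
  mrow <- metrics[match(intakes$food_code, metrics$food_code), ]

  # cutpoints from weighted consumption unless fixed in the config
  w_all <- event_weight(config$consumption_weighting,
                        participants$weight[pidx], intakes$grams,
                        mrow$energy_density)
  if (is.null(config$ed_cutpoints))
    config$ed_cutpoints <- weighted_quantile_cutpoints(
      mrow$energy_density, w_all, config$quantile_probs)
  if (is.null(config$fat_cutpoints))
    config$fat_cutpoints <- weighted_quantile_cutpoints(
      mrow$pct_energy_fat[!mrow$fat_unclassifiable],
      w_all[!mrow$fat_unclassifiable], config$quantile_probs)

  keep <- mrow$replacement_eligible & !mrow$fat_unclassifiable
  if (!any(keep)) stopf("no replacement-eligible consumption events")
  ev <- intakes[keep, , drop = FALSE]
  evm <- mrow[keep, , drop = FALSE]
  w <- w_all[keep]
  key <- assign_stratum(participants$age[pidx][keep], ev$occasion,
                        evm$energy_density, evm$pct_energy_fat, config)
  kid <- interaction(key$age_group, key$meal_type, key$ed_category,
                     key$fat_category, drop = TRUE)

  per_gram <- as.matrix(foods[match(ev$food_code, foods$food_code),
                              composition_columns()]) / 100
  num <- rowsum(per_gram * w, kid)
  den <- rowsum(w, kid)
  prof <- sweep(num, 1, den[, 1], "/")
  first <- !duplicated(kid)
  keys <- key[first, ][order(kid[first]), ]
  nf <- vapply(split(ev$food_code, kid), function(x) length(unique(x)),
               integer(1))
  out <- cbind(keys,
               data.frame(total_weight = den[, 1], n_foods = unname(nf)),
               as.data.frame(prof))
  rownames(out) <- NULL
  stopifnot(all(out$dairy_fat_g == 0))  # no dairy leakage by construction
  attr(out, "cutpoints") <- list(ed = config$ed_cutpoints,
                                 fat = config$fat_cutpoints)
  attr(out, "config") <- config
  out
}

#' Resolve a replacement profile, falling back over empty strata
#'
#' Returns the profile of the exact stratum if one exists.  Otherwise the
#' stratum axes are marginalized in fixed order -- fat sextile first, then
#' energy-density sextile, then meal type, then age group, ending at the
#' global pool -- and at each level the weighted composite over all matching
#' profiles is recomputed (weights are the profiles' consumption mass).
#'
#' @param key One-row data frame or list with `age_group`, `meal_type`,
#'   `ed_category`, `fat_category`.
#' @param profiles Result of [build_replacement_profiles()].
#' @return List with `per_gram` (named numeric vector over
#'   [composition_columns()]), `total_weight`, and `fallback_level`
#'   (0 = exact stratum, 4 = global pool).
#' @export
resolve_profile <- function(key, profiles) {
  if (is.null(profiles) || nrow(profiles) == 0)
    stopf("profiles map is empty: no eligible foods anywhere")
  dims <- c("age_group", "meal_type", "ed_category", "fat_category")
  drop_order <- c("fat_category", "ed_category", "meal_type", "age_group")
  cols <- composition_columns()
  for (level in 0:4) {
    use_dims <- if (level == 0) dims else setdiff(dims, drop_order[seq_len(level)])
    sel <- rep(TRUE, nrow(profiles))
    for (d in use_dims) sel <- sel & profiles[[d]] == key[[d]]
    if (any(sel)) {
      sub <- profiles[sel, , drop = FALSE]
      w <- sub$total_weight
      pg <- colSums(as.matrix(sub[cols]) * w) / sum(w)
      return(list(per_gram = pg, total_weight = sum(w),
                  fallback_level = level))
    }
  }
  stopf("unreachable: global pool empty")  # guarded by the nrow check above
}
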