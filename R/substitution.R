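# The four modeled diets: full removal (Model 1) and 5%-of-energy-capped
# removal (Model 2) of dairy-fat foods, each with an optional gram-for-gram
# swap against stratum replacement profiles.

# internal: per-item dairy-fat kcal and food energy for a set of items
item_energetics <- function(items, foods) {
  idx <- match(items$food_code, foods$food_code)
  if (anyNA(idx)) stopf("unknown food code(s) in intake items")
  list(energy_kcal = items$grams * foods$energy_kcal[idx] / 100,
       dairy_kcal = items$grams * 9 * foods$dairy_fat_g[idx] / 100)
}

new_substitution_result <- function(day, removed, model_id, seed = NA) {
  structure(list(day = day, removed = removed,
                 dairy_fat_energy_removed = sum(removed$dairy_fat_kcal_removed),
                 replacement_grams = sum(removed$grams_removed),
                 model_id = model_id, seed = seed),
            class = "substitution_result")
}

#' Model 1: remove every food containing dairy fat
#'
#' Whole items are removed -- a cheese sandwich goes, not just its cheese --
#' because the substitution operates at the level of consumed foods.  The
#' modified day has exactly zero dairy-fat energy; items without dairy fat
#' are untouched.
#'
#' @param day One participant-day of items: `food_code`, `grams`, `occasion`.
#' @param foods Food composition table including `dairy_fat_g`.
#' @return A `substitution_result`: the modified `day`, a `removed` audit
#'   table (`food_code`, `occasion`, `grams_removed`,
#'   `dairy_fat_kcal_removed`), and the model id `"M1_remove"`.
#' @export
remove_all_dairy <- function(day, foods) {
  en <- item_energetics(day, foods)
  is_dairy <- en$dairy_kcal > 0
  removed <- data.frame(food_code = day$food_code[is_dairy],
                        occasion = day$occasion[is_dairy],
                        grams_removed = day$grams[is_dairy],
                        dairy_fat_kcal_removed = en$dairy_kcal[is_dairy],
                        stringsAsFactors = FALSE)
  new_substitution_result(day[!is_dairy, , drop = FALSE], removed, "M1_remove")
}

#' Model 2: remove dairy-fat foods up to a cap on energy
#'
#' Removes dairy-containing items, visited in a seeded uniformly random
#' order, while the cumulative removed dairy-fat energy stays within
#' `cap` (a fraction of the day's observed total energy, 5% by default).
#' With `partial = "scale"` (default) the first item that would exceed the
#' cap is partially removed -- its grams scaled so the cumulative removed
#' dairy-fat energy hits the cap exactly -- and later dairy items are kept.
#' With `partial = "skip"` the boundary item is kept whole and later items
#' that still fit are removed, leaving the removal strictly below the cap.
#' Persons whose total dairy-fat energy is within the cap lose all dairy
#' items (equivalent to Model 1).  The random order prevents any meal from
#' being systematically the one removed.
#'
#' @inheritParams remove_all_dairy
#' @param cap Cap as a fraction of observed total energy, in (0, 1].
#' @param seed Integer seed for the item order (required for
#'   reproducibility).
#' @param partial Boundary-item policy, `"scale"` or `"skip"`.
#' @return A `substitution_result` with model id `"M2_remove"`.
#' @export
remove_capped_dairy <- function(day, foods, cap = 0.05, seed,
                                partial = c("scale", "skip")) {
  partial <- match.arg(partial)
  stopifnot(cap > 0, cap <= 1)
  en <- item_energetics(day, foods)
  budget <- cap * sum(en$energy_kcal)
  dairy_idx <- which(en$dairy_kcal > 0)
  # canonical order first, so the seeded permutation does not depend on the
  # incidental row order of the intake table
  dairy_idx <- dairy_idx[order(day$food_code[dairy_idx],
                               day$grams[dairy_idx])]
  ord <- with_seed(seed, sample(length(dairy_idx)))
  frac <- numeric(nrow(day))  # fraction of each item's grams removed
  for (i in dairy_idx[ord]) {
    if (budget <= 1e-12) break
    if (en$dairy_kcal[i] <= budget + 1e-12) {
      frac[i] <- 1
      budget <- budget - en$dairy_kcal[i]
    } else if (partial == "scale") {
      frac[i] <- budget / en$dairy_kcal[i]
      budget <- 0
    }  # "skip": keep the boundary item, try later items
  }
  hit <- frac > 0
  removed <- data.frame(food_code = day$food_code[hit],
                        occasion = day$occasion[hit],
                        grams_removed = day$grams[hit] * frac[hit],
                        dairy_fat_kcal_removed = en$dairy_kcal[hit] * frac[hit],
                        stringsAsFactors = FALSE)
  out_day <- day
  out_day$grams <- day$grams * (1 - frac)
  out_day <- out_day[out_day$grams > 0, , drop = FALSE]
  new_substitution_result(out_day, removed, "M2_remove", seed)
}

#' Apply a removal model to a whole intake table
#'
#' Runs [remove_all_dairy()] or [remove_capped_dairy()] for every
#' participant.  For Model 2 each participant-day gets its own random stream
#' keyed by (global seed, participant id), so results do not depend on the
#' order of participants and single days can be re-run in isolation.
#'
#' @param intakes Intake table: `participant_id`, `food_code`, `grams`,
#'   `occasion`.
#' @param foods Food composition table including `dairy_fat_g`.
#' @param model `"M1"` (remove all) or `"M2"` (capped).
#' @param cap,partial Passed to [remove_capped_dairy()] for Model 2.
#' @param seed Global seed (Model 2).
#' @return List: `intakes` (modified table), `removed` (audit table with
#'   `participant_id`), `model`.
#' @export
apply_removal <- function(intakes, foods, model = c("M1", "M2"), cap = 0.05,
                          seed = 1, partial = c("scale", "skip")) {
  model <- match.arg(model)
  partial <- match.arg(partial)
  en <- item_energetics(intakes, foods)
  if (model == "M1") {
    is_dairy <- en$dairy_kcal > 0
    removed <- data.frame(participant_id = intakes$participant_id[is_dairy],
                          food_code = intakes$food_code[is_dairy],
                          occasion = intakes$occasion[is_dairy],
                          grams_removed = intakes$grams[is_dairy],
                          dairy_fat_kcal_removed = en$dairy_kcal[is_dairy],
                          stringsAsFactors = FALSE)
    return(list(intakes = intakes[!is_dairy, , drop = FALSE],
                removed = removed, model = "M1_remove"))
  }
  # Model 2: per-participant capped removal
  groups <- split(seq_len(nrow(intakes)), intakes$participant_id)
  frac <- numeric(nrow(intakes))
  for (pid in names(groups)) {
    rows <- groups[[pid]]
    dairy_rows <- rows[en$dairy_kcal[rows] > 0]
    if (!length(dairy_rows)) next
    budget <- cap * sum(en$energy_kcal[rows])
    dairy_rows <- dairy_rows[order(intakes$food_code[dairy_rows],
                                   intakes$grams[dairy_rows])]
    ord <- with_seed(substream_seed(seed, as.numeric(pid)),
                     sample(length(dairy_rows)))
    for (i in dairy_rows[ord]) {
      if (budget <= 1e-12) break
      if (en$dairy_kcal[i] <= budget + 1e-12) {
        frac[i] <- 1
        budget <- budget - en$dairy_kcal[i]
      } else if (partial == "scale") {
        frac[i] <- budget / en$dairy_kcal[i]
        budget <- 0
      }
    }
  }
  hit <- frac > 0
  removed <- data.frame(participant_id = intakes$participant_id[hit],
                        food_code = intakes$food_code[hit],
                        occasion = intakes$occasion[hit],
                        grams_removed = intakes$grams[hit] * frac[hit],
                        dairy_fat_kcal_removed = en$dairy_kcal[hit] * frac[hit],
                        stringsAsFactors = FALSE)
  out <- intakes
  out$grams <- intakes$grams * (1 - frac)
  out <- out[out$grams > 0, , drop = FALSE]
  list(intakes = out, removed = removed, model = "M2_remove")
}

#' Gram-for-gram swap of removed dairy-fat foods
#'
#' For every removed item (or partial grams), adds a replacement of equal
#' grams whose nutrients are the composite per-gram vector of the profile
#' resolved for the consumer's age group, the occasion at which the item was
#' eaten, and the removed food's energy-density and fat sextiles.  Because
#' the replacement matches the removed food's energy-density stratum, the
#' swap is approximately iso-caloric; it contributes no dairy fat by
#' construction.
#'
#' @param removal Result of [apply_removal()] (or a single-day
#'   `substitution_result` plus `participant_id` column in `removed`).
#' @param profiles Result of [build_replacement_profiles()] (its
#'   `"cutpoints"`/`"config"` attributes supply the stratum definitions).
#' @param participants Participant table (`participant_id`, `age`).
#' @param foods Food composition table.
#' @param metrics Optional [derive_food_metrics()] table.
#' @return Data frame of replacement contributions: `participant_id`,
#'   `occasion`, `grams`, `fallback_level`, and per-gram nutrient columns
#'   over [composition_columns()].
#' @export
apply_swap <- function(removal, profiles, participants, foods,
                       metrics = NULL) {
  removed <- removal$removed
  cols <- composition_columns()
  if (is.null(removed) || nrow(removed) == 0) {
    return(cbind(
      data.frame(participant_id = character(0), occasion = character(0),
                 grams = numeric(0), fallback_level = integer(0)),
      as.data.frame(matrix(numeric(0), 0, length(cols),
                           dimnames = list(NULL, cols)))))
  }
  if (is.null(metrics)) metrics <- derive_food_metrics(foods)
  config <- attr(profiles, "config")
  if (is.null(config)) stopf("profiles lack their stratification config")
  m <- metrics[match(removed$food_code, metrics$food_code), ]
  age <- participants$age[match(removed$participant_id,
                                participants$participant_id)]
  pct <- m$pct_energy_fat
  pct[is.na(pct)] <- 0  # fat-unclassifiable removed foods: lowest fat sextile
  key <- assign_stratum(age, removed$occasion, m$energy_density, pct, config)
  kid <- paste(key$age_group, key$meal_type, key$ed_category,
               key$fat_category, sep = "/")
  uniq <- !duplicated(kid)
  resolved <- lapply(which(uniq), function(i) resolve_profile(key[i, ], profiles))
  names(resolved) <- kid[uniq]
  pg <- t(vapply(resolved, function(r) r$per_gram, numeric(length(cols))))
  fb <- vapply(resolved, function(r) r$fallback_level, integer(1))
  ridx <- match(kid, names(resolved))
  out <- data.frame(participant_id = removed$participant_id,
                    occasion = removed$occasion,
                    grams = removed$grams_removed,
                    fallback_level = fb[ridx],
                    stringsAsFactors = FALSE)
  out[cols] <- pg[ridx, , drop = FALSE]
  stopifnot(all(out$dairy_fat_g == 0))  # replacements never add dairy fat
  out
}
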