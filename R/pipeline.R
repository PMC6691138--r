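# End-to-end orchestration: data -> dairy fat -> profiles -> 4 substitution
# variants -> scores -> survey-weighted summary tables.

# Per-person outcome matrix: energy, %E macronutrients, 2,000 kcal adjusted
# micronutrients, and diet-quality scores.
study_outcomes <- function(totals, scores, basis = 2000) {
  e <- totals[, "energy_kcal"]
  pe <- function(col, kcal_g) pct_energy(totals[, col], kcal_g, e)
  adj <- function(col) ifelse(e > 0, totals[, col] * basis / e, NA_real_)
  cbind(
    energy_kcal = e,
    protein_pct_e = pe("protein_g", 4),
    fat_pct_e = pe("fat_g", 9),
    sat_fat_pct_e = pe("sfa_g", 9),
    pufa_pct_e = pe("pufa_g", 9),
    mufa_pct_e = pe("mufa_g", 9),
    dairy_fat_pct_e = ifelse(e > 0, pct_energy(totals[, "dairy_fat_g"], 9, e), 0),
    carb_pct_e = pe("carb_g", 4),
    added_sugar_pct_e = pe("added_sugar_g", 4),
    calcium_mg_adj = adj("calcium_mg"),
    vit_d_mcg_adj = adj("vit_d_mcg"),
    fiber_g_adj = adj("fiber_g"),
    potassium_mg_adj = adj("potassium_mg"),
    vit_a_mcg_adj = adj("vit_a_mcg"),
    thiamin_mg_adj = adj("thiamin_mg"),
    riboflavin_mg_adj = adj("riboflavin_mg"),
    niacin_mg_adj = adj("niacin_mg"),
    vit_b6_mg_adj = adj("vit_b6_mg"),
    vit_b12_mcg_adj = adj("vit_b12_mcg"),
    folic_acid_mcg_adj = adj("folic_acid_mcg"),
    nr = scores$nr, lim = scores$lim, nrf93 = scores$nrf93,
    hei_total = scores$hei_total,
    hei_total_fruits = scores$total_fruits,
    hei_whole_fruits = scores$whole_fruits,
    hei_total_veg = scores$total_veg,
    hei_greens_beans = scores$greens_beans,
    hei_whole_grains = scores$whole_grains,
    hei_dairy = scores$dairy,
    hei_total_protein = scores$total_protein,
    hei_seafood_plant_prot = scores$seafood_plant_prot,
    hei_fatty_acids = scores$fatty_acids,
    hei_refined_grains = scores$refined_grains,
    hei_sodium = scores$sodium,
    hei_added_sugars = scores$added_sugars,
    hei_sat_fat = scores$sat_fat)
}

summarize_versions <- function(outcome_mats, design, domain = NULL,
                               margin = 0.10) {
  versions <- names(outcome_mats)
  outcomes <- colnames(outcome_mats[[1]])
  res <- list()
  obs_cache <- list()
  for (oc in outcomes) {
    obs_cache[[oc]] <- survey_mean_ci(outcome_mats[["observed"]][, oc],
                                      design, domain = domain)
  }
  for (v in versions) {
    for (oc in outcomes) {
      est <- if (v == "observed") obs_cache[[oc]] else
        survey_mean_ci(outcome_mats[[v]][, oc], design, domain = domain)
      if (v == "observed") {
        rc <- list(relative_change = 0, p_value = NA_real_,
                   significant = FALSE)
      } else {
        rc <- relative_change_test(obs_cache[[oc]], est, margin = margin)
      }
      res[[length(res) + 1L]] <- data.frame(
        outcome = oc, version = v, mean = est$mean, se = est$se,
        ci_low = est$ci_low, ci_high = est$ci_high, n = est$n,
        relative_change = rc$relative_change, p_value = rc$p_value,
        significant = rc$significant, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Run the full dairy-fat substitution study
#'
#' Orchestrates the whole analysis: generate (or accept) the study tables,
#' recompute dairy fat per 100 g from recipes, derive food metrics and
#' sextile cutpoints, build the 576-stratum replacement profiles from the
#' observed diet, apply the four substitution variants (Model 1 = all dairy
#' fat, Model 2 = up to `cap` of energy; each as removal-only and as
#' gram-for-gram swap), score every diet version with NRF 9.3 and HEI-2015,
#' and estimate survey-weighted means with 95% CIs and the 10%
#' relative-change rule -- for the total population and for dairy-fat
#' consumers as an estimation domain.
#'
#' @param config A [synthetic_config()] describing the data to generate.
#'   Ignored when `data` is supplied.
#' @param data Optional pre-built inputs: a list with `foods`, `recipes`,
#'   `ingredients`, `participants`, `intakes` (for example read back from
#'   [write_synthetic_tables()] output).  Supply exactly one of
#'   `config`/`data`.
#' @param strat A [stratification_config()]; leave cutpoints `NULL` to
#'   recompute them from weighted consumption.
#' @param scoring A [score_config()].
#' @param cap Model 2 cap as a fraction of observed energy.
#' @param partial Model 2 boundary-item policy (see [remove_capped_dairy()]).
#' @param seed Global seed fanned out to per-stage substreams; defaults to
#'   the synthetic config's seed.
#' @param margin Relative-change significance margin.
#' @return Object of class `dairy_substitution_study` with summary `tables`
#'   (`$total`, `$consumers`), per-person `scores` and `outcomes` per diet
#'   version, the replacement `profiles` and `cutpoints`, removal and
#'   replacement audit tables, the `calcium_share` table (share with
#'   adjusted calcium >= 1,000 mg), and the inputs used.
#' @export
run_substitution_study <- function(config = synthetic_config(),
                                   data = NULL,
                                   strat = stratification_config(),
                                   scoring = score_config(),
                                   cap = 0.05,
                                   partial = c("scale", "skip"),
                                   seed = NULL, margin = 0.10) {
  partial <- match.arg(partial)
  if (!is.null(data) && !missing(config))
    stopf("supply exactly one of `config` (synthetic) or `data` (tables)")
  if (is.null(data)) {
    seed <- seed %||% config$seed
    message("stage synthetic_data: generating food database, population, recalls")
    db <- generate_food_database(config)
    participants <- generate_population(config)
    intakes <- generate_recalls(participants, db, config)
    foods <- db$foods; recipes <- db$recipes; ingredients <- db$ingredients
  } else {
    seed <- seed %||% 1L
    foods <- data$foods; recipes <- data$recipes
    ingredients <- data$ingredients
    participants <- data$participants; intakes <- data$intakes
  }

  message("stage food_composition: dairy fat by recipe expansion")
  foods <- add_dairy_fat(foods, recipes, ingredients)
  metrics <- derive_food_metrics(foods)

  message("stage replacement_profiles: cutpoints and composite profiles")
  profiles <- build_replacement_profiles(intakes, participants, foods,
                                         config = strat, metrics = metrics)
  strat_used <- attr(profiles, "config")

  message("stage substitution: Model 1 and Model 2, remove and swap")
  sub_seed <- stage_seed(seed, "substitution")
  rem1 <- apply_removal(intakes, foods, model = "M1")
  rem2 <- apply_removal(intakes, foods, model = "M2", cap = cap,
                        seed = sub_seed, partial = partial)
  swap1 <- apply_swap(rem1, profiles, participants, foods, metrics)
  swap2 <- apply_swap(rem2, profiles, participants, foods, metrics)

  message("stage diet_scores: totals, NRF 9.3, HEI-2015")
  ids <- participants$participant_id
  totals <- list(
    observed = population_totals(intakes, foods, ids),
    M1_remove = population_totals(rem1$intakes, foods, ids),
    M2_remove = population_totals(rem2$intakes, foods, ids),
    M1_swap = population_totals(rem1$intakes, foods, ids, swap1),
    M2_swap = population_totals(rem2$intakes, foods, ids, swap2))
  scores <- lapply(totals, score_diet_days, config = scoring)
  outcome_mats <- Map(study_outcomes, totals, scores,
                      basis = scoring$energy_basis)

  message("stage survey_analysis: weighted means, CIs, significance")
  design <- survey_design(participants$weight, participants$stratum,
                          participants$psu)
  consumers <- totals$observed[, "dairy_fat_g"] > 0
  tables <- list(
    total = summarize_versions(outcome_mats, design, margin = margin),
    consumers = summarize_versions(outcome_mats, design, domain = consumers,
                                   margin = margin))
  calcium_share <- do.call(rbind, lapply(names(outcome_mats), function(v) {
    sh <- share_above_threshold(outcome_mats[[v]][, "calcium_mg_adj"],
                                design, 1000)
    data.frame(version = v, share = sh$mean, ci_low = sh$ci_low,
               ci_high = sh$ci_high, stringsAsFactors = FALSE)
  }))

  structure(list(
    tables = tables, calcium_share = calcium_share,
    outcomes = outcome_mats, scores = scores, totals = totals,
    profiles = profiles, cutpoints = attr(profiles, "cutpoints"),
    metrics = metrics, removals = list(M1 = rem1$removed, M2 = rem2$removed),
    replacements = list(M1 = swap1, M2 = swap2),
    design = design, consumers = consumers,
    data = list(foods = foods, recipes = recipes, ingredients = ingredients,
                participants = participants, intakes = intakes),
    strat = strat_used, scoring = scoring, cap = cap, partial = partial,
    seed = seed, margin = margin),
    class = "dairy_substitution_study")
}

#' @export
print.dairy_substitution_study <- function(x, ...) {
  n <- nrow(x$data$participants)
  nc <- sum(x$consumers)
  cat("Dairy-fat substitution study\n")
  cat(sprintf("  participants: %d (dairy-fat consumers: %d)\n", n, nc))
  cat(sprintf("  foods: %d, intake items: %d, strata with profiles: %d of %d\n",
              nrow(x$data$foods), nrow(x$data$intakes), nrow(x$profiles),
              nrow(stratum_key_space(x$strat))))
  cat(sprintf("  Model 2 cap: %.0f%% of observed energy (%s boundary policy)\n",
              100 * x$cap, x$partial))
  key <- c("energy_kcal", "dairy_fat_pct_e", "sat_fat_pct_e", "nrf93",
           "hei_total")
  tab <- x$tables$total
  versions <- c("observed", "M1_remove", "M2_remove", "M1_swap", "M2_swap")
  m <- sapply(versions, function(v) {
    sub <- tab[tab$version == v, ]
    sub$mean[match(key, sub$outcome)]
  })
  rownames(m) <- key
  cat("\nSurvey-weighted means, total population:\n")
  print(round(m, 2))
  invisible(x)
}

#' @export
summary.dairy_substitution_study <- function(object, ...) {
  object$tables
}

#' Write the study's summary tables and audit artifacts as CSV
#'
#' @param study A [run_substitution_study()] result.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_study_tables <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    total = file.path(dir, "summary_total.csv"),
    consumers = file.path(dir, "summary_consumers.csv"),
    calcium = file.path(dir, "calcium_share.csv"),
    profiles = file.path(dir, "replacement_profiles.csv"),
    removed_m1 = file.path(dir, "removed_model1.csv"),
    removed_m2 = file.path(dir, "removed_model2.csv"))
  utils::write.csv(study$tables$total, paths["total"], row.names = FALSE)
  utils::write.csv(study$tables$consumers, paths["consumers"], row.names = FALSE)
  utils::write.csv(study$calcium_share, paths["calcium"], row.names = FALSE)
  utils::write.csv(study$profiles, paths["profiles"], row.names = FALSE)
  utils::write.csv(study$removals$M1, paths["removed_m1"], row.names = FALSE)
  utils::write.csv(study$removals$M2, paths["removed_m2"], row.names = FALSE)
  invisible(paths)
}
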