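# Synthetic dietary-survey generator: food composition database with recipes,
# a stratified two-PSU survey population, and 24-h recall intake tables with a
# calibrated population share of energy from dairy fat.

#' Configuration of the synthetic dietary survey
#'
#' The defaults emulate the structure of a national 24-h recall survey: a
#' food database spanning energy densities from 0 to roughly 680 kcal/100 g
#' and fat shares from under 1 to nearly 98 %E, dairy fat reaching mixed
#' dishes through 1-3-level recipes, four meal-occasion types, a population
#' aged 4-85 y under a stratified design with two PSUs per stratum, and a
#' population mean of 5.6% of energy from dairy fat with both heavy and zero
#' consumers present.
#'
#' @param n_foods Number of foods in the composition database.
#' @param n_participants Number of survey participants.
#' @param target_dairy_pct_energy Population survey-weighted mean percent of
#'   energy from dairy fat the recalls are calibrated to (default 5.6; 0
#'   produces a dairy-free population).
#' @param frac_dairy_foods Fraction of foods carrying dairy fat.
#' @param zero_consumer_frac Fraction of participants who consume no dairy
#'   fat, so consumer/total splits are exercised.
#' @param n_strata,psus_per_stratum Survey design shape (at least 2 PSUs per
#'   stratum are required for variance estimation).
#' @param age_range Age range in whole years, minimum 4.
#' @param meal_probs Named probabilities of the eating-occasion labels.
#' @param mean_energy_kcal Mean daily energy intake.
#' @param seed Integer seed; fully determines all generated tables.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_foods = 400, n_participants = 1000,
                             target_dairy_pct_energy = 5.6,
                             frac_dairy_foods = 0.25,
                             zero_consumer_frac = 0.16,
                             n_strata = 8, psus_per_stratum = 2,
                             age_range = c(4, 85),
                             meal_probs = c(breakfast = 0.20,
                                            lunch_dinner = 0.50,
                                            snack = 0.25, dessert = 0.05),
                             mean_energy_kcal = 2080, seed = 1) {
  stopifnot(n_foods >= 1, n_participants >= 1, n_strata >= 1,
            psus_per_stratum >= 1,
            target_dairy_pct_energy >= 0, target_dairy_pct_energy < 100,
            frac_dairy_foods >= 0, frac_dairy_foods <= 1,
            zero_consumer_frac >= 0, zero_consumer_frac < 1,
            length(age_range) == 2, age_range[1] >= 4,
            age_range[2] > age_range[1],
            abs(sum(meal_probs) - 1) < 1e-8, all(meal_probs >= 0),
            mean_energy_kcal > 0)
  structure(list(n_foods = n_foods, n_participants = n_participants,
                 target_dairy_pct_energy = target_dairy_pct_energy,
                 frac_dairy_foods = frac_dairy_foods,
                 zero_consumer_frac = zero_consumer_frac,
                 n_strata = n_strata, psus_per_stratum = psus_per_stratum,
                 age_range = age_range, meal_probs = meal_probs,
                 mean_energy_kcal = mean_energy_kcal,
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# dairy ingredient reference (fat g per 100 g)
dairy_ingredients <- function() {
  data.frame(
    ingredient_code = c("D_BUTTER", "D_CREAM", "D_CHEESE", "D_MILK",
                        "D_YOGURT", "D_ICECREAM"),
    description = c("butter", "heavy cream", "cheddar cheese", "whole milk",
                    "whole-milk yogurt", "ice cream"),
    fat_g = c(81, 36, 33, 3.3, 3.3, 11),
    stringsAsFactors = FALSE)
}

# base micronutrient draws per 100 g (lognormal, loosely realistic)
draw_micros <- function(n) {
  data.frame(
    fiber_g = stats::rlnorm(n, log(1.2), 0.8),
    sodium_mg = stats::rlnorm(n, log(250), 0.9),
    calcium_mg = stats::rlnorm(n, log(40), 0.8),
    iron_mg = stats::rlnorm(n, log(1.2), 0.7),
    magnesium_mg = stats::rlnorm(n, log(25), 0.6),
    potassium_mg = stats::rlnorm(n, log(180), 0.7),
    vit_a_mcg = stats::rlnorm(n, log(20), 1.0),
    vit_c_mg = stats::rlnorm(n, log(4), 1.2),
    vit_d_mcg = stats::rlnorm(n, log(0.2), 1.0),
    thiamin_mg = stats::rlnorm(n, log(0.12), 0.7),
    riboflavin_mg = stats::rlnorm(n, log(0.15), 0.7),
    niacin_mg = stats::rlnorm(n, log(2), 0.8),
    vit_b6_mg = stats::rlnorm(n, log(0.2), 0.8),
    vit_b12_mcg = stats::rlnorm(n, log(0.4), 1.2),
    folic_acid_mcg = stats::rlnorm(n, log(30), 0.9))
}

# food-group equivalents per 100 g for a non-dairy food of a drawn archetype
draw_fped <- function(n) {
  out <- matrix(0, n, length(fped_columns()),
                dimnames = list(NULL, fped_columns()))
  group <- sample(c("fruit", "veg", "grain", "protein", "mixed"), n, TRUE,
                  prob = c(0.15, 0.25, 0.25, 0.20, 0.15))
  for (i in seq_len(n)) {
    switch(group[i],
      fruit = {
        tf <- stats::runif(1, 0.3, 0.7)
        out[i, "fped_total_fruit"] <- tf
        out[i, "fped_whole_fruit"] <- tf * stats::runif(1, 0.4, 1)
      },
      veg = {
        tv <- stats::runif(1, 0.3, 0.8)
        out[i, "fped_total_veg"] <- tv
        if (stats::runif(1) < 0.4)
          out[i, "fped_greens_beans"] <- tv * stats::runif(1, 0.3, 0.8)
      },
      grain = {
        if (stats::runif(1) < 0.3)
          out[i, "fped_whole_grains"] <- stats::runif(1, 0.5, 2)
        else out[i, "fped_refined_grains"] <- stats::runif(1, 0.5, 2.5)
      },
      protein = {
        pr <- stats::runif(1, 1, 3)
        out[i, "fped_protein"] <- pr
        if (stats::runif(1) < 0.4)
          out[i, "fped_seafood_plant_prot"] <- pr * stats::runif(1, 0.2, 0.6)
      },
      mixed = {
        out[i, "fped_total_veg"] <- stats::runif(1, 0, 0.4)
        out[i, "fped_refined_grains"] <- stats::runif(1, 0, 1.2)
        out[i, "fped_protein"] <- stats::runif(1, 0, 1.5)
      })
  }
  as.data.frame(out)
}

#' Generate a synthetic food composition database with recipes
#'
#' Builds `n_foods` foods: a grid of replacement-eligible "anchor" foods
#' guaranteeing at least one unsaturated-fat-dominant, dairy-free food in
#' every energy-density x fat sextile cell; a configured fraction of
#' dairy-fat foods (pure dairy foods plus mixed dishes that reach dairy
#' ingredients through one- to three-level recipes); a handful of
#' zero/near-zero-energy beverages; and randomly drawn remaining foods, about
#' a quarter of which are saturated-fat dominant and hence ineligible.
#' Macronutrient energy is internally consistent by construction
#' (4/4/9 kcal/g) and fat subtypes never exceed total fat.
#'
#' @param config A [synthetic_config()].
#' @return List of class `synthetic_food_db`: `foods` (composition table with
#'   `dairy_fat_g` and a `popularity` consumption-propensity column),
#'   `recipes`, and `ingredients` (dairy ingredient fat contents).
#' @export
generate_food_database <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  with_seed(stage_seed(config$seed, "foods"), {
    n <- config$n_foods
    n_dairy <- round(config$frac_dairy_foods * n)
    n_special <- min(4L, max(0L, n - n_dairy))
    capacity <- n - n_dairy - n_special
    if (capacity < 36) {
      k <- max(1L, capacity + 1L)
      stopf(paste0("n_foods = %d is too small: cannot place a replacement-",
                   "eligible food in energy-density sextile %d, fat sextile %d"),
            n, (k - 1) %/% 6 + 1, (k - 1) %% 6 + 1)
    }
    n_anchor <- min(capacity, 229L)
    n_other <- n - n_dairy - n_special - n_anchor

    ed_bounds <- c(8, nhanes_ed_cutpoints(), 682)
    fat_bounds <- c(1.5, nhanes_fat_cutpoints(), 96)

    rows <- list()
    add_row <- function(desc, arch, ed, fat, sfa, mufa, pufa, protein,
                        added_sugar = 0, dairy = 0) {
      carb <- pmax(0, (ed - 9 * fat - 4 * protein) / 4)
      rows[[length(rows) + 1L]] <<- data.frame(
        description = desc, archetype = arch, energy_kcal = ed,
        protein_g = protein, carb_g = carb, fat_g = fat, sfa_g = sfa,
        mufa_g = mufa, pufa_g = pufa,
        added_sugar_g = pmin(added_sugar, carb), dairy_fat_g = dairy,
        stringsAsFactors = FALSE)
    }

    # 1. eligible anchors on a lattice over (log energy density, %E fat):
    # a 36-point core hitting every reference sextile cell, then a dense
    # log-spaced lattice so that every sextile cell recomputed from the
    # generated consumption also holds an eligible food.
    ed_grid <- c(9, 13.3, 19.7, 29, 43, 64, 94, 139, 206, 304, 450, 665)
    pf_grid <- c(4, 6, 8, 13, 19, 26, 35, 45, 52, 60, 67, 74, 82, 90, 95)
    core <- expand.grid(ed = c(29, 64, 94, 206, 304, 450),
                        pf = c(8, 19, 35, 45, 60, 82))
    # near-fat-free row at offset energy densities; its %fat band (1.2-1.9)
    # is separated by a gap from the rest of the lattice (>= 3 after jitter),
    # so the lowest consumption-derived fat sextile always holds eligible
    # foods at every energy density
    bottom <- data.frame(ed = c(11, 16, 24, 35, 52, 78, 115, 170, 250, 330,
                                420, 530, 640), pf = NA_real_)
    lattice <- expand.grid(ed = ed_grid, pf = pf_grid)
    lattice <- lattice[sample(nrow(lattice)), ]
    anchors <- rbind(core, bottom, lattice)
    anchors <- anchors[seq_len(min(n_anchor, nrow(anchors))), ]
    n_anchor <- nrow(anchors)
    for (j in seq_len(n_anchor)) {
      ed <- anchors$ed[j] * stats::runif(1, 0.97, 1.03)
      pf <- if (is.na(anchors$pf[j])) stats::runif(1, 1.2, 1.9) else
        anchors$pf[j] + stats::runif(1, -1, 1)
      if (j <= 36) {  # keep core anchors inside their reference cell
        ec <- max(which(c(0, ed_bounds[2:6]) <= anchors$ed[j]))
        fc <- max(which(c(0, fat_bounds[2:6]) <= anchors$pf[j]))
        ed <- min(max(ed, ed_bounds[ec] * 1.01), ed_bounds[ec + 1] * 0.99)
        pf <- min(max(pf, fat_bounds[fc] * 1.01), fat_bounds[fc + 1] * 0.99)
      }
      fat <- pf / 100 * ed / 9
      s <- stats::runif(1, 0.08, 0.28); m <- stats::runif(1, 0.40, 0.58)
      p <- min(0.97 - s - m, stats::runif(1, 0.15, 0.35))
      protein <- stats::runif(1, 0.05, 0.35) * (ed - 9 * fat) / 4
      add_row(sprintf("eligible anchor %d", j), "eligible_mix", ed, fat,
              s * fat, m * fat, p * fat, protein,
              added_sugar = stats::runif(1, 0, 0.2) * (ed / 4))
    }
    n_other <- n - n_dairy - n_special - n_anchor

    # 2. other random foods (about a quarter saturated-dominant)
    for (j in seq_len(n_other)) {
      ed <- stats::runif(1, 8, 660)
      pf <- stats::runif(1, 1.5, 95)
      fat <- pf / 100 * ed / 9
      if (stats::runif(1) < 0.25) {
        # sat-dominant, ineligible
        s <- stats::runif(1, 0.55, 0.70); m <- stats::runif(1, 0.15, 0.25)
        p <- stats::runif(1, 0.05, 0.10)
      } else {
        s <- stats::runif(1, 0.08, 0.30); m <- stats::runif(1, 0.38, 0.55)
        p <- min(0.96 - s - m, stats::runif(1, 0.12, 0.32))
      }
      protein <- stats::runif(1, 0.05, 0.35) * (ed - 9 * fat) / 4
      add_row(sprintf("random food %d", j), "random", ed, fat,
              s * fat, m * fat, p * fat, protein,
              added_sugar = stats::runif(1, 0, 0.35) * (ed / 4))
    }

    # 3. dairy foods (recipes built below)
    ing <- dairy_ingredients()
    recipes <- list()
    add_recipe <- function(parent, ingredient, grams, dairy) {
      recipes[[length(recipes) + 1L]] <<- data.frame(
        parent_code = parent, ingredient_code = ingredient,
        grams_per_100g_parent = grams, is_dairy = dairy,
        stringsAsFactors = FALSE)
    }
    dairy_start <- length(rows)  # dairy foods occupy the next n_dairy slots
    if (n_dairy > 0) {
      # intermediate preparations usable inside dish recipes (nested dairy)
      inter <- data.frame(
        code = c("M_SAUCE", "M_CUSTARD", "M_TOPPING"),
        density = c(0.25 * 36 + 0.05 * 81,            # cream + butter
                    0.30 * 3.3 + 0.10 * 36,           # milk + cream
                    NA),                              # filled below
        stringsAsFactors = FALSE)
      inter$density[3] <- 0.40 * inter$density[1] + 0.10 * 81
      add_recipe("M_SAUCE", "D_CREAM", 25, TRUE)
      add_recipe("M_SAUCE", "D_BUTTER", 5, TRUE)
      add_recipe("M_SAUCE", "FLOUR", 20, FALSE)
      add_recipe("M_CUSTARD", "D_MILK", 30, TRUE)
      add_recipe("M_CUSTARD", "D_CREAM", 10, TRUE)
      add_recipe("M_CUSTARD", "SUGAR", 15, FALSE)
      add_recipe("M_TOPPING", "M_SAUCE", 40, FALSE)
      add_recipe("M_TOPPING", "D_BUTTER", 10, TRUE)

      pure <- data.frame(
        desc = c("whole milk", "cheddar cheese", "butter",
                 "whole-milk yogurt", "ice cream", "heavy cream"),
        ingredient = c("D_MILK", "D_CHEESE", "D_BUTTER", "D_YOGURT",
                       "D_ICECREAM", "D_CREAM"),
        ed = c(61, 403, 733, 63, 207, 340),
        fat = c(3.3, 33, 81, 3.3, 11, 36),
        protein = c(3.2, 23, 0.9, 3.5, 3.5, 2.1),
        added_sugar = c(0, 0, 0, 0, 18, 0),
        fped_dairy = c(0.41, 2.35, 0, 0.41, 0.31, 0.12),
        calcium = c(113, 710, 24, 121, 128, 66),
        vit_a = c(46, 263, 684, 27, 118, 411),
        vit_d = c(1.1, 0.6, 1.5, 1.2, 0.2, 1.1),
        ribo = c(0.17, 0.43, 0.03, 0.14, 0.24, 0.19),
        b12 = c(0.45, 0.88, 0.17, 0.37, 0.39, 0.18),
        stringsAsFactors = FALSE)
      n_pure <- min(nrow(pure), n_dairy)
      pure_extra <- list()
      for (j in seq_len(n_pure)) {
        pj <- pure[j, ]
        fat <- pj$fat
        code_j <- length(rows) + 1L
        add_recipe(sprintf("F%04d", code_j), pj$ingredient, 100, TRUE)
        add_row(pj$desc, "dairy_pure", pj$ed, fat, 0.62 * fat, 0.27 * fat,
                0.04 * fat, pj$protein, pj$added_sugar, dairy = fat)
        pure_extra[[j]] <- pj
      }
      for (j in seq_len(n_dairy - n_pure)) {
        ed <- stats::runif(1, 60, 450)
        r <- stats::runif(1, 0.12, 0.55)       # dairy-fat share of energy
        d_target <- r * ed / 9
        if (stats::runif(1) < 0.3) {           # nested recipe
          k <- sample(3, 1)
          dens <- inter$density[k]
          grams <- min(60, 100 * d_target / dens)
          d <- grams * dens / 100
          ing_code <- inter$code[k]
        } else {
          k <- sample(c(1, 2, 3, 4), 1, prob = c(0.3, 0.2, 0.35, 0.15))
          dens <- ing$fat_g[k]
          gmax <- if (ing$ingredient_code[k] == "D_MILK") 80 else 60
          grams <- min(gmax, 100 * d_target / dens)
          d <- grams * dens / 100
          ing_code <- ing$ingredient_code[k]
        }
        code_j <- length(rows) + 1L           # row index = food number
        add_recipe(sprintf("F%04d", code_j), ing_code, round(grams, 2),
                   ing_code %in% ing$ingredient_code)
        add_recipe(sprintf("F%04d", code_j), "FLOUR",
                   round(stats::runif(1, 10, 35), 1), FALSE)
        extra <- min(stats::runif(1, 0, 0.6) * d + stats::runif(1, 0, 3),
                     0.92 * ed / 9 - d)
        extra <- max(0, extra)
        fat <- d + extra
        protein <- stats::runif(1, 0.10, 0.30) * (ed - 9 * fat) / 4
        add_row(sprintf("dairy dish %d", j), "dairy_mixed", ed, fat,
                0.62 * d + 0.35 * extra, 0.25 * d + 0.40 * extra,
                0.05 * d + 0.18 * extra, protein,
                added_sugar = stats::runif(1, 0, 0.2) * ed / 4, dairy = d)
      }
    }

    # 4. specials: zero / near-zero energy beverages
    specials <- list(
      list("water", 0, 0), list("diet soda", 2, 0),
      list("black coffee", 1, 0), list("sugar soda", 41, 0))
    for (j in seq_len(n_special)) {
      s <- specials[[j]]
      add_row(s[[1]], "beverage", s[[2]], s[[3]], 0, 0, 0, 0,
              added_sugar = if (s[[1]] == "sugar soda") 10 else 0)
    }

    foods <- do.call(rbind, rows)
    foods$food_code <- sprintf("F%04d", seq_len(nrow(foods)))
    micro <- draw_micros(nrow(foods))
    fped <- draw_fped(nrow(foods))
    # beverages carry next to no micronutrients
    bev <- foods$archetype == "beverage"
    micro[bev, ] <- micro[bev, ] * 0.02
    fped[bev, ] <- 0
    # dairy foods: micronutrient and dairy-group bonuses tied to dairy fat
    d <- foods$dairy_fat_g
    micro$calcium_mg <- micro$calcium_mg + 28 * d
    micro$vit_d_mcg <- micro$vit_d_mcg + 0.12 * d
    micro$riboflavin_mg <- micro$riboflavin_mg + 0.02 * d
    micro$vit_b12_mcg <- micro$vit_b12_mcg + 0.05 * d
    micro$vit_a_mcg <- micro$vit_a_mcg + 9 * d
    fped$fped_dairy <- fped$fped_dairy + ifelse(d > 0, 0.12 * d, 0)
    is_pure <- foods$archetype == "dairy_pure"
    if (any(is_pure)) {
      pure_ref <- do.call(rbind, pure_extra)
      micro$calcium_mg[is_pure] <- pure_ref$calcium
      micro$vit_a_mcg[is_pure] <- pure_ref$vit_a
      micro$vit_d_mcg[is_pure] <- pure_ref$vit_d
      micro$riboflavin_mg[is_pure] <- pure_ref$ribo
      micro$vit_b12_mcg[is_pure] <- pure_ref$b12
      fped[is_pure, ] <- 0
      fped$fped_dairy[is_pure] <- pure_ref$fped_dairy
    }
    micro$fiber_g <- pmin(micro$fiber_g, foods$carb_g * 0.5)
    foods <- cbind(foods, micro, fped)
    foods$popularity <- stats::rlnorm(nrow(foods), 0, 1) *
      ifelse(is_pure, 3, 1) * ifelse(foods$description == "water", 5, 1) *
      ifelse(foods$energy_kcal > 0 & foods$energy_kcal < 16, 0.25, 1) *
      ifelse(foods$archetype == "beverage", 0.3, 1)
    foods <- foods[c("food_code", "description", "archetype",
                     composition_columns(), "popularity")]
    rownames(foods) <- NULL

    recipes <- if (length(recipes)) do.call(rbind, recipes) else
      data.frame(parent_code = character(0), ingredient_code = character(0),
                 grams_per_100g_parent = numeric(0), is_dairy = logical(0))
    validate_food_db(foods)

    # coverage: every sextile cell must hold an eligible food
    metrics <- derive_food_metrics(foods)
    cfg <- stratification_config(ed_cutpoints = nhanes_ed_cutpoints(),
                                 fat_cutpoints = nhanes_fat_cutpoints())
    ok <- metrics$replacement_eligible & !metrics$fat_unclassifiable
    key <- assign_stratum(rep(30, sum(ok)), rep("breakfast", sum(ok)),
                          metrics$energy_density[ok],
                          metrics$pct_energy_fat[ok], cfg)
    have <- unique(paste(key$ed_category, key$fat_category))
    want <- with(expand.grid(e = 1:6, f = 1:6), paste(e, f))
    if (length(setdiff(want, have))) {
      miss <- strsplit(setdiff(want, have)[1], " ")[[1]]
      stopf("no replacement-eligible food in energy-density sextile %s, fat sextile %s",
            miss[1], miss[2])
    }
    structure(list(foods = foods, recipes = recipes,
                   ingredients = dairy_ingredients()[c("ingredient_code", "fat_g")]),
              class = "synthetic_food_db")
  })
}

#' Generate a synthetic survey population with a stratified two-PSU design
#'
#' Participants have ages drawn uniformly over the configured range (minimum
#' 4 y), positive lognormal survey weights, an ethnicity label (used only to
#' induce realistic between-group dairy gradients in the recalls), and
#' stratum/PSU labels with every stratum guaranteed at least one observation
#' in each of its PSUs.
#'
#' @param config A [synthetic_config()].
#' @return Participant data frame.
#' @export
generate_population <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  if (config$psus_per_stratum < 2)
    stopf("psus_per_stratum must be >= 2 (variance estimation impossible)")
  n <- config$n_participants
  if (n < config$n_strata * config$psus_per_stratum)
    stopf("need at least %d participants to populate every stratum x PSU cell",
          config$n_strata * config$psus_per_stratum)
  with_seed(stage_seed(config$seed, "population"), {
    grid <- expand.grid(psu = seq_len(config$psus_per_stratum),
                        stratum = seq_len(config$n_strata))
    extra <- data.frame(
      psu = sample(config$psus_per_stratum, n - nrow(grid), TRUE),
      stratum = sample(config$n_strata, n - nrow(grid), TRUE))
    design <- rbind(grid[c("stratum", "psu")], extra[c("stratum", "psu")])
    design <- design[sample(n), ]
    data.frame(
      participant_id = seq_len(n),
      age = sample(seq(config$age_range[1], config$age_range[2]), n, TRUE),
      sex = sample(c("male", "female"), n, TRUE),
      ethnicity = sample(c("nh_white", "hispanic", "nh_black", "nh_asian",
                           "other"), n, TRUE,
                         prob = c(0.62, 0.17, 0.12, 0.054, 0.036)),
      weight = stats::rlnorm(n, log(1000), 0.35),
      stratum = sprintf("S%02d", design$stratum),
      psu = sprintf("P%d", design$psu),
      stringsAsFactors = FALSE)
  })
}

#' Generate synthetic 24-h recall intakes calibrated to a dairy-fat target
#'
#' Each participant-day gets one or more eating occasions drawn from the
#' configured labels.  A per-person dairy-fat propensity (zero for a
#' configured fraction of participants, gamma-distributed otherwise, with
#' mild age and ethnicity gradients) sets a target share of the day's energy
#' to come from dairy fat; dairy items are sized to meet it and non-dairy
#' filler items complete the day's energy.  The survey-weighted population
#' mean percent of energy from dairy fat therefore converges to
#' `target_dairy_pct_energy` as the sample grows.
#'
#' @param population From [generate_population()].
#' @param food_db From [generate_food_database()].
#' @param config The matching [synthetic_config()].
#' @return Intake data frame: `participant_id`, `food_code`, `grams`,
#'   `occasion`, `is_combination`.
#' @export
generate_recalls <- function(population, food_db, config) {
  stopifnot(inherits(config, "synthetic_config"),
            inherits(food_db, "synthetic_food_db"))
  foods <- food_db$foods
  if (nrow(foods) == 0) stopf("empty food database")
  with_seed(stage_seed(config$seed, "recalls"), {
    ed <- foods$energy_kcal
    d <- foods$dairy_fat_g
    dairy_pool <- which(d > 0)
    # favor dairy foods whose dairy fat is a real share of their energy, so
    # item sizes stay realistic
    dairy_w <- foods$popularity[dairy_pool] *
      pmax(0.2, pmin(1, 9 * d[dairy_pool] / pmax(ed[dairy_pool], 1)))
    filler_pool <- which(d == 0 & ed > 5)
    filler_w <- foods$popularity[filler_pool]
    water_pool <- which(d == 0 & ed <= 5)
    if (!length(filler_pool)) stopf("food database has no non-dairy foods with energy")

    labels <- names(config$meal_probs)
    target <- config$target_dairy_pct_energy
    eth_mult <- c(nh_white = 1.08, hispanic = 0.96, nh_black = 0.75,
                  nh_asian = 0.68, other = 0.90)
    n <- nrow(population)
    zero <- stats::runif(n) < config$zero_consumer_frac
    if (target == 0 || !length(dairy_pool)) zero[] <- TRUE
    mean_s <- target / max(1e-9, 1 - config$zero_consumer_frac)
    s <- ifelse(zero, 0,
                pmin(28, stats::rgamma(n, shape = 2, scale = mean_s / 2)) *
                  ifelse(population$age < 20, 1.15, 0.97) *
                  eth_mult[population$ethnicity]) / 100

    acc <- vector("list", n)
    for (i in seq_len(n)) {
      E <- min(6000, max(600, stats::rlnorm(1, log(config$mean_energy_kcal) - 0.045, 0.3)))
      n_occ <- min(7, 1 + stats::rpois(1, 2.5))
      occs <- sample(labels, n_occ, TRUE, prob = config$meal_probs)
      f_code <- character(0); f_grams <- numeric(0); f_occ <- character(0)
      f_comb <- logical(0)
      if (s[i] > 0) {
        k <- 1 + (stats::runif(1) < 0.4)
        pick <- sample(dairy_pool, min(k, length(dairy_pool)),
                       prob = dairy_w)
        prop <- stats::runif(length(pick), 0.5, 1)
        prop <- prop / sum(prop)
        D <- s[i] * E * prop
        grams <- pmin(1000, pmax(2, D * 100 / (9 * d[pick])))
        dairy_energy <- sum(grams * ed[pick] / 100)
        if (dairy_energy > 0.85 * E) {
          grams <- grams * 0.85 * E / dairy_energy
          dairy_energy <- 0.85 * E
        }
        f_code <- foods$food_code[pick]
        f_grams <- grams
        f_occ <- sample(occs, length(pick), TRUE)
        f_comb <- stats::runif(length(pick)) < 0.3
      } else dairy_energy <- 0
      R <- E - dairy_energy
      u <- unique(occs)
      m <- max(length(u), 1 + stats::rpois(1, 4))
      if (R > 20) {
        pick <- sample(filler_pool, m, TRUE, prob = filler_w)
        g0 <- stats::rlnorm(m, log(120), 0.5)
        e0 <- g0 * ed[pick] / 100
        grams <- pmax(2, pmin(1200, g0 * R / sum(e0)))
        f_code <- c(f_code, foods$food_code[pick])
        f_grams <- c(f_grams, grams)
        f_occ <- c(f_occ, c(u, sample(occs, m - length(u), TRUE)))
        f_comb <- c(f_comb, rep(FALSE, m))
      }
      if (length(water_pool) && stats::runif(1) < 0.15) {
        f_code <- c(f_code, foods$food_code[sample(water_pool, 1)])
        f_grams <- c(f_grams, stats::runif(1, 100, 350))
        f_occ <- c(f_occ, sample(occs, 1))
        f_comb <- c(f_comb, FALSE)
      }
      if (!length(f_code)) {  # degenerate day: one small filler item
        pick <- sample(filler_pool, 1, prob = filler_w)
        f_code <- foods$food_code[pick]; f_grams <- 50
        f_occ <- occs[1]; f_comb <- FALSE
      }
      acc[[i]] <- list(code = f_code, grams = round(f_grams, 1),
                       occ = f_occ, comb = f_comb)
    }
    lens <- vapply(acc, function(a) length(a$code), integer(1))
    out <- data.frame(
      participant_id = rep(population$participant_id, lens),
      food_code = unlist(lapply(acc, `[[`, "code")),
      grams = unlist(lapply(acc, `[[`, "grams")),
      occasion = unlist(lapply(acc, `[[`, "occ")),
      is_combination = unlist(lapply(acc, `[[`, "comb")),
      stringsAsFactors = FALSE)
    out[out$grams > 0, ]
  })
}

#' Write the synthetic study tables as CSV files
#'
#' Writes the five input tables (foods, recipes, ingredients, participants,
#' intakes) into a directory using the package's documented column layout.
#'
#' @param food_db From [generate_food_database()].
#' @param population From [generate_population()].
#' @param intakes From [generate_recalls()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the written file paths.
#' @export
write_synthetic_tables <- function(food_db, population, intakes, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("foods.csv", "recipes.csv", "ingredients.csv",
                            "participants.csv", "intakes.csv"))
  utils::write.csv(food_db$foods, paths[1], row.names = FALSE)
  utils::write.csv(food_db$recipes, paths[2], row.names = FALSE)
  utils::write.csv(food_db$ingredients, paths[3], row.names = FALSE)
  utils::write.csv(population, paths[4], row.names = FALSE)
  utils::write.csv(intakes, paths[5], row.names = FALSE)
  invisible(paths)
}
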