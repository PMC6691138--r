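foods_sub <- make_food_db(
  make_food("MILKY", energy = 150, fat = 10, sfa = 6, mufa = 3, pufa = 0.5,
            protein = 5, carb = 10, dairy_fat = 10),
  make_food("CHEESY", energy = 300, fat = 15, sfa = 9, mufa = 4, pufa = 1,
            protein = 12, carb = 18, dairy_fat = 8),
  make_food("BREAD", energy = 200, fat = 2, sfa = 0.4, mufa = 1, pufa = 0.5,
            protein = 6, carb = 40))

test_that("Model 1 removes whole dairy-containing items and nothing else", {
  day0 <- data.frame(food_code = "BREAD", grams = 100, occasion = "lunch")
  r0 <- remove_all_dairy(day0, foods_sub)
  expect_equal(r0$day, day0)
  expect_equal(nrow(r0$removed), 0)

  # 2 dairy items totalling 300 kcal + 1 non-dairy 200 kcal
  day <- data.frame(food_code = c("MILKY", "CHEESY", "BREAD"),
                    grams = c(100, 50, 100),
                    occasion = c("breakfast", "lunch", "lunch"))
  r <- remove_all_dairy(day, foods_sub)
  tot <- daily_totals(r$day, foods_sub)
  expect_equal(unname(tot["energy_kcal"]), 200)
  expect_equal(unname(tot["dairy_fat_g"]), 0)
  expect_equal(sort(r$removed$food_code), c("CHEESY", "MILKY"))
  # removed dairy-fat energy: 9 * (10 + 4) g
  expect_equal(r$dairy_fat_energy_removed, 9 * (10 + 0.5 * 8))
})

test_that("Model 2 caps removed dairy-fat energy at the configured share", {
  # below-cap person: identical to Model 1
  day_small <- data.frame(food_code = c("MILKY", "BREAD", "BREAD"),
                          grams = c(10, 200, 300),
                          occasion = c("breakfast", "lunch", "dinner"))
  # dairy-fat energy = 9 kcal; total = 15 + 400 + 600 = 1015; 9/1015 < 5%
  r_small <- remove_capped_dairy(day_small, foods_sub, cap = 0.05, seed = 4)
  r_all <- remove_all_dairy(day_small, foods_sub)
  expect_equal(r_small$day[c("food_code", "grams")],
               r_all$day[c("food_code", "grams")])

  # single dairy item carrying 8% of energy as dairy fat -> 5/8 of grams go
  # MILKY 100 g: dairy-fat 90 kcal, item 150 kcal; need total 1125 kcal
  day_big <- data.frame(food_code = c("MILKY", "BREAD"),
                        grams = c(100, 487.5),
                        occasion = c("breakfast", "lunch"))
  E <- 150 + 487.5 * 2  # 1125 kcal; dairy-fat 90 kcal = 8 %E
  r_big <- remove_capped_dairy(day_big, foods_sub, cap = 0.05, seed = 4)
  expect_equal(r_big$removed$grams_removed, 100 * 5 / 8)
  expect_equal(r_big$dairy_fat_energy_removed, 0.05 * E)
  kept <- r_big$day
  expect_equal(kept$grams[kept$food_code == "MILKY"], 100 * 3 / 8)

  # skip policy keeps the boundary item whole, removal stays below the cap
  r_skip <- remove_capped_dairy(day_big, foods_sub, cap = 0.05, seed = 4,
                                partial = "skip")
  expect_equal(nrow(r_skip$removed), 0)
  expect_lt(r_skip$dairy_fat_energy_removed, 0.05 * E)

  # determinism: same seed, same result
  expect_identical(remove_capped_dairy(day_big, foods_sub, seed = 99),
                   remove_capped_dairy(day_big, foods_sub, seed = 99))
})

test_that("gram-for-gram swap adds the resolved profile's nutrients", {
  cols <- composition_columns()
  prof <- data.frame(age_group = 2, meal_type = 1, ed_category = 2,
                     fat_category = 5, total_weight = 1, n_foods = 1L)
  prof[cols] <- 0
  prof$energy_kcal <- 2.0  # kcal per gram
  attr(prof, "config") <- stratification_config(
    ed_cutpoints = nhanes_ed_cutpoints(),
    fat_cutpoints = nhanes_fat_cutpoints())
  parts <- data.frame(participant_id = 1, age = 30, weight = 1)

  none <- apply_swap(list(removed = NULL), prof, parts, foods_sub)
  expect_equal(nrow(none), 0)

  removal <- list(removed = data.frame(
    participant_id = 1, food_code = "MILKY", occasion = "breakfast",
    grams_removed = 100, dairy_fat_kcal_removed = 90))
  rep <- apply_swap(removal, prof, parts, foods_sub)
  expect_equal(rep$grams, 100)
  expect_equal(rep$grams * rep$energy_kcal, 200)  # 100 g x 2 kcal/g
  expect_equal(rep$dairy_fat_g, 0)
})

test_that("population-level invariants hold on synthetic data", {
  sm <- small_synthetic()
  rem1 <- apply_removal(sm$ints, sm$foods, model = "M1")
  rem2 <- apply_removal(sm$ints, sm$foods, model = "M2", cap = 0.05,
                        seed = 5)
  ids <- sm$pop$participant_id
  tot_obs <- population_totals(sm$ints, sm$foods, ids)
  tot1 <- population_totals(rem1$intakes, sm$foods, ids)
  tot2 <- population_totals(rem2$intakes, sm$foods, ids)

  # M1 dominance and the cap
  removed1 <- 9 * (tot_obs[, "dairy_fat_g"] - tot1[, "dairy_fat_g"])
  removed2 <- 9 * (tot_obs[, "dairy_fat_g"] - tot2[, "dairy_fat_g"])
  expect_true(all(removed1 >= removed2 - 1e-9))
  expect_true(all(removed2 <= 0.05 * tot_obs[, "energy_kcal"] + 1e-6))
  expect_true(all(tot1[, "dairy_fat_g"] == 0))

  # swap preserves grams per person and adds no dairy
  prof <- suppressMessages(build_replacement_profiles(
    sm$ints, sm$pop, sm$foods, metrics = sm$metrics))
  for (rem in list(rem1, rem2)) {
    repl <- apply_swap(rem, prof, sm$pop, sm$foods, sm$metrics)
    g_obs <- rowsum(sm$ints$grams, sm$ints$participant_id)
    g_mod <- rowsum(c(rem$intakes$grams, repl$grams),
                    c(rem$intakes$participant_id, repl$participant_id))
    expect_equal(g_mod[rownames(g_obs), 1], g_obs[, 1], tolerance = 1e-9)
    expect_true(all(repl$dairy_fat_g == 0))
  }

  # per-participant substreams make results order-independent
  shuffled <- sm$ints[sample(nrow(sm$ints)), ]
  rem2b <- apply_removal(shuffled, sm$foods, model = "M2", cap = 0.05,
                         seed = 5)
  a <- rem2b$removed[order(rem2b$removed$participant_id,
                           rem2b$removed$food_code), ]
  b <- rem2$removed[order(rem2$removed$participant_id,
                          rem2$removed$food_code), ]
  expect_equal(a$grams_removed, b$grams_removed)
})
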