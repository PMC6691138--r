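test_that("daily totals sum grams times per-gram nutrients", {
  foods <- make_food_db(
    make_food("A", energy = 100, protein = 5, carb = 10, fat = 2, mufa = 1,
              pufa = 0.5, sfa = 0.5, calcium_mg = 50),
    make_food("B", energy = 200, protein = 2, carb = 40, fat = 2, mufa = 1,
              pufa = 0.5, sfa = 0.5, calcium_mg = 10))
  empty <- data.frame(food_code = character(0), grams = numeric(0))
  expect_true(all(daily_totals(empty, foods) == 0))
  one <- data.frame(food_code = "A", grams = 200)
  expect_equal(unname(daily_totals(one, foods)["energy_kcal"]), 200)
  expect_error(daily_totals(data.frame(food_code = "ZZ", grams = 1), foods),
               "unresolvable")

  # random day equals an independent brute-force sum
  set.seed(403)
  sm <- small_synthetic()
  day <- sm$ints[sample(nrow(sm$ints), 7), c("food_code", "grams")]
  tot <- daily_totals(day, sm$foods)
  brute <- 0
  for (i in seq_len(nrow(day))) {
    f <- sm$foods[sm$foods$food_code == day$food_code[i], ]
    brute <- brute + day$grams[i] * f$potassium_mg / 100
  }
  expect_equal(unname(tot["potassium_mg"]), brute)

  # population version agrees with per-day version
  ptot <- population_totals(sm$ints, sm$foods, sm$pop$participant_id)
  pid <- sm$ints$participant_id[1]
  expect_equal(ptot[as.character(pid), ],
               daily_totals(sm$ints[sm$ints$participant_id == pid,
                                    c("food_code", "grams")], sm$foods))
})

test_that("energy adjustment rescales to the 2,000 kcal basis", {
  tot <- make_totals(energy_kcal = 1000, calcium_mg = 500)
  adj <- energy_adjust(tot)
  expect_equal(unname(adj["calcium_mg"]), 1000)
  expect_equal(energy_adjust(make_totals(energy_kcal = 2000, iron_mg = 9)),
               make_totals(energy_kcal = 2000, iron_mg = 9))
  half <- energy_adjust(make_totals(energy_kcal = 4000, fiber_g = 20))
  expect_equal(unname(half["fiber_g"]), 10)
  expect_message(z <- energy_adjust(make_totals()), "zero-energy")
  expect_true(all(is.na(z)))
})

test_that("NR truncates each percent-DV component at 100", {
  cfg <- score_config()
  at_dv <- make_totals(energy_kcal = 2000)
  at_dv[names(cfg$dv)] <- cfg$dv
  expect_equal(as.numeric(nr_score(at_dv, cfg)), 900)

  over <- at_dv; over["calcium_mg"] <- 2600  # 2x DV
  nr <- nr_score(over, cfg)
  expect_equal(as.numeric(nr), 900)
  expect_equal(unname(attr(nr, "components")[, "calcium_mg"]), 100)

  half <- make_totals(energy_kcal = 2000)
  half[names(cfg$dv)] <- cfg$dv / 2
  expect_equal(as.numeric(nr_score(half, cfg)), 450)
})

test_that("LIM components interpolate between thresholds", {
  expect_equal(lim_component(12, 8, 16), 0.5)
  expect_equal(lim_component(5, 6, 26), 0)
  expect_equal(lim_component(2500, 1100, 2000), 1)
  cfg <- score_config()
  expect_equal(as.numeric(lim_score(30, 20, 2500, cfg)), 300)
  expect_equal(as.numeric(lim_score(6, 8, 1100, cfg)), 0)
  expect_equal(as.numeric(lim_score(6, 12, 1100, cfg)), 50)
})

test_that("NRF 9.3 is NR minus LIM", {
  expect_equal(nrf93(900, 0), 900)
  expect_equal(nrf93(0, 300), -300)
  expect_equal(nrf93(450, 150), 300)
})

test_that("HEI-2015 spans 0 to 100 with the published component maxima", {
  cfg <- score_config()
  expect_equal(cfg$hei$max_points, c(5, 5, 5, 5, 10, 10, 5, 5, 10, 10, 10,
                                     10, 10))
  ideal <- make_totals(
    energy_kcal = 2000, fat_g = 40, sfa_g = 10, mufa_g = 18, pufa_g = 12,
    added_sugar_g = 20, sodium_mg = 2000, fped_total_fruit = 2,
    fped_whole_fruit = 1, fped_total_veg = 2.6, fped_greens_beans = 0.5,
    fped_whole_grains = 3.2, fped_refined_grains = 2, fped_dairy = 2.7,
    fped_protein = 5.2, fped_seafood_plant_prot = 1.7)
  expect_equal(hei2015_score(ideal, cfg)$hei_total, 100)

  worst <- make_totals(
    energy_kcal = 2000, fat_g = 60, sfa_g = 40, mufa_g = 5, pufa_g = 5,
    added_sugar_g = 140, sodium_mg = 9000, fped_refined_grains = 9)
  expect_equal(hei2015_score(worst, cfg)$hei_total, 0)

  # scale invariance: multiplying a day by any positive constant changes
  # no density-based component
  expect_equal(hei2015_score(ideal * 3.7, cfg), hei2015_score(ideal, cfg))
})

test_that("score bounds hold for randomized diets and monotonicity for NR/LIM", {
  set.seed(404)
  cfg <- score_config()
  for (r in 1:50) {
    tot <- make_totals(
      energy_kcal = stats::runif(1, 500, 5000),
      protein_g = stats::runif(1, 0, 300), fiber_g = stats::runif(1, 0, 80),
      vit_a_mcg = stats::runif(1, 0, 3000), vit_c_mg = stats::runif(1, 0, 400),
      vit_d_mcg = stats::runif(1, 0, 60), calcium_mg = stats::runif(1, 0, 4000),
      iron_mg = stats::runif(1, 0, 60), potassium_mg = stats::runif(1, 0, 9000),
      magnesium_mg = stats::runif(1, 0, 1500),
      fat_g = stats::runif(1, 0, 200), sfa_g = stats::runif(1, 0, 80),
      mufa_g = stats::runif(1, 0, 80), pufa_g = stats::runif(1, 0, 60),
      added_sugar_g = stats::runif(1, 0, 200),
      sodium_mg = stats::runif(1, 0, 8000),
      fped_total_fruit = stats::runif(1, 0, 5),
      fped_dairy = stats::runif(1, 0, 6))
    adj <- energy_adjust(tot, cfg$energy_basis)
    nr <- as.numeric(nr_score(adj, cfg))
    lim <- as.numeric(lim_score(
      100 * 4 * tot["added_sugar_g"] / tot["energy_kcal"],
      100 * 9 * tot["sfa_g"] / tot["energy_kcal"], adj["sodium_mg"], cfg))
    hei <- hei2015_score(tot, cfg)$hei_total
    expect_true(nr >= 0 && nr <= 900)
    expect_true(lim >= 0 && lim <= 300)
    expect_true(nrf93(nr, lim) >= -300 && nrf93(nr, lim) <= 900)
    expect_true(hei >= 0 && hei <= 100)

    # NR nondecreasing in a qualifying nutrient; LIM nondecreasing in sodium
    adj2 <- adj; adj2["potassium_mg"] <- adj2["potassium_mg"] * 1.5
    expect_gte(as.numeric(nr_score(adj2, cfg)), nr)
    lim2 <- as.numeric(lim_score(
      100 * 4 * tot["added_sugar_g"] / tot["energy_kcal"],
      100 * 9 * tot["sfa_g"] / tot["energy_kcal"],
      adj["sodium_mg"] * 1.5, cfg))
    expect_gte(lim2, lim)
  }
})

test_that("zero saturated fat earns the maximum fatty-acid ratio points", {
  cfg <- score_config()
  tot <- make_totals(energy_kcal = 1000, fat_g = 10, sfa_g = 0, mufa_g = 6,
                     pufa_g = 4)
  expect_equal(suppressMessages(hei2015_score(tot, cfg))$fatty_acids, 10)
})
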