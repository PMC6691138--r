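test_that("weighted quantile cutpoints follow the inverse-CDF definition", {
  expect_equal(weighted_quantile_cutpoints(rep(7, 5), rep(1, 5)),
               rep(7, 5))
  # smallest value whose cumulative weight reaches 0.5 among 1..10 is 5
  expect_equal(weighted_quantile_cutpoints(1:10, rep(1, 10), 0.5), 5)
  expect_error(weighted_quantile_cutpoints(numeric(0), numeric(0)),
               "no data")

  # brute-force oracle on random instances
  set.seed(401)
  for (r in 1:100) {
    n <- sample(3:50, 1)
    v <- round(stats::runif(n, 0, 100), 1)
    w <- stats::rexp(n)
    probs <- sort(stats::runif(3, 0.05, 0.95))
    oracle <- vapply(probs, function(p) {
      o <- order(v); cum <- 0
      for (i in o) {
        cum <- cum + w[i] / sum(w)
        if (cum >= p - 1e-12) return(v[i])
      }
      max(v)
    }, numeric(1))
    expect_equal(weighted_quantile_cutpoints(v, w, probs), oracle)
  }
})

test_that("stratum assignment matches the published category definitions", {
  cfg <- stratification_config(ed_cutpoints = nhanes_ed_cutpoints(),
                               fat_cutpoints = nhanes_fat_cutpoints())
  k <- assign_stratum(age = c(45, 10, 25, 70), occasion = rep("breakfast", 4),
                      energy_density = c(100, 40, 49.8, 682),
                      pct_energy_fat = c(20, 5, 16.4, 90), cfg)
  expect_equal(k$age_group, c(3, 1, 2, 4))       # 40-64 y -> group 3
  expect_equal(k$ed_category, c(3, 1, 2, 6))     # 100 kcal/100 g -> 3rd sextile
  expect_equal(k$fat_category, c(2, 1, 2, 6))    # 20 %E -> 2nd sextile
  # boundary values fall in the upper category (49.8, 16.4 above)
  expect_error(assign_stratum(30, "brunch", 100, 20, cfg), "brunch")
  expect_error(assign_stratum(2, "breakfast", 100, 20, cfg), "age")
})

test_that("default key space has exactly 576 strata", {
  expect_equal(nrow(stratum_key_space()), 576)
})

test_that("composite profiles are consumption-weighted per-gram averages", {
  foods <- make_food_db(
    make_food("E1", energy = 200, fat = 10, sfa = 2, mufa = 5, pufa = 2,
              protein = 5, carb = 20, calcium_mg = 80),
    make_food("E2", energy = 100, fat = 2, sfa = 0.5, mufa = 1, pufa = 0.4,
              protein = 4, carb = 15, calcium_mg = 40),
    make_food("DR", energy = 300, fat = 20, sfa = 14, mufa = 4, pufa = 1,
              protein = 5, carb = 25, dairy_fat = 12))
  parts <- data.frame(participant_id = 1:2, age = c(30, 50),
                      weight = c(2, 2))
  cfg <- stratification_config(ed_cutpoints = nhanes_ed_cutpoints(),
                               fat_cutpoints = nhanes_fat_cutpoints())

  # single eligible food consumed -> profile equals its per-gram vector
  ints1 <- data.frame(participant_id = 1, food_code = "E1", grams = 150,
                      occasion = "lunch")
  p1 <- build_replacement_profiles(ints1, parts, foods, cfg)
  expect_equal(nrow(p1), 1)
  expect_equal(p1$calcium_mg, 0.8)
  expect_equal(p1$energy_kcal, 2.0)

  # two foods with equal weight x grams -> arithmetic mean of per-gram vectors
  ints2 <- data.frame(participant_id = c(1, 1), food_code = c("E1", "E2"),
                      grams = c(100, 100), occasion = "lunch")
  p2 <- build_replacement_profiles(ints2, parts, foods, cfg)
  # E1 (200 kcal/100 g, 45 %E) and E2 (100, 18) share age/meal but not
  # ed/fat cells; the weighted average over rows recovers the item mean
  w <- p2$total_weight
  expect_equal(sum(p2$calcium_mg * w) / sum(w), (0.8 + 0.4) / 2)

  # dairy food never contributes
  ints3 <- rbind(ints2, data.frame(participant_id = 2, food_code = "DR",
                                   grams = 500, occasion = "dinner"))
  p3 <- build_replacement_profiles(ints3, parts, foods, cfg)
  expect_true(all(p3$dairy_fat_g == 0))
  expect_equal(sum(p3$total_weight), sum(p2$total_weight))
})

test_that("profiles match a brute-force weighted average on random events", {
  set.seed(402)
  sm <- small_synthetic()
  cfg <- stratification_config(ed_cutpoints = nhanes_ed_cutpoints(),
                               fat_cutpoints = nhanes_fat_cutpoints())
  ev <- sm$ints[sample(nrow(sm$ints), 10), ]
  prof <- build_replacement_profiles(ev, sm$pop, sm$foods, cfg,
                                     metrics = sm$metrics)
  # brute force: loop over events, accumulate per stratum
  fidx <- match(ev$food_code, sm$foods$food_code)
  pidx <- match(ev$participant_id, sm$pop$participant_id)
  met <- sm$metrics[fidx, ]
  for (r in seq_len(nrow(prof))) {
    num <- 0; den <- 0
    for (i in seq_len(nrow(ev))) {
      if (!met$replacement_eligible[i] || met$fat_unclassifiable[i]) next
      k <- assign_stratum(sm$pop$age[pidx[i]], ev$occasion[i],
                          met$energy_density[i], met$pct_energy_fat[i], cfg)
      if (k$age_group == prof$age_group[r] &&
          k$meal_type == prof$meal_type[r] &&
          k$ed_category == prof$ed_category[r] &&
          k$fat_category == prof$fat_category[r]) {
        u <- sm$pop$weight[pidx[i]] * ev$grams[i]
        num <- num + u * sm$foods$calcium_mg[fidx[i]] / 100
        den <- den + u
      }
    }
    expect_equal(prof$calcium_mg[r], num / den)
    expect_equal(prof$total_weight[r], den)
  }
})

test_that("profile convexity: composites stay within contributing foods' range", {
  sm <- small_synthetic()
  prof <- suppressMessages(
    build_replacement_profiles(sm$ints, sm$pop, sm$foods,
                               metrics = sm$metrics))
  el <- sm$metrics$replacement_eligible & !sm$metrics$fat_unclassifiable
  for (col in c("energy_kcal", "protein_g", "fat_g", "calcium_mg")) {
    rng <- range(sm$foods[[col]][el] / 100)
    expect_true(all(prof[[col]] >= rng[1] - 1e-9 &
                      prof[[col]] <= rng[2] + 1e-9))
  }
  expect_true(all(prof$energy_kcal <= 9))  # kcal per gram ceiling
  expect_true(all(prof$total_weight > 0))
})

test_that("profile resolution falls back by marginalizing dimensions in order", {
  cols <- composition_columns()
  mk <- function(ag, mt, ed, fc, kcal, w) {
    row <- data.frame(age_group = ag, meal_type = mt, ed_category = ed,
                      fat_category = fc, total_weight = w, n_foods = 1L)
    row[cols] <- 0; row$energy_kcal <- kcal; row
  }
  profiles <- rbind(mk(1, 1, 3, 2, 2.0, 10), mk(1, 1, 3, 5, 4.0, 30),
                    mk(2, 2, 1, 1, 1.0, 5))

  # exact key -> identity
  r0 <- resolve_profile(list(age_group = 1, meal_type = 1, ed_category = 3,
                             fat_category = 2), profiles)
  expect_equal(r0$fallback_level, 0)
  expect_equal(unname(r0$per_gram["energy_kcal"]), 2.0)

  # absent fat category -> weighted composite over the fat margin
  r1 <- resolve_profile(list(age_group = 1, meal_type = 1, ed_category = 3,
                             fat_category = 6), profiles)
  expect_equal(r1$fallback_level, 1)
  expect_equal(unname(r1$per_gram["energy_kcal"]),
               (2.0 * 10 + 4.0 * 30) / 40)

  # nothing matches until the global pool
  r4 <- resolve_profile(list(age_group = 4, meal_type = 4, ed_category = 6,
                             fat_category = 6), profiles)
  expect_equal(r4$fallback_level, 4)
  expect_equal(unname(r4$per_gram["energy_kcal"]),
               (2 * 10 + 4 * 30 + 1 * 5) / 45)

  expect_error(resolve_profile(list(age_group = 1, meal_type = 1,
                                    ed_category = 1, fat_category = 1),
                               profiles[0, ]), "empty")
})
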