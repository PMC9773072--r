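# LME conversion, mean daily intake and adequacy classification.

test_that("lme_of_record converts by protein ratio with liquid milk as identity", {
  comp <- tiny_compositions()
  expect_equal(lme_of_record(list(amount = 100), composition_entry(comp, "milk_liq")), 100)
  # 20 g powder at 20 g protein/100 g against 3.0 reference
  expect_equal(lme_of_record(list(amount = 20), composition_entry(comp, "powder"), 3.0),
               20 * 20 / 3)
  expect_equal(lme_of_record(list(amount = 0), composition_entry(comp, "yog")), 0)
  expect_error(lme_of_record(list(amount = 50), composition_entry(comp, "rice")),
               "not a dairy food")
  expect_error(lme_of_record(list(amount = 50), composition_entry(comp, "yog"), 0),
               "positive")
})

test_that("dairy_profile averages daily LME over the 4-day diary", {
  comp <- tiny_compositions()
  p <- dairy_profile(daily_diary("c1", "milk_liq", 348), comp)
  expect_equal(p$lme_total, 348)
  expect_true(p$consumed_subtype[["LIQUID_MILK"]])
  expect_true(p$consumed_any_dairy)

  # dairy on one day only: 400 g over 4 days
  one_day <- diary_of("c1", data.frame(day = c(1, 1:4), food_id = c("milk_liq", rep("rice", 4)),
                                       amount = c(400, rep(100, 4))))
  expect_equal(dairy_profile(one_day, comp)$lme_total, 100)

  none <- daily_diary("c1", "rice", 150)
  p0 <- dairy_profile(none, comp)
  expect_equal(p0$lme_total, 0)
  expect_false(p0$consumed_any_dairy)
  expect_false(any(p0$consumed_subtype))
})

test_that("mean_daily_intake averages diet over 4 days and adds supplements", {
  comp <- tiny_compositions()
  ci <- mean_daily_intake(daily_diary("c1", "milk_liq", 100), compositions = comp)
  expect_equal(ci$diet_only[["energy"]], 54)
  expect_equal(ci$intake, ci$diet_only)

  supp <- as_supplement_records(data.frame(child_id = "c1", day = 1:4, vitamin_d = 5))
  ci2 <- mean_daily_intake(daily_diary("c1", "milk_liq", 100), supp, comp)
  expect_equal(ci2$intake[["vitamin_d"]], ci2$diet_only[["vitamin_d"]] + 5)
  expect_equal(ci2$intake - ci2$diet_only, ci2$supplement)

  # two foods on day 1 only: (150/100*100 + 50/100*300) / 4 = 75
  comp2 <- as_composition_table(rbind(
    data.frame(food_id = "a", name = "a", dairy_subtype = "NONE", as.list(nv(energy = 100))),
    data.frame(food_id = "b", name = "b", dairy_subtype = "NONE", as.list(nv(energy = 300)))))
  d <- diary_of("c1", data.frame(day = c(1, 1), food_id = c("a", "b"), amount = c(150, 50)))
  expect_equal(mean_daily_intake(d, compositions = comp2)$diet_only[["energy"]], 75)
})

test_that("cohort intake matches the per-child computation", {
  co <- small_synthetic(seed = 3)
  cohort <- cohort_from_synthetic(co)
  for (cid in sample(co$children$child_id, 5)) {
    single <- mean_daily_intake(co$diet[co$diet$child_id == cid, ],
                                co$supplements, co$compositions)
    expect_equal(cohort$intake[cid, ], single$intake)
    expect_equal(cohort$lme_total[[cid]], single$dairy$lme_total)
    expect_equal(child_intake(cohort, cid)$dairy$dairy_contribution,
                 single$dairy$dairy_contribution)
  }
})

test_that("fat energy percent and fiber density follow their definitions", {
  expect_equal(fat_energy_percent(nv(energy = 100, fat = 0)), 0)
  expect_equal(round_half_up(fat_energy_percent(nv(energy = 993.99, fat = 37.87)), 2),
               34.29)
  expect_equal(fat_energy_percent(nv(energy = 900, fat = 100)), 100)
  expect_error(fat_energy_percent(nv(fat = 1)), "zero energy")
  expect_equal(fiber_density(nv(energy = 1000, fiber = 10)), 10)
  expect_equal(fiber_density(nv(energy = 994, fiber = 3.94)), 1000 * 3.94 / 994)
  expect_error(fiber_density(nv(fiber = 1)), "zero energy")
})

test_that("classification is strict-below for inadequacy, strict-above for surplus", {
  dri <- tiny_dri()
  flags <- classify_adequacy(nv(energy = 1000, fat = 30, fiber = 9.99,
                                calcium = 311.82, potassium = 1200, vitamin_d = 8),
                             age_months = 40, dri = dri)
  expect_true(flags[["calcium"]])          # 311.82 < 600
  expect_false(flags[["potassium"]])       # exactly at AI is adequate
  expect_false(flags[["vitamin_d"]])       # exactly at EAR is adequate
  expect_true(flags[["fiber_density"]])    # 9.99 < 10
  expect_false("fat_energy_pct" %in% names(flags))  # no AMDR rule at 40 months

  flags2 <- classify_adequacy(nv(energy = 1000, fat = 39, fiber = 10, calcium = 600,
                                 potassium = 1500, vitamin_d = 9),
                              age_months = 60, dri = dri)
  expect_true(flags2[["fat_energy_pct"]])  # 35.1 %E > 35
  expect_false(flags2[["fiber_density"]])  # boundary 10 is adequate
  expect_false(flags2[["calcium"]])        # boundary EAR is adequate
  expect_error(classify_adequacy(nv(energy = 1), 40, dri, require = "fat_energy_pct"),
               "no DRI rule")
})

test_that("classification is monotone in each nutrient", {
  dri <- load_dri_table(dairysim_extdata("dri"))
  set.seed(5)
  for (i in 1:25) {
    base <- nutrient_vector(stats::setNames(runif(20, 0, 50), nutrients()))
    base[["energy"]] <- runif(1, 400, 1500)
    age <- sample(37:72, 1)
    f0 <- classify_adequacy(base, age, dri)
    nu <- sample(setdiff(nutrients(), c("energy", "fat")), 1)
    up <- base; up[[nu]] <- up[[nu]] + runif(1, 1, 100)
    f1 <- classify_adequacy(up, age, dri)
    common <- intersect(names(f0), names(f1))
    expect_true(all(!f1[common] | f0[common]))  # never ADEQUATE -> INADEQUATE
  }
})

test_that("cohort adequacy reports counts with the percent convention", {
  co <- small_synthetic(seed = 9)
  cohort <- cohort_from_synthetic(co)
  dri <- load_dri_table(dairysim_extdata("dri"))
  flags <- cohort_classify(cohort, dri)
  ad <- cohort_adequacy(cohort, dri)
  for (i in seq_len(nrow(ad))) {
    nu <- ad$nutrient[i]
    expect_equal(ad$n_flagged[i], sum(flags[, nu], na.rm = TRUE))
    expect_equal(ad$n[i], sum(!is.na(flags[, nu])))
    expect_equal(ad$pct[i], percent(ad$n_flagged[i], ad$n[i]))
  }
  # the fat AMDR bound only applies from 49 months
  expect_lt(ad$n[ad$nutrient == "fat_energy_pct"], nrow(co$children))
})

test_that("intake engine invariants: LME identity, homogeneity, supplement additivity", {
  comp <- tiny_compositions()
  co <- small_synthetic(seed = 21)
  cohort <- cohort_from_synthetic(co)
  # intake - diet_only equals the mean daily supplement vector
  expect_equal(cohort$intake - cohort$diet_only, cohort$supplement)
  # doubling every dairy amount doubles lme and dairy contribution exactly
  diet2 <- co$diet
  idx <- match(diet2$food_id, co$compositions$food_id)
  dairy_rows <- co$compositions$dairy_subtype[idx] != "NONE"
  diet2$amount[dairy_rows] <- 2 * diet2$amount[dairy_rows]
  cohort2 <- compute_cohort_intake(diet2, co$compositions, co$children, co$supplements)
  expect_equal(cohort2$lme_total, 2 * cohort$lme_total)
  expect_equal(cohort2$dairy_contribution, 2 * cohort$dairy_contribution)
  # adding a zero-fiber food strictly decreases fiber density
  v <- nv(energy = 800, fiber = 6)
  v2 <- v + nv(energy = 62)
  expect_lt(fiber_density(v2), fiber_density(v))
})
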