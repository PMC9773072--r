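# The five simulation models: substitution at matching volume and
# top-up to the recommended amount.

cow_like <- function() {
  nv(energy = 54, carbohydrate = 3.4, protein = 3.0, fat = 3.2,
     calcium = 104, potassium = 109, vitamin_b2 = 0.14)
}

test_that("substitution is a no-op for children without dairy", {
  comp <- tiny_compositions()
  cohort <- compute_cohort_intake(daily_diary("c1", "rice", 200), comp,
                                  one_child_roster())
  m <- scenario_model("SUBSTITUTE", cow_like(), 2L)
  sim <- substitute_dairy(cohort, m)
  expect_identical(sim$cohort$intake, cohort$intake)
  expect_equal(sim$delta_energy, c(c1 = 0))
})

test_that("self-substitution with an identical composition is the identity", {
  comp <- tiny_compositions()
  d <- rbind(daily_diary("c1", "milk_liq", 100), daily_diary("c1", "rice", 150))
  cohort <- compute_cohort_intake(as_diet_records(as.data.frame(d), strict = FALSE),
                                  comp, one_child_roster())
  m <- scenario_model("SUBSTITUTE", cow_like(), 2L)  # same composition as milk_liq
  sim <- substitute_dairy(cohort, m)
  expect_equal(sim$cohort$intake, cohort$intake)
  expect_equal(sim$lme_post, cohort$lme_total)
})

test_that("substitution arithmetic removes the dairy contribution and adds by volume", {
  # lme 200 g/d, dairy calcium contribution 220 mg, substitute 50 mg/100 g
  comp <- as_composition_table(data.frame(
    food_id = "m", name = "milk", dairy_subtype = "LIQUID_MILK",
    as.list(nv(energy = 54, protein = 3, calcium = 110))))
  cohort <- compute_cohort_intake(daily_diary("c1", "m", 200), comp, one_child_roster())
  expect_equal(cohort$dairy_contribution[1, "calcium"], 220)
  m <- scenario_model("SUBSTITUTE", nv(energy = 31, protein = 3, calcium = 50), 1L)
  sim <- substitute_dairy(cohort, m)
  expect_equal(sim$cohort$intake[1, "calcium"],
               cohort$intake[1, "calcium"] - 220 + 200 / 100 * 50)
})

test_that("top-up leaves children at or above the recommendation untouched", {
  comp <- tiny_compositions()
  m <- scenario_model("TOPUP", cow_like(), 4L, target_amount = 350)
  at <- compute_cohort_intake(daily_diary("c1", "milk_liq", 350), comp, one_child_roster())
  sim <- topup_dairy(at, m)
  expect_identical(sim$cohort$intake, at$intake)
  above <- compute_cohort_intake(daily_diary("c1", "milk_liq", 400), comp, one_child_roster())
  sim2 <- topup_dairy(above, m)
  expect_identical(sim2$cohort$intake, above$intake)
  expect_equal(sim2$lme_post, c(c1 = 400))
})

test_that("top-up energy change equals the shortfall times substitute energy", {
  comp <- tiny_compositions()
  cohort <- compute_cohort_intake(daily_diary("c1", "milk_liq", 174), comp,
                                  one_child_roster())
  m <- scenario_model("TOPUP", nv(energy = 62, protein = 3), 4L)
  sim <- topup_dairy(cohort, m)
  expect_equal(unname(sim$delta_energy), 176 / 100 * 62)  # 109.12 kcal/d
})

test_that("run_scenario reclassifies adequacy and respects identity/degenerate cases", {
  dri <- tiny_dri()
  comp <- tiny_compositions()
  d <- rbind(daily_diary("c1", "milk_liq", 100), daily_diary("c1", "veg", 300))
  cohort <- compute_cohort_intake(as_diet_records(as.data.frame(d), strict = FALSE),
                                  comp, one_child_roster())
  res <- run_scenario(cohort, scenario_model("SUBSTITUTE", cow_like(), 2L), dri)
  expect_identical(res$flags_pre, res$flags_post)

  # top-up on a cohort already at target leaves the summary at baseline
  at <- compute_cohort_intake(daily_diary("c1", "milk_liq", 360), comp, one_child_roster())
  res2 <- run_scenario(at, scenario_model("TOPUP", cow_like(), 4L), dri)
  expect_equal(res2$summary, cohort_adequacy(at, dri))
})

test_that("top-up floors every child's dairy at the target across a synthetic cohort", {
  co <- small_synthetic(seed = 2, n = c(17, 17, 16))
  cohort <- cohort_from_synthetic(co)
  models <- default_scenario_models()
  sim <- topup_dairy(cohort, models$model5)
  expect_equal(sim$lme_post, pmax(cohort$lme_total, 350))
  expect_true(all(sim$lme_post >= 350))
  unchanged <- cohort$lme_total >= 350
  expect_identical(sim$cohort$intake[unchanged, ], cohort$intake[unchanged, ])
})

test_that("substitution conserves dairy volume and books energy exactly", {
  co <- small_synthetic(seed = 4, n = c(20, 20, 20))
  cohort <- cohort_from_synthetic(co)
  models <- default_scenario_models()
  for (m in models[1:3]) {
    sim <- substitute_dairy(cohort, m)
    expect_equal(sim$lme_post, cohort$lme_total)
    expect_equal(sim$cohort$intake[, "energy"] - cohort$intake[, "energy"],
                 cohort$lme_total / 100 * m$substitute[["energy"]] -
                   cohort$dairy_contribution[, "energy"])
  }
  for (m in models[4:5]) {
    sim <- topup_dairy(cohort, m)
    add <- pmax(0, m$target_amount - cohort$lme_total)
    expect_equal(unname(sim$cohort$intake[, "energy"] - cohort$intake[, "energy"]),
                 unname(add / 100 * m$substitute[["energy"]]))
  }
})

test_that("a zero-fiber top-up never decreases the fiber inadequacy count", {
  dri <- load_dri_table(dairysim_extdata("dri"))
  for (seed in 1:3) {
    co <- small_synthetic(seed = seed, n = c(15, 15, 15))
    cohort <- cohort_from_synthetic(co)
    m <- default_scenario_models()$model4  # cow's milk: fiber 0
    expect_equal(m$substitute[["fiber"]], 0)
    res <- run_scenario(cohort, m, dri)
    expect_gte(sum(res$flags_post[, "fiber_density"]),
               sum(res$flags_pre[, "fiber_density"]))
  }
})

test_that("vector-algebra engine matches record-level re-simulation", {
  co <- small_synthetic(seed = 8, n = c(7, 7, 6))
  cohort <- cohort_from_synthetic(co)
  for (m in default_scenario_models()) {
    fast <- if (m$mode == "SUBSTITUTE") substitute_dairy(cohort, m) else topup_dairy(cohort, m)
    slow <- simulate_scenario_records(co$diet, co$compositions, co$children, m,
                                      supplements = co$supplements)
    expect_equal(fast$cohort$intake, slow$intake, tolerance = 1e-11)
    expect_equal(fast$lme_post, slow$lme_total, tolerance = 1e-11)
  }
})

test_that("scenario model constructor validates mode and target", {
  expect_error(scenario_model("TOPUP", cow_like(), target_amount = -1), "positive")
  m <- scenario_model("SUBSTITUTE", cow_like(), 1L)
  expect_error(topup_dairy(structure(list(), class = "cohort_intake"), m), "TOPUP")
})
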