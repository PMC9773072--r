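# In-code fixtures: a minimal composition table, diary builders and a
# small DRI rule set used across the unit tests.

nv <- function(...) nutrient_vector(...)

tiny_compositions <- function() {
  row <- function(food_id, name, subtype, ...) {
    data.frame(food_id = food_id, name = name, dairy_subtype = subtype,
               as.list(nv(...)), stringsAsFactors = FALSE)
  }
  as_composition_table(rbind(
    row("milk_liq", "Liquid milk", "LIQUID_MILK",
        energy = 54, carbohydrate = 3.4, protein = 3.0, fat = 3.2,
        calcium = 104, potassium = 109, vitamin_b2 = 0.14),
    row("powder", "Milk powder", "MILK_POWDER",
        energy = 480, carbohydrate = 55, protein = 20, fat = 21,
        calcium = 700, vitamin_d = 7),
    row("yog", "Yogurt", "YOGURT",
        energy = 72, carbohydrate = 10, protein = 2.8, fat = 2.5, calcium = 110),
    row("cheese", "Cheese", "OTHER_DAIRY",
        energy = 330, protein = 25, fat = 25, calcium = 730),
    row("rice", "Rice", "NONE",
        energy = 116, carbohydrate = 25.9, protein = 2.6, fiber = 0.3,
        vitamin_b1 = 0.02),
    row("veg", "Greens", "NONE",
        energy = 25, carbohydrate = 4, protein = 2, fiber = 2.2,
        vitamin_c = 40, potassium = 200, calcium = 60),
    row("oilseed", "Oil", "NONE", energy = 899, fat = 99.9)
  ))
}

# one child's 4-day diary: `foods` is a data.frame(day, food_id, amount)
diary_of <- function(child_id, foods) {
  df <- data.frame(child_id = child_id, day = foods$day,
                   day_type = c("working", "working", "weekend", "weekend")[foods$day],
                   food_id = foods$food_id, amount = foods$amount,
                   stringsAsFactors = FALSE)
  as_diet_records(df, strict = FALSE)
}

# the same food every day
daily_diary <- function(child_id, food_id, amount) {
  diary_of(child_id, data.frame(day = 1:4, food_id = food_id, amount = amount))
}

tiny_dri <- function() {
  as_dri_table(data.frame(
    nutrient = c("calcium", "potassium", "vitamin_d", "fiber_density",
                 "fat_energy_pct"),
    age_min_months = c(37, 37, 37, 37, 49),
    age_max_months = c(73, 73, 73, 73, 73),
    rule_type = c("EAR", "AI", "EAR", "FIBER_DENSITY", "AMDR_UPPER"),
    threshold = c(600, 1200, 8, 10, 35),
    stringsAsFactors = FALSE))
}

one_child_roster <- function(child_id = "c1", age_months = 40) {
  as_children(data.frame(child_id = child_id, age_months = age_months))
}

small_synthetic <- function(seed = 1, n = c(7, 7, 6), ...) {
  generate_cohort(cohort_spec(n_per_age_group = n, seed = seed, ...))
}

cohort_from_synthetic <- function(co, ...) {
  compute_cohort_intake(co$diet, co$compositions, co$children, co$supplements, ...)
}
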