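# Scenario engine: the five dairy simulation models.
#   1  SUBSTITUTE soymilk      2  SUBSTITUTE cow's milk   3  SUBSTITUTE FMP-PSC
#   4  TOPUP cow's milk        5  TOPUP FMP-PSC (to 350 g/d by default)
# Substitution removes each child's entire mean daily dairy contribution
# and replaces it with the same liquid-equivalent volume of the
# substitute; top-up adds substitute only to children below the target.
# Supplements are never altered. The engine works on the child-level
# mean dairy contribution; a record-level re-simulation path
# (simulate_scenario_records) exists as an independent check.

.DEFAULT_TARGET_AMOUNT <- 350  # recommended dairy amount, g/d

#' Define a scenario model
#'
#' @param mode `"SUBSTITUTE"` (replace all dairy at matching volume) or
#'   `"TOPUP"` (add substitute until the dairy intake reaches
#'   `target_amount`).
#' @param substitute Composition of the substitute food per 100 g of
#'   liquid(-equivalent) product: a composition entry
#'   ([composition_entry()]), a one-row `composition_table` slice, or a
#'   named nutrient vector.
#' @param model_id Optional integer 1--5 consistent with the standard
#'   mapping (1 soymilk-SUB, 2 cow-SUB, 3 FMP-SUB, 4 cow-TOPUP,
#'   5 FMP-TOPUP); purely a label.
#' @param target_amount Top-up target, g/d (default 350). Ignored for
#'   substitution models.
#' @param label Optional display label.
#' @return A `scenario_model`.
#' @export
scenario_model <- function(mode = c("SUBSTITUTE", "TOPUP"), substitute,
                           model_id = NA_integer_,
                           target_amount = .DEFAULT_TARGET_AMOUNT,
                           label = NULL) {
  mode <- match.arg(mode)
  per100g <- if (is.list(substitute) && !is.null(substitute$per100g)) {
    substitute$per100g
  } else if (is.data.frame(substitute)) {
    unlist(substitute[1, .NUTRIENTS])
  } else {
    substitute
  }
  per100g <- validate_nutrient_vector(per100g)
  if (mode == "TOPUP" && (!is.finite(target_amount) || target_amount <= 0)) {
    stop("target_amount must be a positive number of grams", call. = FALSE)
  }
  structure(list(
    model_id = as.integer(model_id),
    mode = mode,
    substitute = per100g,
    target_amount = if (mode == "TOPUP") target_amount else NA_real_,
    label = label %||% sprintf("model %s (%s)", model_id, tolower(mode))
  ), class = "scenario_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.scenario_model <- function(x, ...) {
  cat("<scenario_model> ", x$label, "; substitute energy ",
      x$substitute[["energy"]], " kcal/100 g",
      if (x$mode == "TOPUP") paste0("; target ", x$target_amount, " g/d"),
      "\n", sep = "")
  invisible(x)
}

#' The five standard scenario models
#'
#' Builds the standard model set from a substitute composition table
#' containing rows `soymilk`, `cow_milk` and `fmp_psc` (per 100 g of
#' liquid-equivalent product). Defaults to the bundled synthetic
#' placeholder compositions, which users should replace with verified
#' label values.
#'
#' @param substitutes A `composition_table` with the three substitute
#'   foods, or a path to one.
#' @param target_amount Top-up target for models 4--5, g/d.
#' @return Named list of five `scenario_model`s (`model1` .. `model5`).
#' @export
default_scenario_models <- function(substitutes = dairysim_extdata("substitutes"),
                                    target_amount = .DEFAULT_TARGET_AMOUNT) {
  if (is.character(substitutes)) substitutes <- load_composition_table(substitutes)
  sub <- function(id) composition_entry(substitutes, id)
  list(
    model1 = scenario_model("SUBSTITUTE", sub("soymilk"), 1L, label = "model 1 (soymilk substitution)"),
    model2 = scenario_model("SUBSTITUTE", sub("cow_milk"), 2L, label = "model 2 (cow's milk substitution)"),
    model3 = scenario_model("SUBSTITUTE", sub("fmp_psc"), 3L, label = "model 3 (FMP-PSC substitution)"),
    model4 = scenario_model("TOPUP", sub("cow_milk"), 4L, target_amount, label = "model 4 (cow's milk top-up)"),
    model5 = scenario_model("TOPUP", sub("fmp_psc"), 5L, target_amount, label = "model 5 (FMP-PSC top-up)")
  )
}

#' Load scenario models from a JSON configuration
#'
#' The configuration is a JSON array of objects with fields `model_id`,
#' `mode`, `substitute_food_id` (resolved in `substitutes`) or inline
#' `substitute` composition, and optional `target_amount`.
#'
#' @param path JSON file path.
#' @param substitutes `composition_table` used to resolve
#'   `substitute_food_id` references.
#' @return Named list of `scenario_model`s.
#' @export
load_scenario_models <- function(path, substitutes = dairysim_extdata("substitutes")) {
  if (is.character(substitutes)) substitutes <- load_composition_table(substitutes)
  cfg <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  models <- lapply(cfg, function(m) {
    sub <- if (!is.null(m$substitute_food_id)) {
      composition_entry(substitutes, m$substitute_food_id)
    } else {
      nutrient_vector(unlist(m$substitute))
    }
    scenario_model(mode = m$mode, substitute = sub,
                   model_id = m$model_id %||% NA_integer_,
                   target_amount = m$target_amount %||% .DEFAULT_TARGET_AMOUNT,
                   label = m$label %||% NULL)
  })
  names(models) <- vapply(models, function(m) paste0("model", m$model_id), character(1))
  models
}

.apply_substitute <- function(cohort, model) {
  n <- nrow(cohort$children)
  add <- outer(cohort$lme_total / 100, model$substitute)
  new_diet <- cohort$diet_only - cohort$dairy_contribution + add
  tol <- 1e-9 * pmax(abs(cohort$diet_only), abs(cohort$dairy_contribution), 1)
  neg <- new_diet < 0
  if (any(new_diet < -tol)) {
    stop("substitution produced a negative intake beyond numerical tolerance",
         call. = FALSE)
  }
  new_diet[neg] <- 0
  list(diet_only = new_diet,
       dairy_contribution = add,
       lme_post = cohort$lme_total,
       added_grams = cohort$lme_total)
}

.apply_topup <- function(cohort, model) {
  add_amount <- pmax(0, model$target_amount - cohort$lme_total)
  add <- outer(add_amount / 100, model$substitute)
  list(diet_only = cohort$diet_only + add,
       dairy_contribution = cohort$dairy_contribution + add,
       lme_post = pmax(cohort$lme_total, model$target_amount),
       added_grams = add_amount)
}

#' Apply a substitution model to a cohort
#'
#' Replaces each child's entire mean daily dairy contribution with the
#' same liquid-equivalent volume of the substitute:
#' `intake_post = intake - dairy_contribution + lme_total/100 * substitute`.
#' Children with no dairy are untouched; dairy volume is conserved.
#'
#' @param ci A `cohort_intake` (may hold a single child).
#' @param m A `scenario_model` with mode `SUBSTITUTE`.
#' @return A `simulated_cohort`: the post-scenario `cohort_intake` plus
#'   `model`, `delta_energy` and `lme_post`.
#' @export
substitute_dairy <- function(ci, m) {
  stopifnot(inherits(ci, "cohort_intake"), inherits(m, "scenario_model"))
  if (m$mode != "SUBSTITUTE") stop("substitute_dairy requires a SUBSTITUTE model", call. = FALSE)
  .simulate(ci, m, .apply_substitute(ci, m))
}

#' Apply a top-up model to a cohort
#'
#' Adds `max(0, target_amount - lme_total)` grams of substitute per day
#' to each child; existing dairy (and everything else) is retained, and
#' children at or above the target are returned unchanged.
#'
#' @inheritParams substitute_dairy
#' @param m A `scenario_model` with mode `TOPUP`.
#' @return A `simulated_cohort`.
#' @export
topup_dairy <- function(ci, m) {
  stopifnot(inherits(ci, "cohort_intake"), inherits(m, "scenario_model"))
  if (m$mode != "TOPUP") stop("topup_dairy requires a TOPUP model", call. = FALSE)
  .simulate(ci, m, .apply_topup(ci, m))
}

.simulate <- function(cohort, model, applied) {
  post <- cohort
  post$diet_only <- applied$diet_only
  post$dairy_contribution <- applied$dairy_contribution
  post$intake <- applied$diet_only + cohort$supplement
  post$lme_total <- applied$lme_post
  structure(list(
    model = model,
    cohort = post,
    baseline = cohort,
    delta_energy = stats::setNames(
      as.numeric(post$intake[, "energy"] - cohort$intake[, "energy"]),
      rownames(post$intake)),
    lme_post = applied$lme_post,
    added_grams = applied$added_grams
  ), class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat("<simulated_cohort> ", x$model$label, "; median energy change ",
      format(stats::median(x$delta_energy), digits = 4), " kcal/d\n", sep = "")
  invisible(x)
}

#' Run one scenario model over a cohort
#'
#' Applies the model to every child, reclassifies adequacy on the
#' post-simulation intakes, and returns the paired before/after
#' structure used by the reporting layer.
#'
#' @param cohort A `cohort_intake` (baseline).
#' @param m A `scenario_model`.
#' @param dri A `dri_table`; must cover every child's age for each of its
#'   nutrients' bands that apply.
#' @return List with the `simulated_cohort` fields plus `flags_pre`,
#'   `flags_post` (logical matrices from [cohort_classify()]) and
#'   `summary` (post-simulation [cohort_adequacy()]).
#' @export
run_scenario <- function(cohort, m, dri) {
  sim <- if (m$mode == "SUBSTITUTE") substitute_dairy(cohort, m) else topup_dairy(cohort, m)
  sim$flags_pre <- cohort_classify(cohort, dri)
  sim$flags_post <- cohort_classify(sim$cohort, dri)
  sim$summary <- cohort_adequacy(sim$cohort, dri)
  sim
}

#' Record-level scenario re-simulation
#'
#' Independent slow path: rebuilds the diary itself (dairy rows swapped
#' for substitute rows at their per-record liquid milk equivalents, or
#' substitute rows appended for top-up) and recomputes the cohort intake
#' from scratch with [compute_cohort_intake()]. Under linearity of the
#' intake computation this must agree with [substitute_dairy()] /
#' [topup_dairy()] to numerical precision; it exists as a consistency
#' check and is exercised in the test suite.
#'
#' @param diet `diet_records`.
#' @param compositions `composition_table` for the diary foods.
#' @param children Children roster.
#' @param m A `scenario_model`.
#' @param supplements Optional supplement records.
#' @param ref_milk_protein Reference milk protein, g/100 g.
#' @param n_days Diary length.
#' @return A `cohort_intake` of post-scenario intakes.
#' @export
simulate_scenario_records <- function(diet, compositions, children, m,
                                      supplements = NULL,
                                      ref_milk_protein = .DEFAULT_REF_MILK_PROTEIN,
                                      n_days = 4) {
  children <- as_children(as.data.frame(children))
  sub_id <- ".scenario_substitute"
  sub_row <- data.frame(food_id = sub_id, name = "scenario substitute",
                        dairy_subtype = "LIQUID_MILK",
                        as.list(m$substitute), stringsAsFactors = FALSE)
  comp2 <- as_composition_table(rbind(as.data.frame(compositions), sub_row))
  idx <- match(diet$food_id, compositions$food_id)
  is_dairy <- compositions$dairy_subtype[idx] != "NONE"
  if (m$mode == "SUBSTITUTE") {
    kept <- diet[!is_dairy, , drop = FALSE]
    dairy <- diet[is_dairy, , drop = FALSE]
    if (nrow(dairy)) {
      dairy$amount <- .lme_of_records(dairy, compositions, ref_milk_protein)
      dairy$food_id <- sub_id
    }
    new_diet <- rbind(kept, dairy)
  } else {
    base <- compute_cohort_intake(diet, compositions, children,
                                  ref_milk_protein = ref_milk_protein,
                                  n_days = n_days)
    add_amount <- pmax(0, m$target_amount - base$lme_total)
    add_rows <- do.call(rbind, lapply(which(add_amount > 0), function(i) {
      data.frame(child_id = children$child_id[i], day = 1:4,
                 day_type = c("working", "working", "weekend", "weekend"),
                 food_id = sub_id, amount = add_amount[i],
                 stringsAsFactors = FALSE)
    }))
    new_diet <- rbind(as.data.frame(diet), add_rows)
  }
  compute_cohort_intake(as_diet_records(new_diet, strict = FALSE), comp2,
                        children, supplements = supplements,
                        ref_milk_protein = ref_milk_protein, n_days = n_days)
}
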