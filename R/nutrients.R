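#' dairysim: dairy substitution and fortification scenario modelling
#'
#' Pipeline for assessing how dairy substitution or top-up scenarios change
#' the nutrient adequacy of young children, from raw multi-day diet diaries
#' to before/after paired statistics. See `vignette("dairysim-methods")`
#' for the modelling conventions.
#'
#' @keywords internal
"_PACKAGE"

# Canonical nutrient axis. Every composition table, intake vector and
# scenario substitute uses exactly these 20 components, in this order,
# with a fixed unit per component (per day for intakes, per 100 g edible
# portion for compositions). No unit inference is ever performed.
.NUTRIENTS <- c(
  "energy", "carbohydrate", "protein", "fat", "fiber", "dha",
  "calcium", "iron", "zinc", "iodine", "potassium",
  "vitamin_a", "vitamin_b1", "vitamin_b2", "vitamin_b3", "vitamin_b6",
  "vitamin_b9", "vitamin_b12", "vitamin_c", "vitamin_d"
)

.NUTRIENT_UNITS <- c(
  energy = "kcal", carbohydrate = "g", protein = "g", fat = "g",
  fiber = "g", dha = "mg", calcium = "mg", iron = "mg", zinc = "mg",
  iodine = "ug", potassium = "mg", vitamin_a = "ug RAE",
  vitamin_b1 = "mg", vitamin_b2 = "mg", vitamin_b3 = "mg NE",
  vitamin_b6 = "mg", vitamin_b9 = "ug DFE", vitamin_b12 = "ug",
  vitamin_c = "mg", vitamin_d = "ug"
)

.DAIRY_SUBTYPES <- c("NONE", "LIQUID_MILK", "MILK_POWDER", "YOGURT", "OTHER_DAIRY")

# Derived quantities that DRI rules may address in addition to the
# nutrients themselves.
.DERIVED_QUANTITIES <- c("fiber_density", "fat_energy_pct")

.RULE_TYPES <- c("EAR", "AI", "FIBER_DENSITY", "AMDR_UPPER")

#' Canonical nutrient names
#'
#' The fixed 20-component nutrient axis used throughout the package:
#' energy plus 19 nutrients, each with a fixed unit (see [nutrient_units()]).
#'
#' @return Character vector of nutrient names.
#' @export
#' @examples
#' nutrients()
nutrients <- function() .NUTRIENTS

#' Units of the canonical nutrients
#'
#' @return Named character vector mapping each nutrient to its unit
#'   (amount per day for intakes; per 100 g edible portion in
#'   composition tables).
#' @export
nutrient_units <- function() .NUTRIENT_UNITS

#' Recognised dairy subtypes
#'
#' Dairy items are tagged with one of four subtypes (or `NONE` for
#' non-dairy foods): liquid milk, milk powder, yogurt, and other dairy
#' foods such as cheese.
#'
#' @return Character vector of subtype codes.
#' @export
dairy_subtypes <- function() .DAIRY_SUBTYPES

#' Construct a nutrient vector
#'
#' Builds a complete named numeric vector over the canonical nutrient
#' axis. Components not supplied default to zero; every component must
#' be finite and non-negative. Addition and scalar scaling of nutrient
#' vectors are ordinary componentwise vector operations and stay on the
#' axis.
#'
#' @param ... Named numeric components (e.g. `energy = 54, protein = 3`),
#'   or a single named numeric vector/list.
#' @return Named numeric vector of length 20 in canonical order.
#' @export
#' @examples
#' nutrient_vector(energy = 54, protein = 3.0, calcium = 104)
nutrient_vector <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]]))) {
    args <- as.list(args[[1]])
  }
  v <- stats::setNames(numeric(length(.NUTRIENTS)), .NUTRIENTS)
  if (length(args)) {
    nm <- names(args)
    if (is.null(nm) || any(nm == "")) {
      stop("all nutrient_vector components must be named", call. = FALSE)
    }
    bad <- setdiff(nm, .NUTRIENTS)
    if (length(bad)) {
      stop("unknown nutrient name(s): ", paste(bad, collapse = ", "), call. = FALSE)
    }
    v[nm] <- vapply(args, as.numeric, numeric(1))
  }
  validate_nutrient_vector(v)
  v
}

#' Validate a nutrient vector
#'
#' Checks that `v` is a named numeric vector carrying all canonical
#' components with finite, non-negative values.
#'
#' @param v Named numeric vector.
#' @return `v`, invisibly, reordered to canonical order.
#' @export
validate_nutrient_vector <- function(v) {
  if (is.null(names(v)) || !all(.NUTRIENTS %in% names(v))) {
    stop("nutrient vector must name all canonical components; missing: ",
         paste(setdiff(.NUTRIENTS, names(v)), collapse = ", "), call. = FALSE)
  }
  v <- v[.NUTRIENTS]
  if (any(!is.finite(v))) stop("nutrient vector has non-finite components", call. = FALSE)
  if (any(v < 0)) {
    stop("nutrient vector has negative component(s): ",
         paste(names(v)[v < 0], collapse = ", "), call. = FALSE)
  }
  invisible(v)
}

#' Age group of a child, in months
#'
#' Ages are binned into three half-open strata: `[37,49)`, `[49,61)` and
#' `[61,73)` months, labelled by the conventional inclusive month ranges.
#'
#' @param age_months Integer vector of ages in months, each in 37--72.
#' @return Factor with levels `"37-48"`, `"49-60"`, `"61-72"`.
#' @export
#' @examples
#' age_group_of(c(37, 48, 49, 72))
age_group_of <- function(age_months) {
  age_months <- as.numeric(age_months)
  if (any(!is.finite(age_months)) || any(age_months < 37) || any(age_months >= 73)) {
    stop("age_months must lie in [37, 73) months", call. = FALSE)
  }
  cut(age_months, breaks = c(37, 49, 61, 73), right = FALSE,
      labels = c("37-48", "49-60", "61-72"))
}

#' Age group labels
#'
#' @return The three stratum labels in order.
#' @export
age_groups <- function() c("37-48", "49-60", "61-72")
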