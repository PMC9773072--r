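# Intake engine: liquid-milk-equivalent conversion, per-child mean daily
# nutrient intake (diet + supplements) and adequacy classification under
# DRI rules. The diary unit of analysis is the plain 4-day mean; no
# within-person variance adjustment is applied.

.DEFAULT_REF_MILK_PROTEIN <- 3.0  # g protein / 100 g liquid milk

#' Liquid milk equivalent of one diary record
#'
#' Dairy items other than liquid milk are converted to the mass of liquid
#' milk with the same protein content: `amount * protein_per100g /
#' ref_milk_protein`. Liquid milk passes through unchanged.
#'
#' @param record One diet record (list or one-row data frame with
#'   `amount` in grams).
#' @param entry Composition entry for the food (see
#'   [composition_entry()]); must be a dairy subtype.
#' @param ref_milk_protein Reference liquid-milk protein, g/100 g
#'   (default 3.0).
#' @return Liquid milk equivalent, grams.
#' @export
#' @examples
#' comp <- as_composition_table(data.frame(
#'   food_id = "pow", name = "milk powder", dairy_subtype = "MILK_POWDER",
#'   t(nutrient_vector(energy = 480, protein = 20))))
#' lme_of_record(list(amount = 20), composition_entry(comp, "pow"), 3.0)
lme_of_record <- function(record, entry, ref_milk_protein = .DEFAULT_REF_MILK_PROTEIN) {
  if (!is.finite(ref_milk_protein) || ref_milk_protein <= 0) {
    stop("ref_milk_protein must be a positive number", call. = FALSE)
  }
  if (identical(entry$dairy_subtype, "NONE")) {
    stop("lme_of_record: '", entry$food_id, "' is not a dairy food", call. = FALSE)
  }
  amount <- as.numeric(record$amount)
  if (entry$dairy_subtype == "LIQUID_MILK") return(amount)
  amount * entry$per100g[["protein"]] / ref_milk_protein
}

# Vectorised LME over a diet-record frame joined to compositions.
.lme_of_records <- function(records, compositions, ref_milk_protein) {
  idx <- match(records$food_id, compositions$food_id)
  subtype <- compositions$dairy_subtype[idx]
  protein <- compositions$protein[idx]
  ifelse(subtype == "LIQUID_MILK", records$amount,
         records$amount * protein / ref_milk_protein)
}

.nutrient_matrix_by_child <- function(records, compositions, child_ids, n_days) {
  out <- matrix(0, nrow = length(child_ids), ncol = length(.NUTRIENTS),
                dimnames = list(child_ids, .NUTRIENTS))
  if (nrow(records) == 0L) return(out)
  idx <- match(records$food_id, compositions$food_id)
  if (anyNA(idx)) {
    stop("records reference unknown food_id(s): ",
         paste(unique(records$food_id[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  per <- as.matrix(compositions[idx, .NUTRIENTS, drop = FALSE]) * (records$amount / 100)
  agg <- rowsum(per, group = records$child_id)
  out[rownames(agg), ] <- agg / n_days
  out
}

#' Dairy consumption profile of one child's diary
#'
#' Summarises a 4-day diary into total liquid milk equivalents (g/d, mean
#' over the diary), LME by dairy subtype, consumption flags, and the mean
#' daily nutrient contribution of all dairy records.
#'
#' @param records Diet records for one child.
#' @param compositions A `composition_table`.
#' @param ref_milk_protein Reference milk protein, g/100 g.
#' @param n_days Diary length used for the mean (default 4).
#' @return List with `child_id`, `lme_total`, `lme_by_subtype`,
#'   `consumed_any_dairy`, `consumed_subtype`, `dairy_contribution`.
#' @export
dairy_profile <- function(records, compositions,
                          ref_milk_protein = .DEFAULT_REF_MILK_PROTEIN,
                          n_days = 4) {
  cid <- unique(records$child_id)
  if (length(cid) != 1L) stop("dairy_profile expects one child's diary", call. = FALSE)
  idx <- match(records$food_id, compositions$food_id)
  if (anyNA(idx)) {
    stop("records reference unknown food_id(s): ",
         paste(unique(records$food_id[is.na(idx)]), collapse = ", "), call. = FALSE)
  }
  subtype <- compositions$dairy_subtype[idx]
  dairy <- records[subtype != "NONE", , drop = FALSE]
  dairy_sub <- subtype[subtype != "NONE"]
  lme <- if (nrow(dairy)) .lme_of_records(dairy, compositions, ref_milk_protein) else numeric(0)
  subtypes <- setdiff(.DAIRY_SUBTYPES, "NONE")
  lme_by <- vapply(subtypes, function(s) sum(lme[dairy_sub == s]) / n_days, numeric(1))
  consumed <- vapply(subtypes, function(s) any(dairy$amount[dairy_sub == s] > 0), logical(1))
  contrib <- .nutrient_matrix_by_child(dairy, compositions, cid, n_days)[1, ]
  list(
    child_id = cid,
    lme_total = sum(lme_by),
    lme_by_subtype = lme_by,
    consumed_any_dairy = any(consumed),
    consumed_subtype = consumed,
    dairy_contribution = contrib
  )
}

#' Mean daily nutrient intake of one child
#'
#' Diet-only intake is the diary total divided by the diary length
#' (default 4 days); supplements declared on any day are averaged over
#' the same denominator and added.
#'
#' @param records Diet records for one child.
#' @param supplements Supplement records for the same child (may be
#'   `NULL` or empty).
#' @param compositions A `composition_table`.
#' @param ref_milk_protein Reference milk protein, g/100 g.
#' @param n_days Diary length (default 4).
#' @return List with `intake`, `diet_only`, `supplement` (nutrient
#'   vectors, per day) and `dairy` (the [dairy_profile()]).
#' @export
mean_daily_intake <- function(records, supplements = NULL, compositions = NULL,
                              ref_milk_protein = .DEFAULT_REF_MILK_PROTEIN,
                              n_days = 4) {
  if (is.null(compositions)) stop("a composition table is required", call. = FALSE)
  cid <- unique(records$child_id)
  if (length(cid) != 1L) stop("mean_daily_intake expects one child's diary", call. = FALSE)
  diet_only <- .nutrient_matrix_by_child(records, compositions, cid, n_days)[1, ]
  supp <- stats::setNames(numeric(length(.NUTRIENTS)), .NUTRIENTS)
  if (!is.null(supplements) && nrow(supplements)) {
    s <- supplements[supplements$child_id == cid, .NUTRIENTS, drop = FALSE]
    if (nrow(s)) supp <- colSums(as.matrix(s)) / n_days
  }
  list(
    intake = diet_only + supp,
    diet_only = diet_only,
    supplement = supp,
    dairy = dairy_profile(records, compositions, ref_milk_protein, n_days)
  )
}

#' Compute intakes for a whole cohort
#'
#' Vectorised cohort-level version of [mean_daily_intake()]. Returns a
#' `cohort_intake` object holding per-child intake matrices and dairy
#' profiles, the container consumed by the scenario engine and the
#' summary statistics.
#'
#' @param diet `diet_records` for all children.
#' @param compositions A `composition_table`.
#' @param children Children roster (`child_id`, `age_months`); see
#'   [as_children()].
#' @param supplements Optional `supplement_records`.
#' @param ref_milk_protein Reference milk protein, g/100 g.
#' @param n_days Diary length (default 4).
#' @return A `cohort_intake`: list with `children` (roster), matrices
#'   `intake`, `diet_only`, `supplement`, `dairy_contribution` (children
#'   x nutrients), vector `lme_total`, matrix `lme_by_subtype`, logical
#'   matrix `consumed`, and `ref_milk_protein`.
#' @export
compute_cohort_intake <- function(diet, compositions, children,
                                  supplements = NULL,
                                  ref_milk_protein = .DEFAULT_REF_MILK_PROTEIN,
                                  n_days = 4) {
  children <- as_children(as.data.frame(children))
  ids <- children$child_id
  missing_children <- setdiff(unique(diet$child_id), ids)
  if (length(missing_children)) {
    stop("diet records for children absent from roster: ",
         paste(missing_children, collapse = ", "), call. = FALSE)
  }
  diet_only <- .nutrient_matrix_by_child(diet, compositions, ids, n_days)
  supp <- matrix(0, nrow = length(ids), ncol = length(.NUTRIENTS),
                 dimnames = list(ids, .NUTRIENTS))
  if (!is.null(supplements) && nrow(supplements)) {
    s <- supplements[supplements$child_id %in% ids, , drop = FALSE]
    if (nrow(s)) {
      agg <- rowsum(as.matrix(s[, .NUTRIENTS, drop = FALSE]), group = s$child_id)
      supp[rownames(agg), ] <- agg / n_days
    }
  }
  idx <- match(diet$food_id, compositions$food_id)
  subtype_all <- compositions$dairy_subtype[idx]
  dairy <- diet[subtype_all != "NONE", , drop = FALSE]
  dairy_sub <- subtype_all[subtype_all != "NONE"]
  contrib <- .nutrient_matrix_by_child(dairy, compositions, ids, n_days)
  subtypes <- setdiff(.DAIRY_SUBTYPES, "NONE")
  lme_by <- matrix(0, nrow = length(ids), ncol = length(subtypes),
                   dimnames = list(ids, subtypes))
  consumed <- matrix(FALSE, nrow = length(ids), ncol = length(subtypes),
                     dimnames = list(ids, subtypes))
  if (nrow(dairy)) {
    lme <- .lme_of_records(dairy, compositions, ref_milk_protein)
    for (s in subtypes) {
      sel <- dairy_sub == s
      if (any(sel)) {
        agg <- rowsum(lme[sel], group = dairy$child_id[sel])
        lme_by[rownames(agg), s] <- agg[, 1] / n_days
        pos <- rowsum((dairy$amount[sel] > 0) * 1, group = dairy$child_id[sel])
        consumed[rownames(pos), s] <- pos[, 1] > 0
      }
    }
  }
  structure(list(
    children = children,
    intake = diet_only + supp,
    diet_only = diet_only,
    supplement = supp,
    dairy_contribution = contrib,
    lme_total = rowSums(lme_by),
    lme_by_subtype = lme_by,
    consumed = consumed,
    ref_milk_protein = ref_milk_protein,
    n_days = n_days
  ), class = "cohort_intake")
}

#' @export
print.cohort_intake <- function(x, ...) {
  cat("<cohort_intake> ", nrow(x$children), " children; median LME ",
      format(stats::median(x$lme_total), digits = 4), " g/d; ",
      sum(x$lme_total > 0), " dairy consumers\n", sep = "")
  invisible(x)
}

#' Extract one child's intake from a cohort
#'
#' @param cohort A `cohort_intake`.
#' @param child_id Child identifier.
#' @return List mirroring [mean_daily_intake()] output plus the child row.
#' @export
child_intake <- function(cohort, child_id) {
  i <- match(child_id, cohort$children$child_id)
  if (is.na(i)) stop("unknown child_id: ", child_id, call. = FALSE)
  list(
    child = cohort$children[i, ],
    intake = cohort$intake[i, ],
    diet_only = cohort$diet_only[i, ],
    supplement = cohort$supplement[i, ],
    dairy = list(
      child_id = child_id,
      lme_total = cohort$lme_total[[i]],
      lme_by_subtype = cohort$lme_by_subtype[i, ],
      consumed_any_dairy = any(cohort$consumed[i, ]),
      consumed_subtype = cohort$consumed[i, ],
      dairy_contribution = cohort$dairy_contribution[i, ]
    )
  )
}

#' Percent of energy from fat
#'
#' `100 * 9 kcal/g * fat / energy`. Undefined (error) at zero energy.
#'
#' @param v Nutrient vector (per day).
#' @return Percent of energy, numeric.
#' @export
fat_energy_percent <- function(v) {
  if (v[["energy"]] <= 0) stop("fat_energy_percent undefined at zero energy", call. = FALSE)
  100 * 9 * v[["fat"]] / v[["energy"]]
}

#' Fiber density, g per 1000 kcal
#'
#' @param v Nutrient vector (per day).
#' @return `1000 * fiber / energy`. Error at zero energy.
#' @export
fiber_density <- function(v) {
  if (v[["energy"]] <= 0) stop("fiber_density undefined at zero energy", call. = FALSE)
  1000 * v[["fiber"]] / v[["energy"]]
}

# Metric matrix used by rule classification: the intake itself for
# EAR/AI nutrients, or the derived quantity for density/AMDR rules.
.rule_metric <- function(intake_matrix, nutrient) {
  if (nutrient == "fiber_density") {
    e <- intake_matrix[, "energy"]
    if (any(e <= 0)) stop("fiber_density undefined at zero energy", call. = FALSE)
    1000 * intake_matrix[, "fiber"] / e
  } else if (nutrient == "fat_energy_pct") {
    e <- intake_matrix[, "energy"]
    if (any(e <= 0)) stop("fat_energy_percent undefined at zero energy", call. = FALSE)
    100 * 9 * intake_matrix[, "fat"] / e
  } else {
    intake_matrix[, nutrient]
  }
}

#' Classify adequacy of one child's intake
#'
#' Applies every DRI rule covering the child's age. EAR/AI and fiber
#' density flag `INADEQUATE` when the metric is strictly below the
#' threshold; the AMDR upper bound flags `fat_excessive` when fat percent
#' of energy is strictly above it. Equality at the threshold is
#' adequate / non-excessive. Nutrients without a rule for that age emit
#' no flag.
#'
#' @param intake Nutrient vector of mean daily intake.
#' @param age_months Child's age, months.
#' @param dri A `dri_table`.
#' @param require Optional character vector of rule nutrients that must
#'   resolve; a missing rule for any of them is a configuration error.
#' @return Named logical vector (`TRUE` = inadequate, or excessive for
#'   `fat_energy_pct`), one element per rule covering the age.
#' @export
classify_adequacy <- function(intake, age_months, dri, require = NULL) {
  if (!is.null(require)) {
    for (nu in require) {
      if (is.null(dri_lookup(dri, nu, age_months))) {
        stop("no DRI rule for requested nutrient '", nu, "' at age ",
             age_months, " months", call. = FALSE)
      }
    }
  }
  m <- matrix(intake[.NUTRIENTS], nrow = 1, dimnames = list(NULL, .NUTRIENTS))
  out <- logical(0)
  for (nu in unique(dri$nutrient)) {
    rule <- dri_lookup(dri, nu, age_months)
    if (is.null(rule)) next
    metric <- .rule_metric(m, nu)[1]
    flag <- if (rule$rule_type == "AMDR_UPPER") metric > rule$threshold
            else metric < rule$threshold
    out[nu] <- flag
  }
  out
}

#' Classify adequacy across a cohort
#'
#' @param cohort A `cohort_intake`.
#' @param dri A `dri_table`.
#' @return Logical matrix children x rule nutrients; `TRUE` = inadequate
#'   (or excessive for `fat_energy_pct`), `NA` where no rule covers the
#'   child's age.
#' @export
cohort_classify <- function(cohort, dri) {
  ages <- cohort$children$age_months
  nus <- unique(dri$nutrient)
  flags <- matrix(NA, nrow = length(ages), ncol = length(nus),
                  dimnames = list(cohort$children$child_id, nus))
  for (nu in nus) {
    rules <- dri[dri$nutrient == nu, , drop = FALSE]
    metric <- .rule_metric(cohort$intake, nu)
    for (k in seq_len(nrow(rules))) {
      in_band <- ages >= rules$age_min_months[k] & ages < rules$age_max_months[k]
      if (!any(in_band)) next
      flags[in_band, nu] <- if (rules$rule_type[k] == "AMDR_UPPER") {
        metric[in_band] > rules$threshold[k]
      } else {
        metric[in_band] < rules$threshold[k]
      }
    }
  }
  flags
}

#' Cohort inadequacy counts and percentages
#'
#' @param cohort A `cohort_intake`.
#' @param dri A `dri_table`.
#' @return Data frame with one row per rule nutrient: `nutrient`,
#'   `rule_type`, `n_flagged`, `n` (children with an applicable rule) and
#'   `pct` (half-up, 2 dp; see [percent()]).
#' @export
cohort_adequacy <- function(cohort, dri) {
  flags <- cohort_classify(cohort, dri)
  nus <- colnames(flags)
  rule_type <- vapply(nus, function(nu) dri$rule_type[dri$nutrient == nu][1],
                      character(1))
  n <- colSums(!is.na(flags))
  cnt <- colSums(flags, na.rm = TRUE)
  data.frame(
    nutrient = nus,
    rule_type = unname(rule_type),
    n_flagged = unname(cnt),
    n = unname(n),
    pct = vapply(seq_along(nus), function(i) {
      if (n[i] == 0) NA_real_ else percent(cnt[i], n[i])
    }, numeric(1)),
    row.names = NULL
  )
}
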