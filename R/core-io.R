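# Validated readers and writers for the plain-text interchange formats:
# composition CSV, diet-diary CSV, supplement CSV, children CSV and the
# DRI rule configuration (JSON or YAML). All files are UTF-8, decimal
# point, canonical column names; no unit inference.

.read_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                  fileEncoding = "UTF-8")
}

.require_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Load a food composition table
#'
#' Reads a CSV with columns `food_id`, `name`, `dairy_subtype` and the 20
#' canonical nutrient columns, each interpreted per 100 g edible portion
#' as consumed. Unknown subtype strings and negative values are rejected.
#'
#' @param path Path to the composition CSV.
#' @return A `composition_table`: data frame keyed by `food_id` (also the
#'   row names) with one column per nutrient.
#' @export
load_composition_table <- function(path) {
  df <- .read_csv(path)
  as_composition_table(df)
}

#' Coerce a data frame to a composition table
#'
#' @param df Data frame with `food_id`, `name`, `dairy_subtype` and all
#'   canonical nutrient columns.
#' @return A validated `composition_table`.
#' @export
as_composition_table <- function(df) {
  .require_columns(df, c("food_id", "name", "dairy_subtype", .NUTRIENTS),
                   "composition table")
  df$food_id <- as.character(df$food_id)
  df$dairy_subtype <- as.character(df$dairy_subtype)
  if (anyDuplicated(df$food_id)) {
    stop("duplicate food_id in composition table: ",
         paste(unique(df$food_id[duplicated(df$food_id)]), collapse = ", "),
         call. = FALSE)
  }
  bad <- !df$dairy_subtype %in% .DAIRY_SUBTYPES
  if (any(bad)) {
    stop("unknown dairy_subtype value(s): ",
         paste(unique(df$dairy_subtype[bad]), collapse = ", "), call. = FALSE)
  }
  for (nu in .NUTRIENTS) {
    vals <- as.numeric(df[[nu]])
    if (any(!is.finite(vals))) {
      stop("non-numeric value in nutrient column '", nu, "', row ",
           which(!is.finite(vals))[1], call. = FALSE)
    }
    if (any(vals < 0)) {
      stop("negative value in nutrient column '", nu, "', row ",
           which(vals < 0)[1], call. = FALSE)
    }
    df[[nu]] <- vals
  }
  df <- df[, c("food_id", "name", "dairy_subtype", .NUTRIENTS)]
  rownames(df) <- df$food_id
  class(df) <- c("composition_table", "data.frame")
  df
}

#' Write a composition table to CSV
#' @param compositions A `composition_table`.
#' @param path Output path.
#' @export
write_composition_table <- function(compositions, path) {
  utils::write.csv(as.data.frame(compositions), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Look up one food's composition entry
#'
#' @param compositions A `composition_table`.
#' @param food_id Single food identifier.
#' @return One-row list with `food_id`, `name`, `dairy_subtype` and
#'   `per100g` (nutrient vector per 100 g).
#' @export
composition_entry <- function(compositions, food_id) {
  i <- match(food_id, compositions$food_id)
  if (is.na(i)) stop("unknown food_id: ", food_id, call. = FALSE)
  list(
    food_id = compositions$food_id[i],
    name = compositions$name[i],
    dairy_subtype = compositions$dairy_subtype[i],
    per100g = unlist(compositions[i, .NUTRIENTS])
  )
}

#' Load diet diary records
#'
#' Reads a CSV of one row per (child, day, food) with columns `child_id`,
#' `day` (1--4), `day_type` (`working`/`weekend`), `food_id` and
#' `amount` (g edible raw weight; the header `amount_g` is accepted as an
#' alias). A valid diary has exactly four distinct days per child, two
#' working and two weekend; `strict = FALSE` relaxes the completeness
#' check (day range and non-negativity are always enforced).
#'
#' @param path Path to the diary CSV.
#' @param compositions Optional `composition_table`; if given, every
#'   `food_id` must resolve in it.
#' @param strict Require complete 2+2 four-day diaries (default `TRUE`).
#' @return Data frame of records, classed `diet_records`.
#' @export
load_diet_records <- function(path, compositions = NULL, strict = TRUE) {
  df <- .read_csv(path)
  if ("amount_g" %in% names(df) && !"amount" %in% names(df)) {
    names(df)[names(df) == "amount_g"] <- "amount"
  }
  as_diet_records(df, compositions = compositions, strict = strict)
}

#' Coerce a data frame to validated diet records
#' @inheritParams load_diet_records
#' @param df Data frame of raw records.
#' @export
as_diet_records <- function(df, compositions = NULL, strict = TRUE) {
  .require_columns(df, c("child_id", "day", "day_type", "food_id", "amount"),
                   "diet records")
  df <- df[, c("child_id", "day", "day_type", "food_id", "amount")]
  df$child_id <- as.character(df$child_id)
  df$food_id <- as.character(df$food_id)
  df$day <- as.integer(df$day)
  df$amount <- as.numeric(df$amount)
  df$day_type <- tolower(as.character(df$day_type))
  df$day_type[df$day_type %in% c("w", "working-day", "workday")] <- "working"
  df$day_type[df$day_type %in% c("e", "weekend-day")] <- "weekend"
  if (any(!df$day_type %in% c("working", "weekend"))) {
    stop("day_type must be 'working' or 'weekend'", call. = FALSE)
  }
  if (any(is.na(df$day)) || any(df$day < 1L | df$day > 4L)) {
    stop("day must be an integer in 1..4", call. = FALSE)
  }
  if (any(!is.finite(df$amount)) || any(df$amount < 0)) {
    stop("amount must be a non-negative number of grams", call. = FALSE)
  }
  if (!is.null(compositions)) {
    unknown <- setdiff(unique(df$food_id), compositions$food_id)
    if (length(unknown)) {
      stop("diet records reference unknown food_id(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
  }
  if (strict) {
    split_days <- split(df[, c("day", "day_type")], df$child_id)
    for (cid in names(split_days)) {
      g <- unique(split_days[[cid]])
      if (!setequal(g$day, 1:4)) {
        stop("child ", cid, ": diary must cover exactly days 1..4", call. = FALSE)
      }
      tab <- table(g$day_type[order(g$day)])
      if (!identical(sort(names(tab)), c("weekend", "working")) ||
          tab[["working"]] != 2L || tab[["weekend"]] != 2L) {
        stop("child ", cid, ": diary must have 2 working and 2 weekend days",
             call. = FALSE)
      }
    }
  }
  class(df) <- c("diet_records", "data.frame")
  df
}

#' Write diet records to CSV
#' @param records `diet_records` data frame.
#' @param path Output path.
#' @export
write_diet_records <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Load supplement records
#'
#' Reads a CSV with `child_id`, `day` and any subset of the canonical
#' nutrient columns giving the amount delivered by supplements on that
#' day. Missing nutrient columns are treated as zero.
#'
#' @param path Path to the supplements CSV.
#' @return Data frame with `child_id`, `day` and all 20 nutrient columns.
#' @export
load_supplement_records <- function(path) {
  df <- .read_csv(path)
  as_supplement_records(df)
}

#' Coerce a data frame to validated supplement records
#' @param df Data frame with `child_id`, `day` and nutrient columns.
#' @export
as_supplement_records <- function(df) {
  .require_columns(df, c("child_id", "day"), "supplement records")
  df$child_id <- as.character(df$child_id)
  df$day <- as.integer(df$day)
  if (any(is.na(df$day)) || any(df$day < 1L | df$day > 4L)) {
    stop("supplement day must be an integer in 1..4", call. = FALSE)
  }
  extra <- setdiff(names(df), c("child_id", "day", .NUTRIENTS))
  if (length(extra)) {
    stop("unknown column(s) in supplement records: ",
         paste(extra, collapse = ", "), call. = FALSE)
  }
  for (nu in .NUTRIENTS) {
    if (!nu %in% names(df)) df[[nu]] <- 0
    df[[nu]] <- as.numeric(df[[nu]])
    df[[nu]][is.na(df[[nu]])] <- 0
    if (any(df[[nu]] < 0)) stop("negative supplement amount for ", nu, call. = FALSE)
  }
  df <- df[, c("child_id", "day", .NUTRIENTS)]
  class(df) <- c("supplement_records", "data.frame")
  df
}

#' Load a children roster
#'
#' @param path CSV with columns `child_id` and `age_months` (37--72).
#' @return Data frame with `child_id`, `age_months`, `age_group`.
#' @export
load_children <- function(path) {
  df <- .read_csv(path)
  as_children(df)
}

#' Coerce a data frame to a validated children roster
#' @param df Data frame with `child_id`, `age_months`.
#' @export
as_children <- function(df) {
  .require_columns(df, c("child_id", "age_months"), "children roster")
  df$child_id <- as.character(df$child_id)
  if (anyDuplicated(df$child_id)) stop("duplicate child_id in roster", call. = FALSE)
  df$age_months <- as.integer(df$age_months)
  df$age_group <- age_group_of(df$age_months)
  df <- df[, c("child_id", "age_months", "age_group")]
  class(df) <- c("children_roster", "data.frame")
  df
}

# ---- DRI rule configuration -------------------------------------------

#' Load a dietary reference intake (DRI) rule table
#'
#' Reads a JSON or YAML list of rules, each with fields `nutrient`
#' (a canonical nutrient, `fiber_density`, or `fat_energy_pct`),
#' `age_min_months` / `age_max_months` (half-open band `[min, max)`),
#' `rule_type` (`EAR`, `AI`, `FIBER_DENSITY`, `AMDR_UPPER`) and a positive
#' `threshold` in the nutrient's unit (g/1000 kcal for fiber density,
#' percent of energy for the fat upper bound). Age bands for a nutrient
#' must not overlap.
#'
#' @param path Path to a `.json`, `.yaml` or `.yml` file.
#' @return A `dri_table` data frame of rules.
#' @export
load_dri_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  rules <- switch(ext,
    json = jsonlite::fromJSON(path, simplifyDataFrame = TRUE),
    yaml = ,
    yml = {
      lst <- yaml::read_yaml(path)
      do.call(rbind, lapply(lst, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
    },
    stop("DRI configuration must be .json, .yaml or .yml", call. = FALSE)
  )
  as_dri_table(rules)
}

#' Coerce a data frame of rules to a validated DRI table
#' @param rules Data frame with columns `nutrient`, `age_min_months`,
#'   `age_max_months`, `rule_type`, `threshold`.
#' @export
as_dri_table <- function(rules) {
  .require_columns(rules, c("nutrient", "age_min_months", "age_max_months",
                            "rule_type", "threshold"), "DRI table")
  rules$nutrient <- as.character(rules$nutrient)
  rules$rule_type <- as.character(rules$rule_type)
  rules$age_min_months <- as.numeric(rules$age_min_months)
  rules$age_max_months <- as.numeric(rules$age_max_months)
  rules$threshold <- as.numeric(rules$threshold)
  known <- c(.NUTRIENTS, .DERIVED_QUANTITIES)
  bad <- setdiff(unique(rules$nutrient), known)
  if (length(bad)) {
    stop("unknown nutrient name(s) in DRI table: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  bad_rt <- setdiff(unique(rules$rule_type), .RULE_TYPES)
  if (length(bad_rt)) {
    stop("unknown rule_type(s) in DRI table: ",
         paste(bad_rt, collapse = ", "), call. = FALSE)
  }
  if (any(rules$threshold <= 0) || any(!is.finite(rules$threshold))) {
    stop("DRI thresholds must be positive numbers", call. = FALSE)
  }
  if (any(rules$age_min_months >= rules$age_max_months)) {
    stop("DRI age bands must satisfy min < max", call. = FALSE)
  }
  # non-overlap of half-open bands per nutrient
  for (nu in unique(rules$nutrient)) {
    r <- rules[rules$nutrient == nu, , drop = FALSE]
    r <- r[order(r$age_min_months), , drop = FALSE]
    if (nrow(r) > 1L &&
        any(r$age_min_months[-1L] < r$age_max_months[-nrow(r)])) {
      stop("overlapping age bands in DRI table for nutrient '", nu, "'",
           call. = FALSE)
    }
  }
  rules <- rules[, c("nutrient", "age_min_months", "age_max_months",
                     "rule_type", "threshold")]
  class(rules) <- c("dri_table", "data.frame")
  rules
}

#' Look up the DRI rule for one nutrient at one age
#'
#' @param dri A `dri_table`.
#' @param nutrient Rule nutrient name.
#' @param age_months Age in months.
#' @return One-row data frame (the unique matching rule), or `NULL` if no
#'   rule covers that age.
#' @export
dri_lookup <- function(dri, nutrient, age_months) {
  r <- dri[dri$nutrient == nutrient &
             dri$age_min_months <= age_months &
             dri$age_max_months > age_months, , drop = FALSE]
  if (nrow(r) == 0L) return(NULL)
  if (nrow(r) > 1L) stop("DRI table resolves ambiguously for ", nutrient, call. = FALSE)
  r
}

#' Path to a bundled default configuration file
#'
#' Convenience accessor for the editable defaults shipped under
#' `inst/extdata`: `"dri"` (2013 Chinese DRI-style rule placeholders,
#' user-verify), `"substitutes"` (synthetic substitute compositions) and
#' `"scenarios"` (the five standard scenario models).
#'
#' @param which One of `"dri"`, `"substitutes"`, `"scenarios"`.
#' @return File path.
#' @export
dairysim_extdata <- function(which = c("dri", "substitutes", "scenarios")) {
  which <- match.arg(which)
  fn <- switch(which,
    dri = "dri_chinese2013_default.json",
    substitutes = "substitutes_synthetic.csv",
    scenarios = "scenarios_default.json"
  )
  system.file("extdata", fn, package = "dairysim", mustWork = TRUE)
}
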