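#' Convert a raw three-plant tuber weight to an areal density
#'
#' Field sampling weighs the tubers of three adjacent plants. The weight is
#' converted to grams per square metre from the in-row planting distance,
#' using the printed conversion constant 1.333 (100 divided by a 75 cm row
#' width):
#' \deqn{y \,(\mathrm{g\,m^{-2}}) = \tilde y \,(\mathrm{g/3\,plants}) \times
#'   \frac{1.333}{\mathrm{planting\ distance\ (cm)} \times 3 / 100}}
#'
#' @param raw_weight_g Numeric vector, tuber weight of three plants in grams.
#' @param planting_distance_cm Numeric vector, in-row distance between plants
#'   in centimetres. Recycled against `raw_weight_g`.
#' @return Numeric vector of tuber weights in g m^-2.
#' @examples
#' tuber_weight_per_m2(675, 30)
#' @export
tuber_weight_per_m2 <- function(raw_weight_g, planting_distance_cm) {
  if (any(!is.finite(planting_distance_cm) | planting_distance_cm <= 0)) {
    rlang::abort("`planting_distance_cm` must be positive and finite.")
  }
  if (any(raw_weight_g < 0, na.rm = TRUE)) {
    rlang::abort("`raw_weight_g` must be non-negative.")
  }
  raw_weight_g * 1.333 / (planting_distance_cm * 3 / 100)
}

#' Standardize sampling days by their pooled standard deviation
#'
#' Days after planting are divided by one global sample standard deviation
#' (n-1 denominator) pooled over all observations, so that the steepness and
#' midpoint parameters of the growth model are estimated on a numerically
#' well-scaled time axis. The scale is returned so fitted curves can be
#' reported back in days.
#'
#' @param observations A data frame with a `days_after_planting` column.
#' @return A list with `observations` (the input plus a `day_std` column) and
#'   `time_scale` (the pooled standard deviation in days).
#' @export
standardize_times <- function(observations) {
  days <- observations$days_after_planting
  if (length(unique(days)) < 2) {
    rlang::abort("All sampling days are identical; time scale is degenerate.")
  }
  s <- stats::sd(days)
  list(
    observations = dplyr::mutate(observations, day_std = days / s),
    time_scale = s
  )
}

soil_numeric_cols <- c(
  "N_soil", "P_soil", "K_soil", "Ca_soil", "Mg_soil", "S_soil",
  "Si_soil", "B_soil", "Fe_soil", "Mn_soil", "Zn_soil"
)
soil_categorical_cols <- c(
  "Dryness", "Nutrient_content", "Previous_crop", "Nematodes"
)

#' Assemble a joined growth dataset
#'
#' Combines a longitudinal growth table (one row per plant-sample event) and
#' a field-descriptor table (one row per field-year) into a single validated
#' dataset. Raw three-plant weights are converted to g m^-2 when needed,
#' sampling days are standardized, zero weights (destroyed fields) are set
#' aside from the likelihood-ready observations but logged, and observations
#' without a matching field record are collected in a rejects report rather
#' than silently dropped.
#'
#' @param growth Data frame with columns `field_id`, `year`,
#'   `days_after_planting` and either `weight_g_m2` or `weight_g_3plants`
#'   plus `planting_distance_cm`.
#' @param fields Data frame with columns `field_id`, `year`, soil descriptors
#'   (`N_soil` ... `Zn_soil`, `Dryness`, `Nutrient_content`, `Previous_crop`,
#'   `Nematodes`), `yield_ton_ha`, `irrigated`, `planting_date`.
#' @param descriptors Character vector of descriptor columns to mine over;
#'   defaults to the soil and management descriptor columns present in
#'   `fields`.
#' @return An object of class `egm_data`: a list with tibbles `records` and
#'   `observations`, the `time_scale` in days, the mined `descriptors`, and
#'   the `excluded_zero` and `rejects` reports.
#' @export
egm_data <- function(growth, fields, descriptors = NULL) {
  growth <- tibble::as_tibble(growth)
  fields <- tibble::as_tibble(fields)
  need_g <- c("field_id", "year", "days_after_planting")
  missing_g <- setdiff(need_g, names(growth))
  if (length(missing_g)) {
    rlang::abort(paste0("`growth` lacks columns: ", paste(missing_g, collapse = ", ")))
  }
  missing_f <- setdiff(c("field_id", "year"), names(fields))
  if (length(missing_f)) {
    rlang::abort(paste0("`fields` lacks columns: ", paste(missing_f, collapse = ", ")))
  }
  if (anyDuplicated(fields[c("field_id", "year")])) {
    rlang::abort("`fields` must have exactly one row per (field_id, year).")
  }

  if (!"weight_g_m2" %in% names(growth)) {
    if (!all(c("weight_g_3plants", "planting_distance_cm") %in% names(growth))) {
      rlang::abort(paste(
        "`growth` needs either `weight_g_m2` or",
        "`weight_g_3plants` with `planting_distance_cm`."
      ))
    }
    growth$weight_g_m2 <- tuber_weight_per_m2(
      growth$weight_g_3plants, growth$planting_distance_cm
    )
  }
  if (any(growth$days_after_planting < 0, na.rm = TRUE)) {
    rlang::abort("`days_after_planting` must be non-negative.")
  }
  if (any(growth$weight_g_m2 < 0, na.rm = TRUE)) {
    rlang::abort("weights must be non-negative.")
  }

  key_known <- paste(fields$field_id, fields$year)
  key_obs <- paste(growth$field_id, growth$year)
  rejects <- growth[!(key_obs %in% key_known), , drop = FALSE]
  matched <- growth[key_obs %in% key_known, , drop = FALSE]

  zero <- matched$weight_g_m2 == 0 | !is.finite(matched$weight_g_m2)
  excluded_zero <- matched[zero, , drop = FALSE]
  obs <- matched[!zero, , drop = FALSE]
  obs <- dplyr::select(
    obs, "field_id", "year", "days_after_planting", "weight_g_m2"
  )
  std <- standardize_times(obs)

  if (is.null(descriptors)) {
    descriptors <- intersect(c(soil_numeric_cols, soil_categorical_cols), names(fields))
  } else {
    bad <- setdiff(descriptors, names(fields))
    if (length(bad)) {
      rlang::abort(paste0("Unknown descriptor columns: ", paste(bad, collapse = ", ")))
    }
  }

  structure(
    list(
      records = fields,
      observations = std$observations,
      time_scale = std$time_scale,
      descriptors = descriptors,
      excluded_zero = tibble::as_tibble(excluded_zero),
      rejects = tibble::as_tibble(rejects)
    ),
    class = "egm_data"
  )
}

#' Read a growth dataset from CSV files
#'
#' Reads the two comma-separated tables (header row, `.` decimal, empty or
#' `NA` for missing) and assembles them with [egm_data()].
#'
#' @param growth_csv Path to the longitudinal growth CSV.
#' @param fields_csv Path to the field-descriptor CSV.
#' @inheritParams egm_data
#' @return An `egm_data` object.
#' @export
load_dataset <- function(growth_csv, fields_csv, descriptors = NULL) {
  growth <- readr::read_csv(growth_csv, show_col_types = FALSE, na = c("", "NA"))
  fields <- readr::read_csv(fields_csv, show_col_types = FALSE, na = c("", "NA"))
  if ("planting_date" %in% names(fields) && !inherits(fields$planting_date, "Date")) {
    fields$planting_date <- as.Date(fields$planting_date)
  }
  if ("irrigated" %in% names(fields) && !is.logical(fields$irrigated)) {
    fields$irrigated <- as.logical(fields$irrigated)
  }
  egm_data(growth, fields, descriptors = descriptors)
}

#' @export
print.egm_data <- function(x, ...) {
  cat("<egm_data>\n")
  cat("  fields:       ", nrow(x$records), "\n", sep = "")
  cat("  observations: ", nrow(x$observations),
      " (time scale ", signif(x$time_scale, 4), " days)\n", sep = "")
  cat("  descriptors:  ", length(x$descriptors), "\n", sep = "")
  if (nrow(x$excluded_zero)) {
    cat("  excluded zero-weight rows: ", nrow(x$excluded_zero), "\n", sep = "")
  }
  if (nrow(x$rejects)) {
    cat("  rejected rows (no matching field record): ", nrow(x$rejects), "\n", sep = "")
  }
  invisible(x)
}
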