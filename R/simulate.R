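#' Configuration for the synthetic farm generator
#'
#' Describes a farm-like study: years, fields per year, a sampling design of
#' 5-7 non-equidistant visits per field, true growth-model parameters on the
#' day scale, descriptor distributions, and optional planted subgroups
#' (descriptor-linked shifts of a random-effect mean).
#'
#' @param years Character vector of year labels.
#' @param n_fields_per_year Integer, fields per year (recycled over years).
#' @param obs_per_field Length-2 integer range of sampling visits per field.
#' @param day_range Length-2 range of days after planting that visits fall in.
#' @param alpha Named per-year log asymptote (log g m^-2).
#' @param beta_day Named per-year log steepness, per day.
#' @param gamma_day Named per-year midpoint, days after planting.
#' @param sigma_a,sigma_b Random-effect scales for log asymptote and log
#'   steepness (unitless).
#' @param sigma_c_day Random-effect scale of the midpoint, in days.
#' @param rho Correlations (ab, ac, bc) of the standardized random effects.
#' @param sigma_e Lognormal measurement-error scale (log scale).
#' @param yield_base Named per-year mean yield, ton ha^-1.
#' @param yield_slope Increase in yield per unit of the `a` random effect.
#' @param yield_sd Residual yield standard deviation.
#' @param numeric_descriptors Named list: for each numeric soil descriptor a
#'   `c(meanlog, sdlog)` pair of its lognormal distribution.
#' @param categorical_descriptors Named list of named probability vectors.
#' @param prop_irrigated Probability that a field can be irrigated.
#' @param planting_window Number of days the planting period spans per year.
#' @param planted_effects List of [planted_effect()] entries.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(years, n_fields_per_year, obs_per_field = c(5, 7),
                       day_range = c(25, 145),
                       alpha, beta_day, gamma_day,
                       sigma_a = 0.35, sigma_b = 0.25, sigma_c_day = 8,
                       rho = c(-0.65, 0.49, -0.73), sigma_e = 0.15,
                       yield_base, yield_slope = 10, yield_sd = 6,
                       numeric_descriptors = default_numeric_descriptors(),
                       categorical_descriptors = default_categorical_descriptors(),
                       prop_irrigated = 0.4, planting_window = 45,
                       planted_effects = list(), seed = 1) {
  R <- rho_matrix(rho)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) <= 1e-10) {
    rlang::abort("`rho` does not give a positive-definite correlation matrix.")
  }
  for (pe in planted_effects) {
    known <- c(names(numeric_descriptors), names(categorical_descriptors))
    if (!pe$attribute %in% known) {
      rlang::abort(paste0("planted effect references unknown descriptor: ",
                          pe$attribute))
    }
  }
  structure(
    list(
      years = as.character(years),
      n_fields_per_year = rep_len(n_fields_per_year, length(years)),
      obs_per_field = obs_per_field, day_range = day_range,
      alpha = alpha, beta_day = beta_day, gamma_day = gamma_day,
      sigma_a = sigma_a, sigma_b = sigma_b, sigma_c_day = sigma_c_day,
      rho = rho, sigma_e = sigma_e,
      yield_base = yield_base, yield_slope = yield_slope, yield_sd = yield_sd,
      numeric_descriptors = numeric_descriptors,
      categorical_descriptors = categorical_descriptors,
      prop_irrigated = prop_irrigated, planting_window = planting_window,
      planted_effects = planted_effects, seed = seed
    ),
    class = "sim_config"
  )
}

#' Declare a planted subgroup effect
#'
#' A descriptor-linked shift: fields satisfying the condition have `delta`
#' added to the mean of one random-effect component. Numeric conditions are
#' stated as a quantile (`prob`) of the generated descriptor with direction
#' `kind` (`"gt"` above / `"le"` at-or-below the quantile); categorical
#' conditions match a level.
#'
#' @param attribute Descriptor name.
#' @param component One of `"a"`, `"b"`, `"c"`.
#' @param delta Shift added to the component's mean for satisfying fields.
#' @param prob Quantile probability for numeric conditions (e.g. 0.75 with
#'   `kind = "gt"` plants the shift on the top quarter).
#' @param value Category label for categorical conditions.
#' @param kind `"gt"`, `"le"`, or `"eq"`.
#' @return A `planted_effect` list.
#' @export
planted_effect <- function(attribute, component, delta, prob = NULL,
                           value = NULL, kind = c("gt", "le", "eq")) {
  kind <- match.arg(kind)
  if (kind == "eq" && is.null(value)) rlang::abort("`eq` needs `value`.")
  if (kind != "eq" && is.null(prob)) rlang::abort("numeric kinds need `prob`.")
  list(attribute = attribute, component = match(component, c("a", "b", "c")),
       delta = delta, prob = prob, value = value, kind = kind)
}

default_numeric_descriptors <- function() {
  list(
    N_soil = c(log(120), 0.45), P_soil = c(log(6), 0.5),
    K_soil = c(log(210), 0.45), Ca_soil = c(log(150), 0.6),
    Mg_soil = c(log(180), 0.4), S_soil = c(log(16), 0.45),
    Si_soil = c(log(100), 0.5), B_soil = c(log(700), 0.5),
    Fe_soil = c(log(380), 0.35), Mn_soil = c(log(4000), 0.7),
    Zn_soil = c(log(3800), 0.6)
  )
}

default_categorical_descriptors <- function() {
  list(
    Dryness = c(dry = 0.25, average = 0.5, wet = 0.25),
    Nutrient_content = c(poor = 0.3, average = 0.5, rich = 0.2),
    Previous_crop = c(maize = 0.3, barley = 0.2, grass = 0.2,
                      beets = 0.15, other = 0.15),
    Nematodes = c(no = 0.8, yes = 0.2)
  )
}

#' Default farm-scale simulation settings
#'
#' Four years of roughly 90 fields each (360 in total), asymptotes spanning
#' about 3000-8000 g m^-2, random-effect correlations (-0.65, 0.49, -0.73)
#' (strong negative between asymptote and steepness and between steepness
#' and midpoint, weak positive between asymptote and midpoint),
#' per-year mean yields between 38 and 63.5 ton ha^-1, lognormal soil
#' nutrient distributions, and a lognormal measurement error of 0.15 on the
#' log scale.
#'
#' @param seed Integer seed.
#' @return A `sim_config`.
#' @export
default_farm_config <- function(seed = 1) {
  yrs <- c("2015", "2016", "2017", "2018")
  sim_config(
    years = yrs, n_fields_per_year = 90,
    alpha = stats::setNames(log(c(6000, 3300, 5200, 3600)), yrs),
    beta_day = stats::setNames(log(c(0.080, 0.092, 0.083, 0.090)), yrs),
    gamma_day = stats::setNames(c(78, 84, 80, 86), yrs),
    yield_base = stats::setNames(c(63.5, 40.1, 54.0, 38.0), yrs),
    seed = seed
  )
}

#' Simulate a farm-like growth dataset
#'
#' Draws correlated standardized random effects per field, applies any
#' planted descriptor-linked shifts, builds field-specific logistic curves,
#' and samples each field 5-7 times with multiplicative lognormal error.
#' Ground truth is always returned alongside the data.
#'
#' @param config A [sim_config].
#' @return A list with `data` (an [egm_data]), `truth` (tibble of realized
#'   random effects per field, after planted shifts), and `config`.
#' @export
simulate_farm <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  yrs <- config$years
  n_per <- config$n_fields_per_year
  n <- sum(n_per)
  year <- rep(yrs, n_per)
  field_id <- sprintf("F%s_%03d", year, unlist(lapply(n_per, seq_len)))

  # descriptors
  rec <- tibble::tibble(field_id = field_id, year = year)
  for (nm in names(config$numeric_descriptors)) {
    p <- config$numeric_descriptors[[nm]]
    rec[[nm]] <- round(stats::rlnorm(n, p[1], p[2]), 1)
  }
  for (nm in names(config$categorical_descriptors)) {
    p <- config$categorical_descriptors[[nm]]
    rec[[nm]] <- sample(names(p), n, replace = TRUE, prob = p)
  }

  # standardized random effects with the configured correlations
  C <- chol(rho_matrix(config$rho))
  U <- matrix(stats::rnorm(3 * n), n, 3) %*% C
  for (pe in config$planted_effects) {
    sat <- switch(pe$kind,
      gt = rec[[pe$attribute]] > stats::quantile(rec[[pe$attribute]], pe$prob),
      le = rec[[pe$attribute]] <= stats::quantile(rec[[pe$attribute]], pe$prob),
      eq = rec[[pe$attribute]] == pe$value
    )
    U[sat, pe$component] <- U[sat, pe$component] + pe$delta
  }

  # field curves on the day scale
  a_f <- config$alpha[year] + config$sigma_a * U[, 1]
  b_f <- exp(config$beta_day[year] + config$sigma_b * U[, 2])
  c_f <- config$gamma_day[year] + config$sigma_c_day * U[, 3]

  m <- sample(seq(config$obs_per_field[1], config$obs_per_field[2]),
              n, replace = TRUE)
  pool <- seq(config$day_range[1], config$day_range[2])
  growth <- purrr::map_dfr(seq_len(n), function(i) {
    days <- sort(sample(pool, m[i]))
    mu <- logistic_mean(a_f[i], b_f[i], c_f[i], days)
    tibble::tibble(
      field_id = field_id[i], year = year[i],
      days_after_planting = days,
      weight_g_m2 = mu * exp(stats::rnorm(m[i], 0, config$sigma_e))
    )
  })

  rec$yield_ton_ha <- round(pmax(
    config$yield_base[year] + config$yield_slope * U[, 1] +
      stats::rnorm(n, 0, config$yield_sd), 5
  ), 1)
  rec$irrigated <- stats::runif(n) < config$prop_irrigated
  rec$planting_date <- as.Date(paste0(year, "-04-01")) +
    sample.int(config$planting_window, n, replace = TRUE) - 1L

  truth <- tibble::tibble(
    field_id = field_id, year = year,
    a = U[, 1], b = U[, 2], c = U[, 3]
  )
  list(data = egm_data(growth, rec), truth = truth, config = config)
}
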