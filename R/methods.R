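#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom generics augment
#' @export
generics::augment

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted growth model
#'
#' One row per parameter. With `scale = "days"` the steepness, midpoint, and
#' midpoint-scale parameters are converted from standardized time back to
#' days after planting using the dataset's time scale.
#'
#' @param x An `egm_fit` object.
#' @param scale `"standardized"` (as fitted) or `"days"`.
#' @param ... Unused.
#' @return A tibble with columns `term`, `type`, `estimate`.
#' @export
tidy.egm_fit <- function(x, scale = c("standardized", "days"), ...) {
  scale <- match.arg(scale)
  p <- x$params
  s <- x$time_scale
  beta <- p$beta
  gamma <- p$gamma
  sigma_c <- p$sigma_c
  if (scale == "days") {
    beta <- beta - log(s)   # steepness per day
    gamma <- gamma * s      # midpoint in days
    sigma_c <- sigma_c * s
  }
  dplyr::bind_rows(
    tibble::tibble(term = paste0("alpha_", p$years), type = "fixed",
                   estimate = unname(p$alpha)),
    tibble::tibble(term = paste0("beta_", p$years), type = "fixed",
                   estimate = unname(beta)),
    tibble::tibble(term = paste0("gamma_", p$years), type = "fixed",
                   estimate = unname(gamma)),
    tibble::tibble(
      term = c("sigma_a", "sigma_b", "sigma_c"), type = "scale",
      estimate = c(p$sigma_a, p$sigma_b, sigma_c)
    ),
    tibble::tibble(
      term = c("rho_ab", "rho_ac", "rho_bc"), type = "correlation",
      estimate = unname(p$rho)
    ),
    tibble::tibble(term = "sigma_e", type = "scale", estimate = p$sigma_e)
  )
}

#' Glance at a fitted growth model
#'
#' @param x An `egm_fit` object.
#' @param ... Unused.
#' @return A one-row tibble with `logLik`, `r.squared`, `n_fields`, `n_obs`,
#'   `n_quadrature`, and `converged`.
#' @export
glance.egm_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    r.squared = x$r_squared,
    n_fields = x$n_fields,
    n_obs = x$n_obs,
    n_quadrature = x$n_quadrature,
    converged = x$converged
  )
}

#' Augment growth observations with fitted values
#'
#' @param x An `egm_fit` object.
#' @param data The [egm_data] the model was fitted to.
#' @param ... Unused.
#' @return The observation tibble plus `.fitted` (predicted weight, g m^-2)
#'   and `.resid` (observed minus fitted).
#' @export
augment.egm_fit <- function(x, data, ...) {
  obs <- data$observations
  obs$.fitted <- predict_obs(x, data)
  obs$.resid <- obs$weight_g_m2 - obs$.fitted
  obs
}

#' Plot fitted growth curves against observations
#'
#' Draws the observed weights and the field-specific empirical-Bayes curves
#' for a sample of fields, faceted by field.
#'
#' @param object An `egm_fit` object.
#' @param data The [egm_data] the model was fitted to.
#' @param fields Number of fields to display (default 9), or a character
#'   vector of field ids.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.egm_fit <- function(object, data, fields = 9, ...) {
  eb <- object$eb
  ids <- if (is.character(fields)) fields else
    eb$field_id[seq_len(min(fields, nrow(eb)))]
  eb <- eb[eb$field_id %in% ids, ]
  p <- object$params
  grid <- tidyr::crossing(
    eb,
    day = seq(min(data$observations$days_after_planting),
              max(data$observations$days_after_planting), length.out = 80)
  )
  yr <- as.character(grid$year)
  grid$weight <- logistic_mean(
    p$alpha[yr] + p$sigma_a * grid$a,
    exp(p$beta[yr] + p$sigma_b * grid$b),
    p$gamma[yr] + p$sigma_c * grid$c,
    grid$day / object$time_scale
  )
  obs <- data$observations[data$observations$field_id %in% ids, ]
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$day, y = .data$weight)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(
      data = obs,
      ggplot2::aes(x = .data$days_after_planting, y = .data$weight_g_m2),
      size = 1
    ) +
    ggplot2::facet_wrap(~field_id) +
    ggplot2::labs(x = "days after planting", y = expression(tuber~weight~(g~m^-2)))
}

#' @importFrom rlang .data
NULL
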