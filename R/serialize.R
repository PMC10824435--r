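#' Write a fitted growth model to versioned JSON
#'
#' Stores the population parameters, empirical-Bayes effects, time scale,
#' and fit metadata in a stable JSON schema (`format_version` "1.0") so a
#' fit can be reused for mining without re-estimation.
#'
#' @param fit An `egm_fit` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
egm_write_model <- function(fit, path) {
  p <- fit$params
  obj <- list(
    format_version = "1.0",
    params = list(
      years = p$years,
      alpha = as.list(p$alpha), beta = as.list(p$beta),
      gamma = as.list(p$gamma),
      sigma_a = p$sigma_a, sigma_b = p$sigma_b, sigma_c = p$sigma_c,
      rho = as.list(p$rho), sigma_e = p$sigma_e
    ),
    loglik = fit$loglik,
    converged = fit$converged,
    n_quadrature = fit$n_quadrature,
    time_scale = fit$time_scale,
    r_squared = fit$r_squared,
    n_fields = fit$n_fields,
    n_obs = fit$n_obs,
    eb = fit$eb
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a fitted growth model from JSON
#'
#' @param path Path written by [egm_write_model()].
#' @return An `egm_fit` object (without the original data).
#' @export
egm_read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format_version, "1.0")) {
    rlang::abort("unsupported model file version.")
  }
  pr <- obj$params
  params <- egm_params(
    alpha = unlist(pr$alpha), beta = unlist(pr$beta),
    gamma = unlist(pr$gamma),
    sigma_a = pr$sigma_a, sigma_b = pr$sigma_b, sigma_c = pr$sigma_c,
    rho = unlist(pr$rho), sigma_e = pr$sigma_e
  )
  structure(
    list(
      params = params, loglik = obj$loglik, converged = obj$converged,
      n_quadrature = obj$n_quadrature,
      eb = tibble::as_tibble(obj$eb),
      time_scale = obj$time_scale, r_squared = obj$r_squared,
      n_fields = obj$n_fields, n_obs = obj$n_obs
    ),
    class = "egm_fit"
  )
}
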