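#' Growth-model parameters
#'
#' Container for the population parameters of the year-stratified logistic
#' growth model. For field i in year k the curve is
#' \deqn{E[y \mid a,b,c] = \frac{\exp(a_{ik})}{1 + \exp\{-b_{ik}(t - c_{ik})\}}}
#' with
#' \deqn{a_{ik} = \alpha_{0k} + \sigma_a a_i,\quad
#'       b_{ik} = \exp(\beta_{0k} + \sigma_b b_i),\quad
#'       c_{ik} = \gamma_{0k} + \sigma_c c_i,}
#' where \eqn{(a_i, b_i, c_i)} are multivariate standard normal with
#' correlations `rho` and the measurement error is multiplicative lognormal
#' with log-scale standard deviation `sigma_e`. Time `t` is measured in
#' standardized days (days after planting divided by their pooled standard
#' deviation). The midpoint scale \eqn{\sigma_c} is kept positive by
#' construction (it is the exponential of an unconstrained parameter during
#' optimization).
#'
#' @param alpha,beta,gamma Named numeric vectors (one entry per year):
#'   year-specific log asymptote, log steepness (per standardized day), and
#'   midpoint (standardized days).
#' @param sigma_a,sigma_b,sigma_c Non-negative random-effect scales.
#' @param rho Length-3 numeric in (-1, 1): correlations (ab, ac, bc). The
#'   implied 3x3 correlation matrix must be positive definite.
#' @param sigma_e Positive residual standard deviation on the log scale.
#' @return An object of class `egm_params`.
#' @export
egm_params <- function(alpha, beta, gamma, sigma_a, sigma_b, sigma_c,
                       rho = c(0, 0, 0), sigma_e = 0.15) {
  years <- names(alpha)
  if (is.null(years) || !identical(years, names(beta)) ||
      !identical(years, names(gamma))) {
    rlang::abort("`alpha`, `beta`, `gamma` must share the same year names.")
  }
  if (any(c(sigma_a, sigma_b, sigma_c) < 0)) {
    rlang::abort("random-effect scales must be non-negative.")
  }
  if (sigma_e <= 0) rlang::abort("`sigma_e` must be positive.")
  R <- rho_matrix(rho)
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    rlang::abort("correlation matrix implied by `rho` is not positive definite.")
  }
  structure(
    list(
      years = years, alpha = alpha, beta = beta, gamma = gamma,
      sigma_a = sigma_a, sigma_b = sigma_b, sigma_c = sigma_c,
      rho = stats::setNames(as.numeric(rho), c("ab", "ac", "bc")),
      sigma_e = sigma_e
    ),
    class = "egm_params"
  )
}

#' @export
print.egm_params <- function(x, ...) {
  cat("<egm_params> years:", paste(x$years, collapse = ", "), "\n")
  fe <- rbind(alpha = x$alpha, beta = x$beta, gamma = x$gamma)
  print(round(fe, 4))
  cat(sprintf(
    "scales: sigma_a %.4f  sigma_b %.4f  sigma_c %.4f  sigma_e %.4f\n",
    x$sigma_a, x$sigma_b, x$sigma_c, x$sigma_e
  ))
  cat(sprintf(
    "correlations: ab %+.3f  ac %+.3f  bc %+.3f\n",
    x$rho[1], x$rho[2], x$rho[3]
  ))
  invisible(x)
}

# 3x3 unit-diagonal correlation matrix from (ab, ac, bc)
rho_matrix <- function(rho) {
  matrix(c(
    1, rho[1], rho[2],
    rho[1], 1, rho[3],
    rho[2], rho[3], 1
  ), 3, 3)
}

# Spherical (Cholesky-angle) parameterization of the correlation matrix:
# unconstrained x -> angles in (0, pi) -> lower Cholesky factor rows of unit
# norm. Guarantees positive definiteness for any real x.
angles_to_rho <- function(x) {
  th <- pi * stats::plogis(x)
  r12 <- cos(th[1])
  r13 <- cos(th[2])
  r23 <- cos(th[1]) * cos(th[2]) + sin(th[1]) * sin(th[2]) * cos(th[3])
  c(r12, r13, r23)
}

rho_to_angles <- function(rho) {
  t1 <- acos(min(1 - 1e-12, max(-1 + 1e-12, rho[1])))
  t2 <- acos(min(1 - 1e-12, max(-1 + 1e-12, rho[2])))
  c3 <- (rho[3] - cos(t1) * cos(t2)) / (sin(t1) * sin(t2))
  t3 <- acos(min(1 - 1e-12, max(-1 + 1e-12, c3)))
  stats::qlogis(pmin(1 - 1e-9, pmax(1e-9, c(t1, t2, t3) / pi)))
}

# Pack/unpack the optimizer vector:
# (alpha_k, beta_k, gamma_k, log sigma_a, log sigma_b, log sigma_c,
#  3 correlation angles, log sigma_e)
pack_params <- function(p) {
  c(
    p$alpha, p$beta, p$gamma,
    log(pmax(p$sigma_a, 1e-6)), log(pmax(p$sigma_b, 1e-6)),
    log(pmax(p$sigma_c, 1e-6)),
    rho_to_angles(p$rho), log(p$sigma_e)
  )
}

unpack_params <- function(theta, years) {
  K <- length(years)
  alpha <- stats::setNames(theta[seq_len(K)], years)
  beta <- stats::setNames(theta[K + seq_len(K)], years)
  gamma <- stats::setNames(theta[2 * K + seq_len(K)], years)
  rest <- unname(theta[(3 * K + 1):length(theta)])
  list(
    years = years, alpha = alpha, beta = beta, gamma = gamma,
    sigma_a = exp(rest[1]), sigma_b = exp(rest[2]), sigma_c = exp(rest[3]),
    rho = angles_to_rho(rest[4:6]), sigma_e = exp(rest[7])
  )
}
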