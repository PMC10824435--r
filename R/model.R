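#' Logistic growth-curve mean
#'
#' Expected weight at time `t` for a field with curve parameters
#' (log asymptote `a`, steepness `b`, midpoint `c`):
#' \eqn{\exp(a) / (1 + \exp\{-b (t - c)\})}. Evaluated in the log domain so
#' large asymptotes and extreme times do not overflow.
#'
#' @param a Log asymptote (log g m^-2).
#' @param b Steepness (> 0), per unit of `t`.
#' @param c Midpoint on the scale of `t`.
#' @param t Time (standardized days in the fitted model, but any consistent
#'   unit works).
#' @return Expected weight in g m^-2; increasing in `t`, bounded by `exp(a)`,
#'   equal to `exp(a)/2` at `t = c`.
#' @export
logistic_mean <- function(a, b, c, t) {
  if (any(b <= 0)) rlang::abort("steepness `b` must be positive.")
  exp(a - softplus(-b * (t - c)))
}

# numerically stable log(1 + exp(x))
softplus <- function(x) pmax(x, 0) + log1p(exp(-abs(x)))

#' Field-level curve parameters from population parameters and random effects
#'
#' Maps a field's standardized random effects onto its curve:
#' `a = alpha_0k + sigma_a * re_a`, `b = exp(beta_0k + sigma_b * re_b)`,
#' `c = gamma_0k + sigma_c * re_c`.
#'
#' @param params An [egm_params] object.
#' @param year Year label (must be one of the fitted years).
#' @param re Numeric length-3 vector `(a, b, c)` of standardized random
#'   effects.
#' @return A tibble with columns `a`, `b`, `c`.
#' @export
field_params <- function(params, year, re) {
  year <- as.character(year)
  if (!year %in% as.character(params$years)) {
    rlang::abort(paste0("unknown year: ", year))
  }
  tibble::tibble(
    a = params$alpha[[year]] + params$sigma_a * re[1],
    b = exp(params$beta[[year]] + params$sigma_b * re[2]),
    c = params$gamma[[year]] + params$sigma_c * re[3]
  )
}

# ---- internal likelihood machinery -----------------------------------------

# Flatten an egm_data object into index vectors for the likelihood engine.
# One unit = one (field_id, year) with >= 1 positive-weight observation.
ll_data <- function(data) {
  obs <- data$observations
  key <- paste(obs$field_id, obs$year, sep = "\r")
  fields <- obs[!duplicated(key), c("field_id", "year")]
  fidx <- match(key, unique(key))
  years <- sort(unique(as.character(fields$year)))
  list(
    field_id = fields$field_id,
    field_year = as.character(fields$year),
    yidx = match(as.character(fields$year), years),
    years = years,
    n_fields = nrow(fields),
    fidx = fidx,
    t = obs$day_std,
    logy = log(obs$weight_g_m2),
    m = as.numeric(tabulate(fidx, nrow(fields)))
  )
}

# Joint log density h(u) = log p(obs | u) + log p(u) for all fields at once.
# U is an n_fields x 3 matrix. Returns per-field h plus residual pieces
# needed for gradients when `parts = TRUE`.
joint_h <- function(U, pl, lld, Rinv, logdetR, parts = FALSE) {
  a_f <- pl$alpha[lld$yidx] + pl$sigma_a * U[, 1]
  # cap log steepness: beyond exp(30) the curve is a step and Inf*0 = NaN
  b_f <- exp(pmin(pl$beta[lld$yidx] + pl$sigma_b * U[, 2], 30))
  c_f <- pl$gamma[lld$yidx] + pl$sigma_c * U[, 3]
  eta <- b_f[lld$fidx] * (lld$t - c_f[lld$fidx])
  logmu <- a_f[lld$fidx] - softplus(-eta)
  r <- lld$logy - logmu
  s2 <- pl$sigma_e^2
  ss <- rowsum_1(r^2, lld$fidx, lld$n_fields)
  cond <- -0.5 * ss / s2 - lld$m * (log(pl$sigma_e) + 0.5 * log(2 * pi))
  qf <- Rinv[1, 1] * U[, 1]^2 + Rinv[2, 2] * U[, 2]^2 + Rinv[3, 3] * U[, 3]^2 +
    2 * (Rinv[1, 2] * U[, 1] * U[, 2] + Rinv[1, 3] * U[, 1] * U[, 3] +
           Rinv[2, 3] * U[, 2] * U[, 3])
  h <- cond - 0.5 * qf - 0.5 * logdetR - 1.5 * log(2 * pi)
  if (!parts) return(h)
  list(h = h, r = r, eta = eta, b_f = b_f)
}

rowsum_1 <- function(x, g, n) {
  out <- numeric(n)
  out[] <- rowsum(x, g)[, 1]
  out
}

# Gradient and Gauss-Newton Hessian of h at U (per field). The Gauss-Newton
# curvature J'J/sigma^2 + R^-1 is positive definite by construction, which
# keeps the Newton iteration and the quadrature scaling stable.
joint_grad_hess <- function(U, pl, lld, Rinv) {
  jp <- joint_h(U, pl, lld, Rinv, 0, parts = TRUE)
  q <- stats::plogis(-jp$eta)
  Ja <- rep(pl$sigma_a, length(jp$eta))
  Jb <- q * jp$eta * pl$sigma_b
  Jc <- -q * jp$b_f[lld$fidx] * pl$sigma_c
  s2 <- pl$sigma_e^2
  n <- lld$n_fields
  g1 <- rowsum_1(jp$r * Ja, lld$fidx, n) / s2 -
    (Rinv[1, 1] * U[, 1] + Rinv[1, 2] * U[, 2] + Rinv[1, 3] * U[, 3])
  g2 <- rowsum_1(jp$r * Jb, lld$fidx, n) / s2 -
    (Rinv[1, 2] * U[, 1] + Rinv[2, 2] * U[, 2] + Rinv[2, 3] * U[, 3])
  g3 <- rowsum_1(jp$r * Jc, lld$fidx, n) / s2 -
    (Rinv[1, 3] * U[, 1] + Rinv[2, 3] * U[, 2] + Rinv[3, 3] * U[, 3])
  H <- list(
    h11 = rowsum_1(Ja * Ja, lld$fidx, n) / s2 + Rinv[1, 1],
    h12 = rowsum_1(Ja * Jb, lld$fidx, n) / s2 + Rinv[1, 2],
    h13 = rowsum_1(Ja * Jc, lld$fidx, n) / s2 + Rinv[1, 3],
    h22 = rowsum_1(Jb * Jb, lld$fidx, n) / s2 + Rinv[2, 2],
    h23 = rowsum_1(Jb * Jc, lld$fidx, n) / s2 + Rinv[2, 3],
    h33 = rowsum_1(Jc * Jc, lld$fidx, n) / s2 + Rinv[3, 3]
  )
  list(g = cbind(g1, g2, g3), H = H)
}

# Vectorized 3x3 Cholesky H = L L' for all fields (lists of vectors).
chol3 <- function(H) {
  l11 <- sqrt(pmax(H$h11, 1e-12))
  l21 <- H$h12 / l11
  l31 <- H$h13 / l11
  l22 <- sqrt(pmax(H$h22 - l21^2, 1e-12))
  l32 <- (H$h23 - l21 * l31) / l22
  l33 <- sqrt(pmax(H$h33 - l31^2 - l32^2, 1e-12))
  list(l11 = l11, l21 = l21, l31 = l31, l22 = l22, l32 = l32, l33 = l33)
}

# Solve H s = g via the Cholesky factor, vectorized over fields.
chol3_solve <- function(L, g) {
  w1 <- g[, 1] / L$l11
  w2 <- (g[, 2] - L$l21 * w1) / L$l22
  w3 <- (g[, 3] - L$l31 * w1 - L$l32 * w2) / L$l33
  s3 <- w3 / L$l33
  s2 <- (w2 - L$l32 * s3) / L$l22
  s1 <- (w1 - L$l21 * s2 - L$l31 * s3) / L$l11
  cbind(s1, s2, s3)
}

# Posterior modes of the random effects for every field: damped Newton with
# Gauss-Newton curvature, vectorized across fields.
find_modes <- function(pl, lld, Rinv, logdetR, init = NULL,
                       maxit = 40, tol = 1e-9) {
  U <- if (is.null(init)) matrix(0, lld$n_fields, 3) else init
  h <- joint_h(U, pl, lld, Rinv, logdetR)
  for (it in seq_len(maxit)) {
    gh <- joint_grad_hess(U, pl, lld, Rinv)
    if (max(abs(gh$g)) < tol) break
    L <- chol3(gh$H)
    step <- chol3_solve(L, gh$g)
    step[!is.finite(step)] <- 0
    # trust region: standardized effects live on a unit scale, so cap the
    # per-field step length to keep the iteration out of overflow territory
    slen <- sqrt(rowSums(step^2))
    big <- slen > 4
    if (any(big)) step[big, ] <- step[big, , drop = FALSE] * (4 / slen[big])
    lam <- rep(1, lld$n_fields)
    for (bt in 1:10) {
      U1 <- U + lam * step
      h1 <- joint_h(U1, pl, lld, Rinv, logdetR)
      bad <- !is.finite(h1) | h1 < h - 1e-12
      if (!any(bad)) break
      lam[bad] <- lam[bad] / 2
    }
    moved <- max(abs(lam * step))
    U <- U + lam * step
    h <- joint_h(U, pl, lld, Rinv, logdetR)
    if (moved < 1e-10) break
  }
  gh <- joint_grad_hess(U, pl, lld, Rinv)
  list(U = U, h = h, L = chol3(gh$H))
}

# Marginal log likelihood by adaptive Gauss-Hermite quadrature, recentred
# per field at the posterior mode with Gauss-Newton Hessian scaling.
# n_points = 1 is the Laplace approximation.
agq_engine <- function(pl, lld, n_points, modes_init = NULL) {
  R <- rho_matrix(pl$rho)
  Rinv <- solve(R)
  logdetR <- determinant(R, logarithm = TRUE)$modulus[1]
  md <- find_modes(pl, lld, Rinv, logdetR, init = modes_init)
  L <- md$L
  logdetL <- log(L$l11) + log(L$l22) + log(L$l33)
  if (n_points == 1) {
    li <- md$h + 1.5 * log(2 * pi) - logdetL
    return(list(loglik = sum(li), per_field = li, modes = md$U))
  }
  gh <- pracma::gaussHermite(n_points)
  grid <- expand.grid(i = seq_len(n_points), j = seq_len(n_points),
                      k = seq_len(n_points))
  Z <- cbind(gh$x[grid$i], gh$x[grid$j], gh$x[grid$k])
  logw <- log(gh$w[grid$i]) + log(gh$w[grid$j]) + log(gh$w[grid$k])
  zn2 <- rowSums(Z^2)
  M <- matrix(-Inf, lld$n_fields, nrow(Z))
  for (g in seq_len(nrow(Z))) {
    # u = mode + sqrt(2) * A z with A = L^{-T}: back-substitution on L'
    v3 <- Z[g, 3] / L$l33
    v2 <- (Z[g, 2] - L$l32 * v3) / L$l22
    v1 <- (Z[g, 1] - L$l21 * v2 - L$l31 * v3) / L$l11
    Ug <- md$U + sqrt(2) * cbind(v1, v2, v3)
    M[, g] <- logw[g] + zn2[g] + joint_h(Ug, pl, lld, Rinv, logdetR)
  }
  mx <- apply(M, 1, max)
  li <- 1.5 * log(2) - logdetL + mx + log(rowSums(exp(M - mx)))
  list(loglik = sum(li), per_field = li, modes = md$U)
}

#' Marginal log likelihood of the growth model
#'
#' Integrates the per-field random effects out of the joint likelihood with
#' adaptive Gauss-Hermite quadrature: the three-dimensional integral for each
#' field is recentred at its posterior mode and scaled by the curvature
#' there, then evaluated on an `n_points`^3 tensor grid. One point per
#' dimension gives the Laplace approximation. The conditional density is
#' normal on log weight, which is identical to a multiplicative lognormal
#' error on the original scale.
#'
#' @param params An [egm_params] object covering every year in `data`.
#' @param data An [egm_data] object.
#' @param n_points Quadrature points per dimension (>= 1); default 5.
#' @return The marginal log likelihood (a single number).
#' @export
marginal_loglik <- function(params, data, n_points = 5) {
  stopifnot(inherits(data, "egm_data"), n_points >= 1)
  lld <- ll_data(data)
  missing_years <- setdiff(lld$years, as.character(params$years))
  if (length(missing_years)) {
    rlang::abort(paste0("params lack years: ", paste(missing_years, collapse = ", ")))
  }
  pl <- align_params(params, lld$years)
  agq_engine(pl, lld, n_points)$loglik
}

# reorder the year-indexed fixed effects to the engine's year ordering
align_params <- function(params, years) {
  list(
    alpha = unname(params$alpha[years]),
    beta = unname(params$beta[years]),
    gamma = unname(params$gamma[years]),
    sigma_a = params$sigma_a, sigma_b = params$sigma_b,
    sigma_c = params$sigma_c, rho = unname(params$rho),
    sigma_e = params$sigma_e
  )
}

# Per-year starting values: least squares of the fixed-effect logistic on
# pooled log weights, then pooled residual scale.
init_params <- function(lld) {
  K <- length(lld$years)
  alpha <- beta <- gamma <- numeric(K)
  resid2 <- 0
  nobs <- 0
  for (k in seq_len(K)) {
    sel <- lld$yidx[lld$fidx] == k
    t <- lld$t[sel]
    logy <- lld$logy[sel]
    a0 <- stats::quantile(logy, 0.95, names = FALSE)
    b0 <- 6 / max(diff(range(t)), 0.5)
    c0 <- stats::median(t)
    sse <- function(p) {
      mu <- p[1] - softplus(-exp(p[2]) * (t - p[3]))
      sum((logy - mu)^2)
    }
    op <- stats::optim(c(a0, log(b0), c0), sse, control = list(maxit = 500))
    alpha[k] <- op$par[1]
    beta[k] <- op$par[2]
    gamma[k] <- op$par[3]
    resid2 <- resid2 + op$value
    nobs <- nobs + length(t)
  }
  list(
    alpha = alpha, beta = beta, gamma = gamma,
    sigma_a = 0.3, sigma_b = 0.3, sigma_c = 0.3,
    rho = c(0, 0, 0),
    sigma_e = max(sqrt(resid2 / nobs) * 0.7, 0.02)
  )
}

#' Fit the logistic nonlinear mixed growth model
#'
#' Maximizes the marginal likelihood of the year-stratified logistic growth
#' model over the fixed effects, random-effect scales, correlations, and
#' residual scale. Random-effect scales are optimized on the log scale and
#' the correlation matrix through a spherical Cholesky-angle
#' parameterization, so every candidate is positive definite. When
#' `n_quadrature > 1` the optimizer first converges under the cheap Laplace
#' approximation and then refines under full adaptive quadrature.
#'
#' @param data An [egm_data] object with at least two fields.
#' @param n_quadrature Quadrature points per dimension for the final fit
#'   (default 5, i.e. 125 nodes per field).
#' @param control List of optimizer settings: `maxit` (default 400),
#'   `reltol` (1e-9), `laplace_init` (TRUE), `trace` (0).
#' @return An object of class `egm_fit` with elements `params`
#'   ([egm_params]), `loglik`, `converged`, `n_quadrature`, `eb` (tibble of
#'   empirical-Bayes random effects per field), `time_scale`, `r_squared`,
#'   `n_fields`, `n_obs`.
#' @export
fit_growth_model <- function(data, n_quadrature = 5, control = list()) {
  stopifnot(inherits(data, "egm_data"))
  ctl <- utils::modifyList(
    list(maxit = 400, reltol = 1e-9, laplace_init = TRUE, trace = 0),
    control
  )
  lld <- ll_data(data)
  if (lld$n_fields < 2) rlang::abort("need at least two fields to fit.")
  if (stats::sd(lld$logy) < 1e-10) {
    rlang::abort("all weights are (nearly) identical; model is degenerate.")
  }
  p0 <- init_params(lld)
  theta0 <- pack_params(p0)
  env <- new.env()
  env$modes <- NULL
  make_negll <- function(np) {
    function(theta) {
      pl <- unpack_params(theta, lld$years)
      pl$alpha <- unname(pl$alpha); pl$beta <- unname(pl$beta)
      pl$gamma <- unname(pl$gamma)
      out <- tryCatch(
        agq_engine(pl, lld, np, modes_init = env$modes),
        error = function(e) NULL
      )
      if (is.null(out) || !is.finite(out$loglik)) return(1e10)
      env$modes <- out$modes
      -out$loglik
    }
  }
  oc <- list(maxit = ctl$maxit, reltol = ctl$reltol, trace = ctl$trace)
  if (n_quadrature > 1 && ctl$laplace_init) {
    op1 <- stats::optim(theta0, make_negll(1), method = "BFGS", control = oc)
    theta0 <- op1$par
  }
  op <- stats::optim(theta0, make_negll(n_quadrature), method = "BFGS",
                     control = oc)
  pl <- unpack_params(op$par, lld$years)
  params <- egm_params(
    alpha = stats::setNames(unname(pl$alpha), lld$years),
    beta = stats::setNames(unname(pl$beta), lld$years),
    gamma = stats::setNames(unname(pl$gamma), lld$years),
    sigma_a = pl$sigma_a, sigma_b = pl$sigma_b, sigma_c = pl$sigma_c,
    rho = pl$rho, sigma_e = pl$sigma_e
  )
  final <- agq_engine(align_params(params, lld$years), lld, n_quadrature,
                      modes_init = env$modes)
  eb <- tibble::tibble(
    field_id = lld$field_id,
    year = lld$field_year,
    a = final$modes[, 1], b = final$modes[, 2], c = final$modes[, 3]
  )
  fit <- structure(
    list(
      params = params,
      loglik = final$loglik,
      converged = op$convergence == 0,
      n_quadrature = n_quadrature,
      eb = eb,
      time_scale = data$time_scale,
      n_fields = lld$n_fields,
      n_obs = length(lld$logy),
      optim_counts = op$counts
    ),
    class = "egm_fit"
  )
  fit$r_squared <- r_squared(fit, data)
  if (!fit$converged) {
    rlang::warn("optimizer did not report convergence; inspect `fit$converged`.")
  }
  fit
}

#' Empirical-Bayes random effects
#'
#' Posterior mode of each field's standardized random effects `(a, b, c)`
#' given its observations and the population parameters — the same mode used
#' to recentre the adaptive quadrature. These are the targets for subgroup
#' discovery.
#'
#' @param params An [egm_params] object.
#' @param data An [egm_data] object.
#' @return A tibble with columns `field_id`, `year`, `a`, `b`, `c`.
#' @export
eb_random_effects <- function(params, data) {
  lld <- ll_data(data)
  pl <- align_params(params, lld$years)
  modes <- agq_engine(pl, lld, 1)$modes
  tibble::tibble(
    field_id = lld$field_id, year = lld$field_year,
    a = modes[, 1], b = modes[, 2], c = modes[, 3]
  )
}

# Per-observation predictions on the original g m^-2 scale, using each
# field's empirical-Bayes curve.
predict_obs <- function(fit, data) {
  eb <- fit$eb
  obs <- data$observations
  idx <- match(paste(obs$field_id, obs$year), paste(eb$field_id, eb$year))
  if (anyNA(idx)) rlang::abort("observations present for fields without EB effects.")
  p <- fit$params
  yr <- as.character(obs$year)
  a <- p$alpha[yr] + p$sigma_a * eb$a[idx]
  b <- exp(p$beta[yr] + p$sigma_b * eb$b[idx])
  cc <- p$gamma[yr] + p$sigma_c * eb$c[idx]
  logistic_mean(a, b, cc, obs$day_std)
}

#' Goodness of fit of the growth curves
#'
#' Ordinary least-squares regression (with intercept) of the observed weights
#' on the model-predicted weights, where predictions use each field's
#' empirical-Bayes random effects on the original g m^-2 scale. Returns the
#' regression R-squared.
#'
#' @param fit An `egm_fit` object.
#' @param data The [egm_data] the model was fitted to.
#' @return R-squared in `[0, 1]`.
#' @export
r_squared <- function(fit, data) {
  pred <- predict_obs(fit, data)
  obs <- data$observations$weight_g_m2
  if (length(obs) < 3) rlang::abort("need at least 3 observations.")
  if (stats::sd(pred) < 1e-12) rlang::abort("predictions have zero variance.")
  summary(stats::lm(obs ~ pred))$r.squared
}

#' Fitted random-effect correlation matrix
#'
#' @param fit An `egm_fit` object.
#' @return A symmetric 3x3 unit-diagonal matrix with the fitted correlations
#'   between the `a`, `b`, `c` random effects.
#' @export
random_effect_correlations <- function(fit) {
  R <- rho_matrix(fit$params$rho)
  dimnames(R) <- list(c("a", "b", "c"), c("a", "b", "c"))
  R
}

#' @export
print.egm_fit <- function(x, ...) {
  cat("<egm_fit> logistic nonlinear mixed growth model\n")
  cat(sprintf(
    "  %d fields, %d observations, %d^3 quadrature nodes, converged: %s\n",
    x$n_fields, x$n_obs, x$n_quadrature, x$converged
  ))
  cat(sprintf("  log likelihood %.2f, R-squared %.4f\n", x$loglik, x$r_squared))
  print(x$params)
  invisible(x)
}
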