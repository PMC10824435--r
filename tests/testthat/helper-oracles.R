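# Plain Monte-Carlo integration of the random-effects integral from prior
# draws: the brute-force oracle for the adaptive quadrature. Returns the
# total log marginal likelihood and its standard error (delta method on the
# log of the per-field means, combined across fields).
mc_marginal_loglik <- function(params, data, n_draws = 1e6, seed = 99) {
  set.seed(seed)
  obs <- data$observations
  R <- egmine:::rho_matrix(params$rho)
  C <- chol(R)
  total <- 0
  var_log <- 0
  for (key in unique(paste(obs$field_id, obs$year))) {
    sel <- paste(obs$field_id, obs$year) == key
    t <- obs$day_std[sel]
    logy <- log(obs$weight_g_m2[sel])
    yr <- as.character(obs$year[sel][1])
    U <- matrix(stats::rnorm(3 * n_draws), n_draws, 3) %*% C
    a <- params$alpha[[yr]] + params$sigma_a * U[, 1]
    b <- exp(params$beta[[yr]] + params$sigma_b * U[, 2])
    cc <- params$gamma[[yr]] + params$sigma_c * U[, 3]
    ll <- 0
    for (j in seq_along(t)) {
      mu <- a - egmine:::softplus(-b * (t[j] - cc))
      ll <- ll + stats::dnorm(logy[j], mu, params$sigma_e, log = TRUE)
    }
    m <- max(ll)
    w <- exp(ll - m)
    mw <- mean(w)
    total <- total + m + log(mw)
    var_log <- var_log + stats::var(w) / (n_draws * mw^2)
  }
  list(loglik = total, se = sqrt(var_log))
}
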