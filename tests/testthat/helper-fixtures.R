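# Shared fixtures built in code.

# two-field toy growth table (six rows) and matching field records
toy_growth <- function() {
  tibble::tibble(
    field_id = rep(c("f1", "f2"), each = 3),
    year = "2017",
    days_after_planting = c(40, 80, 120, 50, 90, 130),
    weight_g_m2 = c(300, 2000, 4200, 500, 2500, 4800)
  )
}

toy_fields <- function() {
  tibble::tibble(
    field_id = c("f1", "f2"),
    year = "2017",
    K_soil = c(150, 320),
    Dryness = c("dry", "wet"),
    yield_ton_ha = c(45, 60),
    irrigated = c(TRUE, FALSE),
    planting_date = as.Date(c("2017-04-10", "2017-04-20"))
  )
}

# a small two-year simulation used by several model tests
tiny_sim <- function(seed = 3, n_per_year = 15) {
  yrs <- c("2016", "2017")
  cfg <- sim_config(
    years = yrs, n_fields_per_year = n_per_year,
    alpha = stats::setNames(log(c(4000, 5200)), yrs),
    beta_day = stats::setNames(log(c(0.09, 0.08)), yrs),
    gamma_day = stats::setNames(c(80, 78), yrs),
    yield_base = stats::setNames(c(45, 55), yrs),
    seed = seed
  )
  simulate_farm(cfg)
}

# true parameters of a sim config expressed on the standardized-time scale
true_params_std <- function(config, time_scale) {
  egm_params(
    alpha = config$alpha,
    beta = config$beta_day + log(time_scale),
    gamma = config$gamma_day / time_scale,
    sigma_a = config$sigma_a, sigma_b = config$sigma_b,
    sigma_c = config$sigma_c_day / time_scale,
    rho = config$rho, sigma_e = config$sigma_e
  )
}

# Standard two-field toy for quadrature accuracy checks: enough visits per
# field that the random-effect posterior is close to Gaussian.
quad_toy <- function(seed = 2, n_fields = 2) {
  set.seed(seed)
  days <- seq(30, 138, length.out = 14)
  s <- stats::sd(rep(days, n_fields))
  p <- egm_params(
    alpha = c(`2017` = 8.3), beta = c(`2017` = 1.2), gamma = c(`2017` = 2.3),
    sigma_a = 0.35, sigma_b = 0.25, sigma_c = 0.25,
    rho = c(-0.5, 0.3, -0.6), sigma_e = 0.2
  )
  growth <- dplyr::bind_rows(lapply(seq_len(n_fields), function(i) {
    re <- stats::rnorm(3)
    mu <- logistic_mean(8.3 + 0.35 * re[1], exp(1.2 + 0.25 * re[2]),
                        2.3 + 0.25 * re[3], days / s)
    tibble::tibble(
      field_id = paste0("f", i), year = "2017", days_after_planting = days,
      weight_g_m2 = mu * exp(stats::rnorm(length(days), 0, 0.2))
    )
  }))
  fields <- tibble::tibble(field_id = paste0("f", seq_len(n_fields)),
                           year = "2017")
  list(params = p, data = egm_data(growth, fields))
}

# deterministic 12-record table with three descriptors, for search oracles
records12 <- function() {
  tibble::tibble(
    .key = as.character(1:12),
    K_soil = c(90, 110, 130, 150, 170, 190, 210, 230, 250, 270, 290, 310),
    Mg_soil = c(200, 120, 180, 240, 160, 140, 220, 260, 100, 130, 210, 190),
    Dryness = c("dry", "wet", "average", "dry", "wet", "average",
                "dry", "wet", "average", "dry", "wet", "average")
  )
}

targets12 <- function() {
  c(1.2, -0.4, 0.8, 1.5, -1.1, 0.3, 0.9, -0.2, -0.7, 1.1, 0.5, -0.9)
}

# Independent exhaustive enumerator over the conjunctive description
# language (dynamic equal-frequency thresholds recomputed inside the
# current subgroup), used as the oracle for beam search with infinite
# width. Deliberately written with plain loops and logical filtering,
# not via refine()/beam_search().
enumerate_descriptions <- function(records, targets, descriptors, depth,
                                   n_bins, direction) {
  results <- new.env()
  store <- function(desc_labels, members) {
    vals <- targets[members]
    lab <- paste(sort(desc_labels, method = "radix"), collapse = " & ")
    if (length(vals) < 2 || stats::sd(vals) == 0) {
      q <- -Inf; mn <- NA; s <- NA
    } else {
      t <- mean(vals) * sqrt(length(vals)) / stats::sd(vals)
      q <- if (direction == "high") t else -t
      mn <- mean(vals); s <- stats::sd(vals)
    }
    key <- paste(lab, paste(sort(records$.key[members]), collapse = ","))
    results[[key]] <- tibble::tibble(
      description = lab, n = length(vals), mean = mn, sd = s, quality = q
    )
    q
  }
  conds_for <- function(members) {
    out <- list()
    for (attr in descriptors) {
      v <- records[[attr]][members]
      v <- v[!is.na(v)]
      if (!length(v)) next
      if (is.numeric(v)) {
        qs <- unique(stats::quantile(v, seq_len(n_bins - 1) / n_bins,
                                     names = FALSE, type = 7))
        for (q in qs) {
          out <- c(out,
                   list(list(attr = attr, op = "le", val = q)),
                   list(list(attr = attr, op = "gt", val = q)))
        }
      } else {
        for (lev in sort(unique(as.character(v)))) {
          out <- c(out,
                   list(list(attr = attr, op = "eq", val = lev)),
                   list(list(attr = attr, op = "neq", val = lev)))
        }
      }
    }
    out
  }
  cond_lab <- function(cd) {
    op <- c(le = "<=", gt = ">", eq = "==", neq = "!=")[[cd$op]]
    val <- if (is.numeric(cd$val)) format(cd$val, trim = TRUE) else
      paste0("'", cd$val, "'")
    paste(cd$attr, op, val)
  }
  apply_cond <- function(cd, members) {
    v <- records[[cd$attr]]
    keep <- switch(cd$op,
      le = v <= cd$val, gt = v > cd$val,
      eq = v == cd$val, neq = v != cd$val)
    keep[is.na(keep)] <- FALSE
    members & keep
  }
  # canonical info check: a condition adds information iff it changes the
  # (attr, op)-tightest bound set
  recurse <- function(desc, labels, members, level) {
    if (level > depth) return()
    for (cd in conds_for(members)) {
      # skip conditions that are not the tightest for their (attr, op)
      dup <- FALSE
      for (p in desc) {
        if (p$attr == cd$attr && p$op == cd$op) {
          if (cd$op == "le" && cd$val >= p$val) dup <- TRUE
          if (cd$op == "gt" && cd$val <= p$val) dup <- TRUE
          if (cd$op %in% c("eq", "neq") && identical(cd$val, p$val)) dup <- TRUE
        }
      }
      if (dup) next
      # keep only the tightest per (attr, op) in the stored description
      new_desc <- desc
      replaced <- FALSE
      for (i in seq_along(new_desc)) {
        p <- new_desc[[i]]
        if (p$attr == cd$attr && p$op == cd$op &&
            ((cd$op == "le" && cd$val < p$val) ||
             (cd$op == "gt" && cd$val > p$val))) {
          new_desc[[i]] <- cd
          replaced <- TRUE
        }
      }
      if (!replaced) new_desc <- c(new_desc, list(cd))
      new_labels <- vapply(new_desc, cond_lab, character(1))
      new_members <- apply_cond(cd, members)
      q <- store(new_labels, new_members)
      # degenerate subgroups never seed further refinement
      if (is.finite(q)) recurse(new_desc, new_labels, new_members, level + 1)
    }
  }
  recurse(list(), character(0), rep(TRUE, nrow(records)), 1)
  out <- dplyr::bind_rows(as.list(results))
  dplyr::distinct(out)
}
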