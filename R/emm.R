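#' One-sample t statistic of a target sample against mean zero
#'
#' The quality statistic of exceptional growth mining: for a subgroup's
#' random-effect values it is \eqn{t = \hat\mu \sqrt{n} / \hat\sigma}, with
#' the sample standard deviation (n-1 denominator). Under the population
#' model the random effects have mean zero, so large |t| flags a subgroup
#' whose growth deviates systematically from the yearly average curve.
#'
#' @param values Numeric vector of target values (n >= 2, non-constant).
#' @return The t statistic.
#' @export
t_statistic <- function(values) {
  n <- length(values)
  if (n < 2) rlang::abort("t statistic undefined for fewer than 2 values.")
  s <- stats::sd(values)
  if (s == 0) rlang::abort("t statistic undefined for constant values.")
  mean(values) * sqrt(n) / s
}

#' Directional quality measure
#'
#' `direction = "high"` scores subgroups with positive target values
#' (quality = t); `direction = "low"` scores negative ones (quality = -t).
#'
#' @param values Numeric vector of target values.
#' @param direction `"high"` or `"low"`.
#' @return The quality value.
#' @export
quality_measure <- function(values, direction = c("high", "low")) {
  direction <- match.arg(direction)
  t <- t_statistic(values)
  if (direction == "high") t else -t
}

# ---- description language ---------------------------------------------------

new_condition <- function(attribute, kind, value) {
  list(attribute = attribute, kind = kind, value = value)
}

cond_label <- function(cond) {
  op <- switch(cond$kind, le = "<=", gt = ">", eq = "==", neq = "!=")
  val <- if (is.numeric(cond$value)) format(cond$value, trim = TRUE) else
    paste0("'", cond$value, "'")
  paste(cond$attribute, op, val)
}

desc_label <- function(desc) {
  if (!length(desc)) return("(all)")
  paste(vapply(desc, cond_label, character(1)), collapse = " & ")
}

# Records with a missing value on the condition's attribute do not satisfy it.
cond_match <- function(cond, records) {
  v <- records[[cond$attribute]]
  out <- switch(cond$kind,
    le = v <= cond$value,
    gt = v > cond$value,
    eq = v == cond$value,
    neq = v != cond$value
  )
  out & !is.na(out)
}

desc_match <- function(desc, records) {
  out <- rep(TRUE, nrow(records))
  for (cond in desc) out <- out & cond_match(cond, records)
  out
}

# Canonical form: per numeric attribute keep only the tightest <= (smallest)
# and tightest > (largest); drop exact duplicates; order conditions
# deterministically.
canonicalize <- function(desc) {
  if (!length(desc)) return(desc)
  keys <- vapply(desc, function(cd) paste(cd$attribute, cd$kind), character(1))
  out <- list()
  for (key in unique(keys)) {
    grp <- desc[keys == key]
    kind <- grp[[1]]$kind
    if (kind == "le") {
      best <- grp[[which.min(vapply(grp, function(cd) cd$value, numeric(1)))]]
      out <- c(out, list(best))
    } else if (kind == "gt") {
      best <- grp[[which.max(vapply(grp, function(cd) cd$value, numeric(1)))]]
      out <- c(out, list(best))
    } else {
      vals <- vapply(grp, function(cd) as.character(cd$value), character(1))
      out <- c(out, grp[!duplicated(vals)])
    }
  }
  labels <- vapply(out, cond_label, character(1))
  out[order(labels, method = "radix")]
}

#' Refine a description by one extra condition
#'
#' For every numeric descriptor, candidate thresholds are the `n_bins - 1`
#' equal-frequency quantiles of that descriptor among the current members
#' (dynamic discretization), each contributing a `<=` and a `>` condition;
#' every categorical descriptor contributes an `==` and a `!=` condition per
#' level observed among members. Each condition is conjoined to the parent
#' and canonicalized; refinements that add no information (looser thresholds
#' on an already-constrained attribute) are dropped.
#'
#' @param desc A description: list of conditions (possibly empty).
#' @param records Tibble of field records with descriptor columns.
#' @param descriptors Character vector of descriptor column names.
#' @param n_bins Number of equal-frequency bins (thresholds = n_bins - 1).
#' @return A list of candidate descriptions (deduplicated by label).
#' @export
refine <- function(desc, records, descriptors, n_bins = 6) {
  members <- desc_match(desc, records)
  sub <- records[members, , drop = FALSE]
  cands <- list()
  for (attr in descriptors) {
    v <- sub[[attr]]
    v <- v[!is.na(v)]
    if (!length(v)) next
    if (is.numeric(v)) {
      qs <- unique(stats::quantile(v, probs = seq_len(n_bins - 1) / n_bins,
                                   names = FALSE, type = 7))
      for (q in qs) {
        cands <- c(cands,
                   list(new_condition(attr, "le", q)),
                   list(new_condition(attr, "gt", q)))
      }
    } else {
      for (lev in sort(unique(as.character(v)))) {
        cands <- c(cands,
                   list(new_condition(attr, "eq", lev)),
                   list(new_condition(attr, "neq", lev)))
      }
    }
  }
  out <- list()
  parent_lab <- desc_label(canonicalize(desc))
  seen <- character(0)
  for (cand in cands) {
    new_desc <- canonicalize(c(desc, list(cand)))
    lab <- desc_label(new_desc)
    if (lab == parent_lab) next  # looser threshold: no new information
    if (lab %in% seen) next
    seen <- c(seen, lab)
    out <- c(out, list(new_desc))
  }
  out
}

# Evaluate one description: membership, stats, quality. Subgroups with
# n < min_n or zero spread get quality -Inf and never enter the beam.
evaluate_desc <- function(desc, records, targets, direction, min_n = 2) {
  members <- desc_match(desc, records)
  vals <- targets[members]
  n <- length(vals)
  if (n < max(2, min_n) || stats::sd(vals) == 0) {
    stats_row <- list(n = n, mean = NA_real_, sd = NA_real_, t = NA_real_,
                      quality = -Inf)
  } else {
    t <- mean(vals) * sqrt(n) / stats::sd(vals)
    stats_row <- list(
      n = n, mean = mean(vals), sd = stats::sd(vals), t = t,
      quality = if (direction == "high") t else -t
    )
  }
  tibble::tibble(
    description = desc_label(desc),
    depth = length(desc),
    n = stats_row$n, mean = stats_row$mean, sd = stats_row$sd,
    t = stats_row$t, quality = stats_row$quality,
    conditions = list(desc),
    members = list(records$.key[members])
  )
}

#' Beam search for exceptional subgroups
#'
#' Level-wise search over conjunctive descriptions up to depth `depth`: at
#' each level the `beam_width` best candidates by quality seed the next
#' level's refinements. Returns every distinct evaluated subgroup
#' (deduplicated on canonical description and member set), sorted by quality
#' with deterministic tie-breaking (shorter description first, then
#' lexicographic).
#'
#' @param records Tibble of field records (descriptor columns plus a `.key`
#'   column identifying each record).
#' @param targets Numeric vector of target values, aligned with `records`.
#' @param descriptors Descriptor column names to search over.
#' @param direction `"high"` or `"low"`.
#' @param beam_width Beam width `w` (may be `Inf` for exhaustive level-wise
#'   search).
#' @param depth Maximum number of conditions `d`.
#' @param n_bins Equal-frequency bins for numeric thresholds.
#' @param min_size Minimum subgroup size during search (default 2).
#' @return A tibble of subgroups: `description`, `depth`, `n`, `mean`, `sd`,
#'   `t`, `quality`, plus list columns `conditions` and `members`, and the
#'   constant columns `target_direction`.
#' @export
beam_search <- function(records, targets, descriptors,
                        direction = c("high", "low"),
                        beam_width = 25, depth = 2, n_bins = 6,
                        min_size = 2) {
  direction <- match.arg(direction)
  stopifnot(beam_width >= 1, depth >= 1, n_bins >= 2, min_size >= 2)
  if (is.null(records$.key)) records$.key <- as.character(seq_len(nrow(records)))
  keep <- !is.na(targets)
  records <- records[keep, , drop = FALSE]
  targets <- targets[keep]

  results <- list()
  seen <- character(0)
  beam <- list(list())  # level 0: the empty description
  for (level in seq_len(depth)) {
    rows <- list()
    cand_descs <- list()
    for (parent in beam) {
      for (cand in refine(parent, records, descriptors, n_bins)) {
        row <- evaluate_desc(cand, records, targets, direction, min_size)
        key <- paste(row$description, paste(sort(row$members[[1]]),
                                            collapse = ","), sep = "\r")
        if (key %in% seen) next
        seen <- c(seen, key)
        rows <- c(rows, list(row))
        cand_descs <- c(cand_descs, list(cand))
      }
    }
    if (!length(rows)) break
    lev <- dplyr::bind_rows(rows)
    results <- c(results, list(lev))
    ok <- which(is.finite(lev$quality))
    ord <- ok[order(-lev$quality[ok], lev$depth[ok], lev$description[ok],
                    method = "radix")]
    take <- utils::head(ord, if (is.finite(beam_width)) beam_width else length(ord))
    beam <- cand_descs[take]
    if (!length(beam)) break
  }
  out <- dplyr::bind_rows(results)
  if (!nrow(out)) return(out)
  out <- out[order(-out$quality, out$depth, out$description, method = "radix"), ]
  out$direction <- direction
  out
}

#' Mine exceptional growth subgroups
#'
#' Joins the empirical-Bayes random effects onto the field records and runs
#' the beam search on one random-effect component.
#'
#' @param data An [egm_data] object.
#' @param eb Tibble of empirical-Bayes effects (`field_id`, `year`, `a`,
#'   `b`, `c`), e.g. `fit$eb` from [fit_growth_model()].
#' @param target Which random effect to mine: `"a"` (maximum growth), `"b"`
#'   (steepness), or `"c"` (midpoint timing).
#' @param direction `"high"` or `"low"`.
#' @inheritParams beam_search
#' @param descriptors Descriptor columns; defaults to those in `data`.
#' @return A subgroup tibble (see [beam_search()]) with a `target` column.
#' @export
mine_subgroups <- function(data, eb, target = c("a", "b", "c"),
                           direction = c("high", "low"),
                           beam_width = 25, depth = 2, n_bins = 6,
                           min_size = 2, descriptors = NULL) {
  target <- match.arg(target)
  direction <- match.arg(direction)
  if (inherits(eb, "egm_fit")) eb <- eb$eb
  if (is.null(descriptors)) descriptors <- data$descriptors
  rec <- data$records
  rec$.key <- paste(rec$field_id, rec$year, sep = "|")
  idx <- match(rec$.key, paste(eb$field_id, eb$year, sep = "|"))
  targets <- eb[[target]][idx]
  out <- beam_search(rec, targets, descriptors, direction = direction,
                     beam_width = beam_width, depth = depth, n_bins = n_bins,
                     min_size = min_size)
  if (nrow(out)) out$target <- target
  out
}
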