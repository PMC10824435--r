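#' Split each year's planting period into tertiles
#'
#' Within each year, fields are ordered by planting date (stable with
#' respect to input order on ties) and split into three equal-frequency
#' groups: early, middle, late. When the count is not divisible by three,
#' the earlier groups receive the extra fields. Fields with a missing
#' planting date are labelled `"unknown"`.
#'
#' @param fields Tibble with `field_id`, `year`, `planting_date`.
#' @return A tibble `field_id`, `year`, `planting_group`.
#' @export
planting_tertiles <- function(fields) {
  out <- fields[c("field_id", "year")]
  out$planting_group <- NA_character_
  for (yr in unique(fields$year)) {
    sel <- which(fields$year == yr)
    dates <- fields$planting_date[sel]
    known <- sel[!is.na(dates)]
    if (length(known)) {
      ord <- known[order(fields$planting_date[known], method = "radix")]
      n <- length(ord)
      sizes <- rep(n %/% 3, 3) + (seq_len(3) <= n %% 3)
      out$planting_group[ord] <- rep(c("early", "middle", "late"), sizes)
    }
    out$planting_group[sel[is.na(dates)]] <- "unknown"
  }
  out
}

#' Profile one subgroup against potential confounders
#'
#' Summaries inspected alongside each mined subgroup: how its members are
#' spread over years, their mean yield, how many can be irrigated, and how
#' they fall in the per-year planting tertiles. Because the targets are
#' within-year deviations, a subgroup concentrated in one year or one
#' planting window would hint at a management or weather story rather than
#' a soil one.
#'
#' @param members Character vector of member keys `"field_id|year"` (as in
#'   the `members` list column of mined subgroups).
#' @param data An [egm_data] object (its `records` supply the annotations).
#' @return A one-row tibble: `n`, `mean_yield`, `irrigated_no`,
#'   `irrigated_yes`, per-year counts `year_<yr>`, and planting counts
#'   `planting_early`, `planting_middle`, `planting_late`.
#' @export
subgroup_profile <- function(members, data) {
  rec <- data$records
  key <- paste(rec$field_id, rec$year, sep = "|")
  sel <- match(members, key)
  if (anyNA(sel)) rlang::abort("some members do not resolve to field records.")
  sub <- rec[sel, , drop = FALSE]
  yrs <- sort(unique(as.character(rec$year)))
  year_counts <- stats::setNames(
    as.integer(table(factor(as.character(sub$year), levels = yrs))),
    paste0("year_", yrs)
  )
  tert <- planting_tertiles(rec)
  grp <- tert$planting_group[sel]
  pg <- stats::setNames(
    as.integer(table(factor(grp, levels = c("early", "middle", "late")))),
    c("planting_early", "planting_middle", "planting_late")
  )
  irr <- if ("irrigated" %in% names(sub)) sub$irrigated else
    rep(NA, nrow(sub))
  yield <- if ("yield_ton_ha" %in% names(sub)) sub$yield_ton_ha else
    rep(NA_real_, nrow(sub))
  dplyr::bind_cols(
    tibble::tibble(
      n = nrow(sub),
      mean_yield = mean(yield, na.rm = TRUE),
      irrigated_no = sum(!irr, na.rm = TRUE),
      irrigated_yes = sum(irr, na.rm = TRUE)
    ),
    tibble::as_tibble(as.list(year_counts)),
    tibble::as_tibble(as.list(pg))
  )
}

#' Append confounder profiles to a subgroup table
#'
#' @param subgroups Subgroup tibble with a `members` list column.
#' @param data An [egm_data] object.
#' @return `subgroups` with the [subgroup_profile()] columns appended.
#' @export
profile_subgroups <- function(subgroups, data) {
  if (!nrow(subgroups)) return(subgroups)
  prof <- purrr::map_dfr(subgroups$members,
                         function(m) subgroup_profile(m, data))
  prof$n <- NULL
  dplyr::bind_cols(subgroups, prof)
}

#' Run the full exceptional-growth pipeline for one target
#'
#' Convenience wrapper: mine subgroups on one random effect and direction,
#' filter to the Pareto front over (directional mean, spread, size), apply
#' the top-k report post-processing, and append confounder profiles.
#'
#' @param fit An `egm_fit` object.
#' @param data The [egm_data] the model was fitted to.
#' @inheritParams mine_subgroups
#' @param k Number of subgroups to report.
#' @param report_min_size Size filter for reporting (subgroups with
#'   `n <= report_min_size` are not reported; default 15).
#' @return A tibble of up to `k` profiled subgroups.
#' @export
egm_report <- function(fit, data, target = c("a", "b", "c"),
                       direction = c("high", "low"), beam_width = 25,
                       depth = 2, n_bins = 6, k = 5, report_min_size = 15) {
  mined <- mine_subgroups(data, fit, target = target, direction = direction,
                          beam_width = beam_width, depth = depth,
                          n_bins = n_bins)
  front <- pareto_front(mined)
  top <- top_k_report(front, k = k, min_size = report_min_size)
  profile_subgroups(top, data)
}

#' Plot mined subgroups in the Pareto space
#'
#' Scatter of directional mean against standard deviation, point size by
#' member count, front members highlighted.
#'
#' @param subgroups Subgroup tibble from [mine_subgroups()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_pareto <- function(subgroups, ...) {
  front <- pareto_front(subgroups)
  direction <- if ("direction" %in% names(subgroups))
    subgroups$direction[1] else "high"
  sg <- subgroups[is.finite(subgroups$quality), , drop = FALSE]
  sg$dmean <- if (direction == "low") -sg$mean else sg$mean
  sg$on_front <- sg$description %in% front$description
  ggplot2::ggplot(sg, ggplot2::aes(x = .data$dmean, y = .data$sd,
                                   size = .data$n,
                                   colour = .data$on_front)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60")) +
    ggplot2::labs(x = "directional mean of target", y = "standard deviation",
                  colour = "Pareto front", size = "fields")
}
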