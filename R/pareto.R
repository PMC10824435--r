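#' Pareto dominance between subgroup objective triples
#'
#' Subgroups trade off directional mean (larger better), standard deviation
#' (smaller better), and size (larger better). `x` dominates `y` when it is
#' at least as good on all three and strictly better on at least one.
#'
#' @param x,y Numeric length-3 vectors `(dmean, sd, n)`.
#' @return `TRUE` iff `x` dominates `y`.
#' @export
dominates <- function(x, y) {
  ge <- x[1] >= y[1] && x[2] <= y[2] && x[3] >= y[3]
  strict <- x[1] > y[1] || x[2] < y[2] || x[3] > y[3]
  ge && strict
}

#' Pareto front of mined subgroups
#'
#' Keeps exactly the subgroups not dominated by any other in the input, in
#' the space of directional mean (the mean for `"high"` runs, its negative
#' for `"low"` runs), standard deviation, and size. Input order is
#' preserved. Subgroups with undefined statistics are dropped first.
#'
#' @param subgroups Subgroup tibble from [mine_subgroups()] /
#'   [beam_search()], or any data frame with `mean`, `sd`, `n` columns.
#' @param direction `"high"` or `"low"`; defaults to the tibble's
#'   `direction` column when present.
#' @return The non-dominated rows of `subgroups`.
#' @export
pareto_front <- function(subgroups, direction = NULL) {
  if (is.null(direction)) {
    direction <- if ("direction" %in% names(subgroups))
      subgroups$direction[1] else "high"
  }
  ok <- is.finite(subgroups$mean) & is.finite(subgroups$sd) &
    is.finite(subgroups$n)
  subgroups <- subgroups[ok, , drop = FALSE]
  n <- nrow(subgroups)
  if (n <= 1) return(subgroups)
  dm <- if (direction == "low") -subgroups$mean else subgroups$mean
  sd <- subgroups$sd
  sz <- subgroups$n
  dominated <- vapply(seq_len(n), function(i) {
    ge <- dm >= dm[i] & sd <= sd[i] & sz >= sz[i]
    strict <- dm > dm[i] | sd < sd[i] | sz > sz[i]
    any(ge & strict)
  }, logical(1))
  subgroups[!dominated, , drop = FALSE]
}

#' Top-k subgroup report
#'
#' Post-processes a Pareto front the way results are presented: (i) drop
#' subgroups with `n <= min_size`; (ii) collapse redundant same-attribute,
#' same-direction conditions within a description to the tightest threshold
#' (e.g. `K_soil <= 200 & K_soil <= 100` becomes `K_soil <= 100`);
#' (iii) when two retained subgroups' member sets are nested and their
#' descriptions differ only in thresholds on the same attributes, keep the
#' larger subgroup; (iv) return the `k` highest-quality survivors.
#'
#' @param front Subgroup tibble (typically the output of [pareto_front()]).
#' @param k Number of subgroups to report (default 5).
#' @param min_size Minimum member count; subgroups with `n <= min_size` are
#'   dropped (default 15).
#' @return At most `k` rows; if fewer survive, all of them (with a message).
#' @export
top_k_report <- function(front, k = 5, min_size = 15) {
  stopifnot(k >= 1)
  out <- front[front$n > min_size, , drop = FALSE]
  if (nrow(out) && "conditions" %in% names(out)) {
    out$conditions <- lapply(out$conditions, canonicalize)
    out$description <- vapply(out$conditions, desc_label, character(1))
    sig <- vapply(out$conditions, function(desc) {
      paste(sort(vapply(desc, function(cd) paste(cd$attribute, cd$kind),
                        character(1))), collapse = "&")
    }, character(1))
    drop <- rep(FALSE, nrow(out))
    for (i in seq_len(nrow(out))) {
      for (j in seq_len(nrow(out))) {
        if (i == j || drop[i]) next
        if (sig[i] != sig[j]) next
        mi <- out$members[[i]]
        mj <- out$members[[j]]
        if (length(mi) < length(mj) && all(mi %in% mj)) drop[i] <- TRUE
      }
    }
    out <- out[!drop, , drop = FALSE]
  }
  out <- out[order(-out$quality, out$depth, out$description,
                   method = "radix"), , drop = FALSE]
  if (nrow(out) < k) {
    message("only ", nrow(out), " subgroups survive the report filters.")
    return(out)
  }
  utils::head(out, k)
}
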