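#' Published subgroup summaries from the potato-farm case study
#'
#' The top-5 subgroups per random effect and direction reported for the
#' Dutch potato farm the method was developed on: description, quality
#' \eqn{\phi}, subgroup mean and standard deviation of the target random
#' effect, member counts (total and per year), and mean yield. The printed
#' statistics are rounded to two decimals, so recomputing
#' \eqn{t = \hat\mu \sqrt{n} / \hat\sigma} from them reproduces \eqn{\phi}
#' only to about one decimal. Useful as a consistency check of the quality
#' measure and as a realistic reference for subgroup magnitudes.
#'
#' @return A tibble with columns `target`, `direction`, `description`,
#'   `phi`, `mu`, `sd`, `n`, `n_2015` ... `n_2018`, `yield`.
#' @export
case_study_subgroups <- function() {
  path <- system.file("extdata", "case_study_subgroups.csv",
                      package = "egmine", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE)
}
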