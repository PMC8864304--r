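#' Published global cause-of-death counts, 2000 and 2019
#'
#' Point estimates of global deaths by cause in 5-19-year-olds for 2000 and
#' 2019, overall and by age-sex group, as published (the `all_cause` rows
#' are the all-cause totals). These printed counts are consistency inputs:
#' running [csmf_from_counts()] and [broad_group_totals()] on them
#' reproduces the published percentages and broad-group sums.
#'
#' @param group Optional filter: `"all"`, or one of [age_sex_groups()].
#' @return Tibble with `group`, `cause`, `deaths_2000`, `deaths_2019`.
#' @export
#' @examples
#' head(global_cod_table("5to9"))
global_cod_table <- function(group = NULL) {
  path <- system.file("extdata", "global_cod_2019.csv", package = "csmf519")
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!is.null(group)) df <- df[df$group == group, ]
  df
}

#' Published input-source death counts, 2019
#'
#' Global deaths in 5-19-year-olds in 2019 by estimation input source:
#' high-quality vital registration countries, low-mortality modelled
#' countries, high-mortality modelled countries, and the national
#' surveillance pass-through stratum.
#'
#' @return Named numeric vector of deaths by stratum.
#' @export
input_source_deaths_2019 <- function() {
  c(HQVR = 119802, LMM = 84414, HMM = 1221418, passthrough = 54593)
}
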