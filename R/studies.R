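#' Validate and filter multi-cause death-count studies
#'
#' Applies the two inclusion rules for cause-of-death input studies: a study
#' must report at least two causes of death, and must contribute at least 15
#' deaths in total. Studies are long-format records, one row per
#' (study, cause) with a nonnegative death count; zero-count rows are treated
#' as reported causes only if the study explicitly lists them, so "reported"
#' means present in the table with any count, and the two-cause rule counts
#' distinct listed causes.
#'
#' @param studies Tibble with columns `study_id`, `iso_code`, `group`,
#'   `year_mid`, `cause`, `deaths`.
#' @param taxonomy Taxonomy tibble for the studies' age-sex group (or a
#'   superset of allowed cause labels across groups).
#' @param min_deaths Minimum total deaths for inclusion (default 15).
#' @return A list with `accepted` (the retained rows, unchanged) and
#'   `rejected` (one row per excluded study with a `reason` column naming the
#'   violated rule). Unknown cause labels and negative counts are errors, not
#'   rejections.
#' @export
#' @examples
#' tax <- cause_taxonomy("5to9")
#' s <- tibble::tibble(study_id = "s1", iso_code = "AAA", group = "5to9",
#'                     year_mid = 2010, cause = c("malaria", "diarrhoea"),
#'                     deaths = c(10, 8))
#' validate_studies(s, tax)$accepted
validate_studies <- function(studies, taxonomy, min_deaths = 15) {
  req <- c("study_id", "iso_code", "group", "year_mid", "cause", "deaths")
  missing_cols <- setdiff(req, names(studies))
  if (length(missing_cols)) {
    stop("studies table missing columns: ", paste(missing_cols, collapse = ", "))
  }
  unknown <- setdiff(unique(studies$cause), taxonomy$cause)
  if (length(unknown)) {
    stop("unknown cause label(s): ", paste(unknown, collapse = ", "))
  }
  if (any(studies$deaths < 0)) stop("negative death counts are not allowed")
  per_study <- studies |>
    dplyr::group_by(.data$study_id) |>
    dplyr::summarise(n_causes = dplyr::n_distinct(.data$cause),
                     total_deaths = sum(.data$deaths), .groups = "drop") |>
    dplyr::mutate(reason = dplyr::case_when(
      .data$n_causes < 2 ~ "fewer than 2 reported causes",
      .data$total_deaths < min_deaths ~ paste0("fewer than ", min_deaths, " deaths"),
      TRUE ~ NA_character_
    ))
  bad <- per_study |> dplyr::filter(!is.na(.data$reason))
  list(
    accepted = studies |> dplyr::filter(!.data$study_id %in% bad$study_id),
    rejected = bad |> dplyr::select("study_id", "total_deaths", "n_causes", "reason")
  )
}

#' Cause-specific mortality fractions from death counts
#'
#' Divides cause-specific death counts by the all-cause total, giving a point
#' on the probability simplex over causes. This is the arithmetic that links
#' printed death counts to printed percentages (e.g. 115843 road-traffic
#' deaths of 1480227 all-cause deaths is a CSMF of 0.0783, printed as 7.8%).
#'
#' @param deaths Named numeric vector (or a data frame with `cause` and
#'   `deaths` columns) of nonnegative cause-specific death counts.
#' @param total All-cause total. Defaults to `sum(deaths)`, in which case
#'   fractions sum to 1 exactly. An explicitly supplied total may differ
#'   from the cause sum by up to 2% (published tables print independently
#'   rounded point estimates, so cause rows rarely sum exactly to the
#'   printed all-cause row); fractions are then counts over that total.
#' @return A tibble with columns `cause`, `deaths`, `fraction`; fractions sum
#'   to 1 up to floating-point tolerance.
#' @export
#' @examples
#' csmf_from_counts(c(road_traffic = 115843, other = 1364384))
csmf_from_counts <- function(deaths, total = NULL) {
  if (is.data.frame(deaths)) {
    deaths <- stats::setNames(deaths$deaths, deaths$cause)
  }
  if (any(deaths < 0)) stop("negative counts")
  s <- sum(deaths)
  if (is.null(total)) total <- s
  if (total <= 0) stop("total deaths must be positive")
  if (abs(total - s) > 0.02 * max(1, total)) {
    stop("sum of cause counts (", s, ") does not equal total (", total, ")")
  }
  tibble::tibble(
    cause = names(deaths) %||% paste0("cause", seq_along(deaths)),
    deaths = as.numeric(deaths),
    fraction = as.numeric(deaths) / total
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
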