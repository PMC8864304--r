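# Delimited-text I/O for the five input streams and the output cube.
# All tables are long-format CSV keyed by (iso_code, year, group[, cause]).

.check_schema <- function(df, required, what) {
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(what, " file missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  invisible(df)
}

.check_dup_keys <- function(df, keys, what) {
  dup <- duplicated(df[keys])
  if (any(dup)) {
    first <- df[which(dup)[1], keys, drop = FALSE]
    stop("duplicate ", what, " key: ",
         paste(sprintf("%s=%s", keys, unlist(first)), collapse = ", "),
         " (line ", which(dup)[1] + 1L, ")")
  }
  invisible(df)
}

#' Read / write study records
#'
#' Studies are long-format: one row per (study, cause) with columns
#' `study_id, iso_code, group, year_mid, cause, deaths`. An optional alias
#' table (columns `alias`, `cause`) renames synonym cause labels at read
#' time, so external vocabularies can be mapped onto the closed cause list.
#'
#' @param path File path (CSV).
#' @param aliases Optional tibble with columns `alias`, `cause`.
#' @return A tibble of study rows.
#' @export
read_studies <- function(path, aliases = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  .check_schema(df, c("study_id", "iso_code", "group", "year_mid", "cause", "deaths"),
                "studies")
  if (!is.null(aliases)) {
    idx <- match(df$cause, aliases$alias)
    df$cause[!is.na(idx)] <- aliases$cause[idx[!is.na(idx)]]
  }
  .check_dup_keys(df, c("study_id", "cause"), "study")
  df
}

#' @rdname read_studies
#' @param studies Tibble of study rows.
#' @export
write_studies <- function(studies, path) {
  readr::write_csv(studies, path)
  invisible(path)
}

#' Read / write a country-year covariate panel
#'
#' The panel is wide: one row per (iso_code, year), one column per covariate.
#' For prediction the panel must be complete (no missing cells) over the
#' requested year span; `require_years` enforces this.
#'
#' @param path File path (CSV).
#' @param require_years Optional integer vector; every country present must
#'   have a complete, non-missing row for each of these years.
#' @return A tibble.
#' @export
read_panel <- function(path, require_years = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  .check_schema(df, c("iso_code", "year"), "covariate panel")
  .check_dup_keys(df, c("iso_code", "year"), "panel")
  if (!is.null(require_years)) check_panel_complete(df, require_years)
  df
}

#' @rdname read_panel
#' @param panel Tibble as returned by `read_panel`.
#' @export
write_panel <- function(panel, path) {
  readr::write_csv(panel, path)
  invisible(path)
}

#' Check a covariate panel is complete over a year span
#'
#' @param panel Covariate panel tibble.
#' @param years Years that must be fully covered for every country present.
#' @return The panel, invisibly, or an error naming the first violation.
#' @export
check_panel_complete <- function(panel, years = 2000:2019) {
  for (iso in unique(panel$iso_code)) {
    sub <- panel[panel$iso_code == iso, ]
    miss_yr <- setdiff(years, sub$year)
    if (length(miss_yr)) {
      stop("complete time series violated: country ", iso,
           " missing year(s) ", paste(utils::head(miss_yr, 3), collapse = ", "))
    }
    sub <- sub[sub$year %in% years, ]
    if (anyNA(sub)) {
      stop("complete time series violated: country ", iso,
           " has missing covariate cell(s)")
    }
  }
  invisible(panel)
}

#' Read all-cause mortality envelopes
#'
#' Point file columns: `iso_code, year, group, deaths, rate`. If `draws_path`
#' is given it must hold columns `iso_code, year, group, draw, deaths, rate`
#' with K draws per cell; draws express envelope sampling uncertainty.
#'
#' @param path Point-estimate CSV.
#' @param draws_path Optional draws CSV.
#' @return A list with elements `point` and (optionally) `draws`.
#' @export
read_envelopes <- function(path, draws_path = NULL) {
  pt <- readr::read_csv(path, show_col_types = FALSE)
  .check_schema(pt, c("iso_code", "year", "group", "deaths", "rate"), "envelope")
  .check_dup_keys(pt, c("iso_code", "year", "group"), "envelope")
  if (any(pt$deaths < 0) || any(pt$rate < 0)) stop("negative envelope values")
  out <- list(point = pt)
  if (!is.null(draws_path)) {
    dr <- readr::read_csv(draws_path, show_col_types = FALSE)
    .check_schema(dr, c("iso_code", "year", "group", "draw", "deaths", "rate"),
                  "envelope draws")
    out$draws <- dr
  }
  out
}

#' Read single-cause death series
#'
#' Columns: `cause, iso_code, year, group, deaths, lower, upper` plus
#' optional `crisis_nature` and `in_envelope`. Absent (cause, country, year)
#' combinations are treated as zero downstream.
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_single_causes <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  .check_schema(df, c("cause", "iso_code", "year", "group", "deaths",
                      "lower", "upper"), "single-cause")
  .check_dup_keys(df, c("cause", "iso_code", "year", "group"), "single-cause")
  if (any(df$lower > df$deaths | df$deaths > df$upper)) {
    stop("single-cause series with point outside its uncertainty interval")
  }
  df
}

#' Write an estimate cube summary to CSV
#'
#' @param cube_summary Long tibble of estimates (as from [summarise_cube()]).
#' @param path Output CSV path.
#' @export
write_cube <- function(cube_summary, path) {
  readr::write_csv(cube_summary, path)
  invisible(path)
}
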