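#' Age-sex groups
#'
#' The four estimation strata used throughout the package: 5-9-year-olds of
#' both sexes, 10-14-year-olds of both sexes, 15-19-year-old females, and
#' 15-19-year-old males. Every record in the system carries exactly one of
#' these codes.
#'
#' @return Character vector of the four group codes, in age order.
#' @export
#' @examples
#' age_sex_groups()
age_sex_groups <- function() {
  c("5to9", "10to14", "15to19f", "15to19m")
}

# cause -> broad group, shared across groups
.broad_group_map <- c(
  diarrhoea              = "cmpn",
  malaria                = "cmpn",
  lri                    = "cmpn",
  tuberculosis           = "cmpn",
  hiv                    = "cmpn",
  measles                = "cmpn",
  maternal               = "cmpn",
  other_cmpn             = "cmpn",
  neoplasms              = "ncd",
  cardiovascular         = "ncd",
  digestive              = "ncd",
  congenital             = "ncd",
  other_ncd              = "ncd",
  road_traffic           = "injury",
  drowning               = "injury",
  self_harm              = "injury",
  interpersonal_violence = "injury",
  collective_violence    = "injury",
  natural_disasters      = "injury",
  other_injuries         = "injury"
)

# group-specific cause membership; causes reported for >= 3% of global deaths
# in the group. congenital only in 5-9; measles only in 5-9; maternal only in
# 15-19 females; cardiovascular, self-harm and interpersonal violence only in
# the 15-19 groups; malaria modelled only below age 15.
.group_causes <- list(
  "5to9" = c("diarrhoea", "malaria", "lri", "tuberculosis", "hiv", "measles",
             "other_cmpn", "neoplasms", "congenital", "digestive", "other_ncd",
             "drowning", "road_traffic", "collective_violence",
             "natural_disasters", "other_injuries"),
  "10to14" = c("malaria", "lri", "diarrhoea", "tuberculosis", "hiv",
               "other_cmpn", "neoplasms", "digestive", "other_ncd",
               "drowning", "road_traffic", "collective_violence",
               "natural_disasters", "other_injuries"),
  "15to19f" = c("tuberculosis", "hiv", "maternal", "other_cmpn",
                "neoplasms", "cardiovascular", "digestive", "other_ncd",
                "self_harm", "road_traffic", "interpersonal_violence",
                "drowning", "collective_violence", "natural_disasters",
                "other_injuries"),
  "15to19m" = c("tuberculosis", "hiv", "other_cmpn",
                "neoplasms", "cardiovascular", "digestive", "other_ncd",
                "self_harm", "road_traffic", "interpersonal_violence",
                "drowning", "collective_violence", "natural_disasters",
                "other_injuries")
)

# causes whose deaths come from external single-cause programme estimates and
# are squeezed into / capped against the modelled fractions rather than being
# categories of the multinomial model
.single_causes <- c("hiv", "tuberculosis", "measles",
                    "collective_violence", "natural_disasters")

# modelled composites whose final value is residual-derived: an external floor
# (median HQVR fraction) remains after single causes are carved out
.residual_causes <- c("lri", "other_cmpn")

#' Cause taxonomy for an age-sex group
#'
#' Returns the ordered cause list for one age-sex group, with each cause's
#' broad group (CMPN / NCD / injury) and its source: `modelled` (a category of
#' the multinomial model), `single_cause` (externally estimated and integrated
#' by squeezing or crisis capping), or `residual` (a modelled composite that
#' retains a residual floor after single causes are carved out of it). The
#' reference (baseline) category of the multinomial model is flagged; it is
#' always `other_cmpn`, which is present and modelled in every group.
#'
#' @param group One of [age_sex_groups()].
#' @return A tibble with columns `cause`, `broad_group`, `source`,
#'   `is_reference`, and a `group` attribute.
#' @export
#' @examples
#' cause_taxonomy("5to9")
cause_taxonomy <- function(group) {
  group <- match.arg(group, age_sex_groups())
  causes <- .group_causes[[group]]
  tax <- tibble::tibble(
    cause = causes,
    broad_group = unname(.broad_group_map[causes]),
    source = dplyr::case_when(
      causes %in% .single_causes ~ "single_cause",
      causes %in% .residual_causes ~ "residual",
      TRUE ~ "modelled"
    ),
    is_reference = causes == "other_cmpn"
  )
  attr(tax, "group") <- group
  validate_taxonomy(tax)
}

#' Validate a cause taxonomy
#'
#' Checks the structural invariants a taxonomy must satisfy: unique cause
#' labels, every cause assigned to exactly one broad group and one source,
#' and a single reference cause that is a category of the multinomial model.
#'
#' @param tax A taxonomy tibble as returned by [cause_taxonomy()].
#' @return `tax`, invisibly unchanged, or an error.
#' @export
validate_taxonomy <- function(tax) {
  stopifnot(is.data.frame(tax),
            all(c("cause", "broad_group", "source", "is_reference") %in% names(tax)))
  if (anyDuplicated(tax$cause)) {
    stop("duplicate cause labels: ",
         paste(unique(tax$cause[duplicated(tax$cause)]), collapse = ", "))
  }
  if (!all(tax$broad_group %in% c("cmpn", "ncd", "injury"))) {
    stop("broad_group must be one of cmpn/ncd/injury")
  }
  if (!all(tax$source %in% c("modelled", "single_cause", "residual"))) {
    stop("source must be one of modelled/single_cause/residual")
  }
  if (sum(tax$is_reference) != 1L) stop("exactly one reference cause required")
  if (tax$source[tax$is_reference] == "single_cause") {
    stop("reference cause must be a modelled category")
  }
  tax
}

#' Causes entering the multinomial model
#'
#' The model categories are all causes except externally estimated single
#' causes; the reference cause is placed first.
#'
#' @param tax A taxonomy tibble.
#' @return Character vector of modelled cause labels, reference first.
#' @export
modelled_causes <- function(tax) {
  m <- tax$cause[tax$source != "single_cause"]
  ref <- tax$cause[tax$is_reference]
  c(ref, setdiff(m, ref))
}

#' Region labels
#'
#' The nine world regions used for aggregation.
#'
#' @return Character vector of nine region labels.
#' @export
region_labels <- function() {
  c("sub_saharan_africa_west_central", "sub_saharan_africa_east_south",
    "middle_east_north_africa", "south_asia", "east_asia_pacific",
    "latin_america_caribbean", "north_america", "western_europe",
    "eastern_europe_central_asia")
}

#' Classify a country into an estimation stratum
#'
#' Countries with high-quality vital registration use their data directly
#' (HQVR). Remaining countries are split by mortality level: a probability of
#' death between ages 5 and 19 of at least 10 per 1000 puts a country in the
#' high-mortality modelled stratum (HMM), otherwise low-mortality modelled
#' (LMM). The boundary value 10 itself maps to HMM.
#'
#' @param prob_death_5_19 Probability of death between 5 and 19, per 1000.
#' @param hqvr_flag Logical; does the country have high-quality vital
#'   registration?
#' @return Character vector in `{"HQVR","LMM","HMM"}`, vectorised over inputs.
#' @export
#' @examples
#' classify_country(c(12, 4, 10), hqvr_flag = c(FALSE, FALSE, FALSE))
classify_country <- function(prob_death_5_19, hqvr_flag) {
  stopifnot(length(prob_death_5_19) == length(hqvr_flag) ||
              length(prob_death_5_19) == 1L || length(hqvr_flag) == 1L)
  if (any(is.na(prob_death_5_19)) || any(prob_death_5_19 < 0)) {
    stop("prob_death_5_19 must be nonnegative")
  }
  out <- ifelse(hqvr_flag, "HQVR",
                ifelse(prob_death_5_19 >= 10, "HMM", "LMM"))
  as.character(out)
}
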