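# Single-cause integration algebra: capping with pro-rata redistribution,
# squeezing external single-cause fractions into modelled composites with
# residual floors, and crisis capping. All operations preserve the simplex.

#' Cap one cause's fraction and redistribute the excess pro rata
#'
#' Replaces the fraction of `cause` by `min(fraction, cap)` and redistributes
#' the excess across the remaining causes in proportion to their current
#' fractions, so ratios among untouched causes are preserved. If the
#' remaining causes all have zero mass the excess is spread uniformly.
#'
#' @param fractions Named numeric simplex vector, or a draws matrix with one
#'   row per draw and named cause columns.
#' @param cause The cause to cap.
#' @param cap Cap in `[0, 1]` (0 zeroes the cause out entirely); for the
#'   matrix form, either a scalar or one cap per draw row.
#' @return Same shape as `fractions`, still on the simplex.
#' @export
#' @examples
#' cap_fraction(c(malaria = 0.5, diarrhoea = 0.3, other_cmpn = 0.2),
#'              "malaria", 0.2)
cap_fraction <- function(fractions, cause, cap) {
  if (any(is.na(cap)) || any(cap < 0 | cap > 1)) stop("cap must be in [0, 1]")
  if (is.matrix(fractions)) {
    m <- fractions[, cause]
    excess <- pmax(m - cap, 0)
    out <- fractions
    out[, cause] <- pmin(m, cap)
    rest <- setdiff(colnames(fractions), cause)
    rest_sum <- rowSums(fractions[, rest, drop = FALSE])
    w <- fractions[, rest, drop = FALSE] /
      ifelse(rest_sum > 0, rest_sum, 1)
    w[rest_sum == 0, ] <- 1 / length(rest)
    out[, rest] <- fractions[, rest, drop = FALSE] + excess * w
    return(out)
  }
  m <- fractions[[cause]]
  excess <- max(m - cap, 0)
  out <- fractions
  out[cause] <- min(m, cap)
  rest <- setdiff(names(fractions), cause)
  rest_sum <- sum(fractions[rest])
  if (rest_sum > 0) {
    out[rest] <- fractions[rest] + excess * fractions[rest] / rest_sum
  } else {
    out[rest] <- fractions[rest] + excess / length(rest)
  }
  out
}

#' Squeeze single causes into the modelled other-CMPN composite
#'
#' HIV/AIDS, endemic measles, and extrapulmonary tuberculosis fractions are
#' carved out of the modelled other-CMPN fraction, subject to a residual
#' floor (the minimum other-CMPN fraction, taken from high-quality vital
#' registration). If the three single causes together exceed the available
#' room (`modelled - residual`) they are scaled down pro rata; the residual
#' floor is never eaten into. The returned partition sums exactly to the
#' modelled input.
#'
#' All arguments are vectorised (equal length or length 1).
#'
#' @param modelled Modelled other-CMPN fraction(s), in `[0, 1]`.
#' @param hiv,measles_endemic,tb_extrapulmonary Single-cause fraction(s).
#' @param residual Residual other-CMPN floor (clipped to `modelled` if
#'   larger).
#' @return Tibble with columns `hiv`, `measles_endemic`, `tb_extrapulmonary`,
#'   `other_cmpn` (the post-squeeze composite, always `>=` the effective
#'   residual).
#' @export
#' @examples
#' squeeze_other_cmpn(0.30, 0.15, 0.06, 0.04, residual = 0.10)
squeeze_other_cmpn <- function(modelled, hiv, measles_endemic,
                               tb_extrapulmonary, residual) {
  if (any(c(modelled, hiv, measles_endemic, tb_extrapulmonary, residual) < 0)) {
    stop("negative input fraction")
  }
  res <- pmin(residual, modelled)
  available <- modelled - res
  s <- hiv + measles_endemic + tb_extrapulmonary
  scale <- ifelse(s > available & s > 0, available / s, 1)
  tibble::tibble(
    hiv = hiv * scale,
    measles_endemic = measles_endemic * scale,
    tb_extrapulmonary = tb_extrapulmonary * scale,
    other_cmpn = modelled - s * scale
  )
}

#' Squeeze pulmonary tuberculosis into the modelled LRI composite
#'
#' Pulmonary tuberculosis is carved out of the modelled lower-respiratory
#' tract infection fraction, with a residual LRI floor from high-quality
#' vital registration. The partition sums exactly to the modelled input.
#'
#' @param modelled Modelled LRI fraction(s).
#' @param tb_pulmonary Pulmonary TB fraction(s).
#' @param residual Residual LRI floor.
#' @return Tibble with columns `tb_pulmonary`, `lri`.
#' @export
#' @examples
#' squeeze_lri(0.10, 0.03, residual = 0.04)
squeeze_lri <- function(modelled, tb_pulmonary, residual) {
  if (any(c(modelled, tb_pulmonary, residual) < 0)) {
    stop("negative input fraction")
  }
  res <- pmin(residual, modelled)
  available <- modelled - res
  tb <- pmin(tb_pulmonary, available)
  tibble::tibble(tb_pulmonary = tb, lri = modelled - tb)
}

#' Residual LRI and other-CMPN floors from vital-registration CSMFs
#'
#' High-quality vital registration countries are assumed to have the minimum
#' fractions of lower-respiratory infections and other CMPN; the residual
#' floor for each is the median of the corresponding fraction across HQVR
#' country-years.
#'
#' @param vr Long tibble of HQVR death counts (`iso_code, year, group,
#'   cause, deaths`).
#' @return Tibble with one row per group present: `group`, `residual_lri`,
#'   `residual_other_cmpn`. Groups without a separate LRI cause get
#'   `residual_lri = 0`.
#' @export
residuals_from_vr <- function(vr) {
  if (!nrow(vr)) stop("no vital-registration rows supplied")
  fr <- vr |>
    dplyr::group_by(.data$group, .data$iso_code, .data$year) |>
    dplyr::mutate(fraction = .data$deaths / sum(.data$deaths)) |>
    dplyr::ungroup()
  fr |>
    dplyr::group_by(.data$group) |>
    dplyr::summarise(
      residual_lri = if (any(.data$cause == "lri"))
        stats::median(.data$fraction[.data$cause == "lri"]) else 0,
      residual_other_cmpn =
        stats::median(.data$fraction[.data$cause == "other_cmpn"]),
      .groups = "drop"
    )
}

#' Fraction of the envelope taken by a single-cause death series
#'
#' @param deaths Single-cause deaths (NA or missing series treated as zero).
#' @param envelope_deaths All-cause envelope deaths.
#' @return Fractions truncated to `[0, 1]`; vectorised. A zero envelope with
#'   nonzero cause deaths is an error.
#' @export
#' @examples
#' single_cause_fraction(50, 1000)
single_cause_fraction <- function(deaths, envelope_deaths) {
  deaths <- ifelse(is.na(deaths), 0, deaths)
  if (any(envelope_deaths == 0 & deaths > 0)) {
    stop("zero envelope with nonzero single-cause deaths")
  }
  f <- ifelse(envelope_deaths > 0, deaths / envelope_deaths, 0)
  pmin(pmax(f, 0), 1)
}

#' Cap a crisis fraction and insert it into a CSMF
#'
#' The raw crisis fraction is capped at the country-year's maximum plausible
#' fraction (`ghe_max`). The capped fraction is assigned to the cause
#' matching the crisis nature; when the crisis deaths are already inside the
#' all-cause envelope the non-target causes are scaled down so the result
#' stays on the simplex, and when they are outside the envelope the target
#' mass is added on top and the envelope is inflated (the returned
#' `envelope_scale` is the factor the envelope total must be multiplied by).
#'
#' @param fractions Named simplex vector, or draws matrix with cause columns.
#' @param crisis_fraction Raw crisis fraction(s) (relative to the original
#'   envelope); scalar or one per draw row.
#' @param ghe_max Cap in `[0, 1]`.
#' @param target_cause Cause receiving the crisis mass (e.g.
#'   `"collective_violence"`).
#' @param in_envelope Logical; are the crisis deaths already inside the
#'   envelope?
#' @return List with `fractions` (same shape, on the simplex) and
#'   `envelope_scale` (1 when `in_envelope`).
#' @export
#' @examples
#' apply_crisis(c(collective_violence = 0, diarrhoea = 0.6, other_cmpn = 0.4),
#'              crisis_fraction = 0.9, ghe_max = 0.3,
#'              target_cause = "collective_violence", in_envelope = TRUE)
apply_crisis <- function(fractions, crisis_fraction, ghe_max, target_cause,
                         in_envelope = TRUE) {
  if (any(ghe_max < 0 | ghe_max > 1)) stop("ghe_max must be in [0, 1]")
  f <- pmin(crisis_fraction, ghe_max)
  is_mat <- is.matrix(fractions)
  nm <- if (is_mat) colnames(fractions) else names(fractions)
  if (!target_cause %in% nm) {
    stop("unknown crisis target cause: ", target_cause)
  }
  if (in_envelope) {
    scale_env <- if (is_mat) rep(1, nrow(fractions)) else 1
  } else {
    # deaths added on top: new envelope = old * (1 + f); re-express f on the
    # inflated envelope scale
    scale_env <- 1 + f
    f <- f / (1 + f)
  }
  # existing mass (target included) is scaled by (1 - f), then f is added to
  # the target; simplex-preserving for any starting target mass
  if (is_mat) {
    out <- fractions * (1 - f)   # f recycles down columns (per-draw)
    out[, target_cause] <- out[, target_cause] + f
  } else {
    out <- fractions * (1 - f)
    out[target_cause] <- out[target_cause] + f
  }
  list(fractions = out, envelope_scale = scale_env)
}
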