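# Monte Carlo uncertainty propagation, single-cause integration at draw
# level, aggregation to regions and the globe, and trend summaries.

#' Monte Carlo draws matched to a point estimate and 95% interval
#'
#' Draws K samples from a distribution matched to a reported point estimate
#' and its 95% uncertainty interval: a lognormal quantile-matched to the
#' bounds when the lower bound is positive (recentred multiplicatively so
#' the draw median equals the point estimate), and a normal truncated at
#' zero otherwise. A degenerate interval returns the point for every draw.
#'
#' @param point Point estimate.
#' @param lower,upper 95% interval bounds (`lower <= point <= upper`).
#' @param K Number of draws.
#' @param seed Optional RNG seed.
#' @return Numeric vector of K nonnegative draws.
#' @export
#' @examples
#' quantile(sample_single_cause(100, 80, 125, 1e4, seed = 1), c(.025, .975))
sample_single_cause <- function(point, lower, upper, K, seed = NULL) {
  if (upper < lower) stop("upper < lower")
  if (!is.null(seed)) set.seed(seed)
  if (upper == lower) return(rep(point, K))
  z <- stats::qnorm(0.975)
  if (lower > 0) {
    sdlog <- (log(upper) - log(lower)) / (2 * z)
    meanlog <- (log(upper) + log(lower)) / 2
    stats::rlnorm(K, meanlog, sdlog) * point / exp(meanlog)
  } else {
    sd <- (upper - lower) / (2 * z)
    p0 <- stats::pnorm(0, point, sd)
    stats::qnorm(stats::runif(K, p0, 1), point, sd)
  }
}

.default_crisis_map <- c(collective_violence = "collective_violence",
                         natural_disaster = "natural_disasters",
                         epidemic = "measles")

#' Integrate single-cause estimates into modelled CSMF draws
#'
#' The squeezing stage, per country-year-group cell and per draw:
#' single-cause death draws (from their 95% intervals) are converted to
#' envelope fractions; HIV, endemic measles, and extrapulmonary TB are
#' squeezed pro rata into the modelled other-CMPN composite with its
#' residual floor; pulmonary TB is squeezed into the modelled LRI composite
#' where the group has one (in the 15-19 groups, which carry no separate LRI
#' cause, both TB components go into other CMPN); reported tuberculosis is
#' the sum of the two components; and crisis events are capped at the
#' country-year's maximum plausible fraction and inserted into the cause
#' matching their nature. Output draws cover the full cause taxonomy and
#' remain on the simplex.
#'
#' @param csmf A `csmf_draws` tibble over the modelled causes.
#' @param single_causes Single-cause series tibble ([read_single_causes()]
#'   layout); absent series mean zero.
#' @param envelopes Envelope list; point deaths define the fraction scale.
#' @param residuals One-row residual table for this group
#'   ([residuals_from_vr()]), or a list with `residual_lri`,
#'   `residual_other_cmpn`.
#' @param taxonomy Full cause taxonomy for the group.
#' @param crisis_caps Optional tibble `iso_code, year, ghe_max`; cells
#'   without a row are capped at 1 (no cap).
#' @param crisis_map Named map from crisis nature to target cause; natures
#'   mapping to a cause absent from the taxonomy fall back to `other_cmpn`.
#' @param seed RNG seed for the interval sampling.
#' @return A `csmf_draws` tibble over the full taxonomy, with an
#'   `env_scale` list-column (per-draw envelope inflation factors, 1 for
#'   in-envelope crises) consumed by [apply_envelope()].
#' @export
integrate_single_causes <- function(csmf, single_causes, envelopes,
                                    residuals, taxonomy,
                                    crisis_caps = NULL,
                                    crisis_map = .default_crisis_map,
                                    seed = 1) {
  stopifnot(nrow(csmf) > 0)
  set.seed(seed)
  res_lri <- residuals$residual_lri[1]
  res_oc <- residuals$residual_other_cmpn[1]
  pt <- envelopes$point
  full_causes <- taxonomy$cause
  has_lri <- "lri" %in% full_causes
  has_measles <- "measles" %in% full_causes

  sc_draws <- function(rows, which_cause, E, K) {
    r <- rows[rows$cause == which_cause, ]
    if (!nrow(r)) return(rep(0, K))
    d <- sample_single_cause(r$deaths[1], r$lower[1], r$upper[1], K)
    single_cause_fraction(d, rep(E, K))
  }

  out_draws <- vector("list", nrow(csmf))
  out_scale <- vector("list", nrow(csmf))
  for (i in seq_len(nrow(csmf))) {
    j <- csmf$iso_code[i]; y <- csmf$year[i]; g <- csmf$group[i]
    d <- csmf$draws[[i]]
    K <- nrow(d)
    E <- pt$deaths[pt$iso_code == j & pt$year == y & pt$group == g]
    if (!length(E)) stop("no envelope for ", j, " ", y, " ", g)
    rows <- single_causes[single_causes$iso_code == j &
                            single_causes$year == y &
                            single_causes$group == g, ]
    hiv <- sc_draws(rows, "hiv", E, K)
    tbp <- sc_draws(rows, "tb_pulmonary", E, K)
    tbe <- sc_draws(rows, "tb_extrapulmonary", E, K)
    mse <- if (has_measles) sc_draws(rows, "measles_endemic", E, K) else rep(0, K)

    oc_in_tbe <- if (has_lri) tbe else tbe + tbp
    oc <- squeeze_other_cmpn(d[, "other_cmpn"], hiv, mse, oc_in_tbe, res_oc)
    full <- matrix(0, K, length(full_causes),
                   dimnames = list(NULL, full_causes))
    plain <- intersect(colnames(d), full_causes)
    plain <- setdiff(plain, c("other_cmpn", "lri"))
    full[, plain] <- d[, plain]
    full[, "other_cmpn"] <- oc$other_cmpn
    full[, "hiv"] <- oc$hiv
    tb <- oc$tb_extrapulmonary
    if (has_lri) {
      lr <- squeeze_lri(d[, "lri"], tbp, res_lri)
      full[, "lri"] <- lr$lri
      tb <- tb + lr$tb_pulmonary
    }
    full[, "tuberculosis"] <- tb
    if (has_measles) full[, "measles"] <- oc$measles_endemic

    scale_env <- rep(1, K)
    cr <- rows[rows$cause == "crisis", ]
    if (nrow(cr)) {
      for (r in seq_len(nrow(cr))) {
        nature <- cr$crisis_nature[r]
        if (!nature %in% names(crisis_map)) {
          stop("unknown crisis nature: ", nature)
        }
        target <- crisis_map[[nature]]
        if (!target %in% full_causes) target <- "other_cmpn"
        raw <- single_cause_fraction(
          sample_single_cause(cr$deaths[r], cr$lower[r], cr$upper[r], K),
          rep(E, K))
        cap <- 1
        if (!is.null(crisis_caps)) {
          cc <- crisis_caps[crisis_caps$iso_code == j & crisis_caps$year == y, ]
          if (nrow(cc)) cap <- cc$ghe_max[1]
        }
        in_env <- if ("in_envelope" %in% names(cr)) isTRUE(cr$in_envelope[r]) else TRUE
        ac <- apply_crisis(full, raw, cap, target, in_envelope = in_env)
        full <- ac$fractions
        scale_env <- scale_env * ac$envelope_scale
      }
    }
    out_draws[[i]] <- full
    out_scale[[i]] <- scale_env
  }
  out <- tibble::tibble(iso_code = csmf$iso_code, year = csmf$year,
                        group = csmf$group, draws = out_draws,
                        env_scale = out_scale)
  class(out) <- c("csmf_draws", class(out))
  out
}

#' Propagate model, envelope and single-cause uncertainty into a cube
#'
#' Draw k of every output uses draw k of every input: modelled CSMF draws
#' are squeezed against single-cause draws ([integrate_single_causes()]) and
#' multiplied by envelope draws ([apply_envelope()]). Per-draw conservation
#' (cause deaths summing to the possibly crisis-augmented envelope) holds by
#' construction.
#'
#' @inheritParams integrate_single_causes
#' @param ... Passed to [integrate_single_causes()].
#' @return An `estimate_cube` with draw matrices retained.
#' @export
propagate <- function(csmf, envelopes, single_causes, residuals, taxonomy,
                      ...) {
  K <- unique(vapply(csmf$draws, nrow, integer(1)))
  if (length(K) != 1) stop("draw misalignment: cells carry differing draw counts")
  full <- integrate_single_causes(csmf, single_causes, envelopes, residuals,
                                  taxonomy, ...)
  cube <- apply_envelope(full, envelopes)
  if (!is.null(full$env_scale)) {
    for (i in seq_len(nrow(cube))) {
      s <- full$env_scale[[i]]
      cube$death_draws[[i]] <- cube$death_draws[[i]] * s
      cube$rate_draws[[i]] <- cube$rate_draws[[i]] * s
      cube$env_deaths[[i]] <- cube$env_deaths[[i]] * s
      cube$env_rate[[i]] <- cube$env_rate[[i]] * s
    }
  }
  cube
}

.ui <- function(v) {
  q <- stats::quantile(v, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
  c(point = q[1], lower = q[2], upper = q[3])
}

#' Summarise an estimate cube
#'
#' Point estimates are medians of draws; bounds are the 2.5th and 97.5th
#' percentiles, so `lower <= point <= upper` by construction.
#'
#' @param cube An `estimate_cube`.
#' @return Long tibble: one row per (iso_code, year, group, cause) with
#'   `deaths`, `rate`, `fraction` and their `_lower` / `_upper` bounds.
#' @export
summarise_cube <- function(cube) {
  purrr::pmap_dfr(
    list(cube$iso_code, cube$year, cube$group, cube$frac_draws,
         cube$death_draws, cube$rate_draws),
    function(j, y, g, fd, dd, rd) {
      causes <- colnames(fd)
      f <- apply(fd, 2, .ui); d <- apply(dd, 2, .ui); r <- apply(rd, 2, .ui)
      tibble::tibble(
        iso_code = j, year = y, group = g, cause = causes,
        deaths = d[1, ], deaths_lower = d[2, ], deaths_upper = d[3, ],
        rate = r[1, ], rate_lower = r[2, ], rate_upper = r[3, ],
        fraction = f[1, ], fraction_lower = f[2, ], fraction_upper = f[3, ])
    })
}

#' Aggregate an estimate cube to regions (or the globe)
#'
#' Cause deaths are summed per draw across the countries of each region;
#' regional fractions are regional cause deaths over regional all-cause
#' deaths, and regional rates divide summed deaths by summed person-years
#' (each country's person-years recovered per draw as deaths/rate).
#'
#' @param cube An `estimate_cube` at country level.
#' @param region_map Tibble `iso_code`, `region`, covering every country in
#'   the cube. Map every country to a single label (e.g. `"global"`) for the
#'   global aggregate.
#' @return An `estimate_cube` whose `iso_code` column holds region labels.
#' @export
aggregate_cube <- function(cube, region_map) {
  unmapped <- setdiff(unique(cube$iso_code), region_map$iso_code)
  if (length(unmapped)) {
    stop("unmapped country: ", paste(unmapped, collapse = ", "))
  }
  cube$region <- region_map$region[match(cube$iso_code, region_map$iso_code)]
  groups <- dplyr::distinct(cube, .data$region, .data$year, .data$group)
  rows <- purrr::pmap(groups, function(region, year, group) {
    sub <- cube[cube$region == region & cube$year == year &
                  cube$group == group, ]
    dd <- Reduce(`+`, sub$death_draws)
    ed <- Reduce(`+`, sub$env_deaths)
    py <- Reduce(`+`, purrr::map2(sub$env_deaths, sub$env_rate,
                                  function(d, r) d / r))
    fd <- dd / ed
    rd <- dd / py
    list(frac_draws = fd, death_draws = dd, rate_draws = rd,
         env_deaths = ed, env_rate = ed / py)
  })
  out <- tibble::tibble(
    iso_code = groups$region, year = groups$year, group = groups$group,
    frac_draws = purrr::map(rows, "frac_draws"),
    death_draws = purrr::map(rows, "death_draws"),
    rate_draws = purrr::map(rows, "rate_draws"),
    env_deaths = purrr::map(rows, "env_deaths"),
    env_rate = purrr::map(rows, "env_rate"))
  class(out) <- c("estimate_cube", class(out))
  out
}

#' Broad cause-group totals
#'
#' Sums cause-specific deaths into the three broad groups (communicable,
#' maternal, perinatal and nutritional conditions; non-communicable
#' diseases; injuries) and expresses each as a fraction of all-cause deaths.
#'
#' @param counts Tibble with `cause` and `deaths` columns (e.g. one group's
#'   printed global table, or a [summarise_cube()] slice).
#' @param taxonomy Optional taxonomy restricting and ordering the causes;
#'   defaults to the package-wide cause -> broad-group map.
#' @return Tibble `broad_group`, `deaths`, `fraction`.
#' @export
#' @examples
#' broad_group_totals(tibble::tibble(cause = c("malaria", "road_traffic"),
#'                                   deaths = c(60, 40)))
broad_group_totals <- function(counts, taxonomy = NULL) {
  map <- if (is.null(taxonomy)) .broad_group_map else
    stats::setNames(taxonomy$broad_group, taxonomy$cause)
  unknown <- setdiff(counts$cause, names(map))
  if (length(unknown)) stop("cause(s) without broad group: ",
                            paste(unknown, collapse = ", "))
  counts |>
    dplyr::mutate(broad_group = map[.data$cause]) |>
    dplyr::group_by(.data$broad_group) |>
    dplyr::summarise(deaths = sum(.data$deaths), .groups = "drop") |>
    dplyr::mutate(fraction = .data$deaths / sum(.data$deaths))
}

#' Annual average rate of reduction
#'
#' The log-scale average yearly percent decline of a mortality rate between
#' two years: `100 * log(rate_t1 / rate_t2) / (t2 - t1)`. Positive values
#' are declines; a rate that halves over 19 years gives 3.65.
#'
#' @param rate_t1,rate_t2 Rates at the earlier and later year (positive).
#' @param t1,t2 The two years (`t2 > t1`).
#' @return AARR in percent per year; vectorised.
#' @export
#' @examples
#' compute_aarr(2, 1, 2000, 2019)
compute_aarr <- function(rate_t1, rate_t2, t1, t2) {
  if (any(t2 <= t1)) stop("t2 must exceed t1")
  if (any(rate_t1 <= 0 | rate_t2 <= 0)) stop("rates must be positive")
  100 * log(rate_t1 / rate_t2) / (t2 - t1)
}

#' AARR table with uncertainty from an estimate cube
#'
#' Computes the AARR per cause between two years of a (typically aggregated)
#' cube, per draw, and summarises with a median and 95% interval. Natural
#' disasters are excluded (idiosyncratic year-to-year series), as are causes
#' with nonpositive rates in either year.
#'
#' @param cube An `estimate_cube` (one `iso_code` level, e.g. "global").
#' @param t1,t2 Years to compare (defaults 2000 and 2019).
#' @param exclude Causes to drop (default `"natural_disasters"`).
#' @return Tibble `iso_code, group, cause, aarr, aarr_lower, aarr_upper`.
#' @export
aarr_table <- function(cube, t1 = 2000, t2 = 2019,
                       exclude = "natural_disasters") {
  cells <- dplyr::distinct(cube, .data$iso_code, .data$group)
  purrr::pmap_dfr(cells, function(iso_code, group) {
    r1 <- cube$rate_draws[cube$iso_code == iso_code & cube$year == t1 &
                            cube$group == group][[1]]
    r2 <- cube$rate_draws[cube$iso_code == iso_code & cube$year == t2 &
                            cube$group == group][[1]]
    causes <- setdiff(colnames(r1), exclude)
    purrr::map_dfr(causes, function(cs) {
      a <- r1[, cs]; b <- r2[, cs]
      ok <- a > 0 & b > 0
      if (!any(ok)) return(NULL)
      v <- compute_aarr(a[ok], b[ok], t1, t2)
      q <- .ui(v)
      tibble::tibble(iso_code = iso_code, group = group, cause = cs,
                     aarr = q[1], aarr_lower = q[2], aarr_upper = q[3])
    })
  })
}

#' Input-source share table
#'
#' Shares of all-cause deaths by estimation stratum (the fraction of global
#' deaths whose causes come from each input source).
#'
#' @param deaths_by_stratum Named numeric vector or tibble (`stratum`,
#'   `deaths`).
#' @return Tibble `stratum`, `deaths`, `percent`; percents sum to 100.
#' @export
#' @examples
#' source_share_table(c(HQVR = 119802, LMM = 84414, HMM = 1221418,
#'                      passthrough = 54593))
source_share_table <- function(deaths_by_stratum) {
  if (is.data.frame(deaths_by_stratum)) {
    deaths_by_stratum <- stats::setNames(deaths_by_stratum$deaths,
                                         deaths_by_stratum$stratum)
  }
  tibble::tibble(
    stratum = names(deaths_by_stratum),
    deaths = as.numeric(deaths_by_stratum),
    percent = 100 * as.numeric(deaths_by_stratum) / sum(deaths_by_stratum)
  )
}
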