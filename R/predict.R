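# CSMF prediction for every country-year, malaria structural rules, and
# conversion of fractions to deaths and rates via all-cause envelopes.
# Draw matrices are carried in a nested tibble (`csmf_draws`): one row per
# (iso_code, year, group) with a draws list-column of [n_draw x n_cause]
# matrices.

#' Posterior CSMF draws for one country-year
#'
#' Applies the stored covariate standardisation, adds the country's random
#' effect when the country contributed training data (zero otherwise), and
#' maps each posterior draw through the softmax.
#'
#' @param fit A `csmf_fit`.
#' @param covariates Covariate panel.
#' @param iso_code,year The cell to predict.
#' @return Matrix `[n_draw x n_cause]` of simplex rows, cause columns named.
#' @export
posterior_csmf_draws <- function(fit, covariates, iso_code, year) {
  P <- length(fit$covariate_names)
  S <- nrow(fit$b0)
  C <- length(fit$causes)
  eta <- matrix(0, S, C, dimnames = list(NULL, fit$causes))
  eta[, -1] <- fit$b0
  if (P > 0) {
    row <- covariates[covariates$iso_code == iso_code &
                        covariates$year == year, fit$covariate_names]
    if (nrow(row) != 1 || anyNA(row)) {
      stop("no complete covariate row for ", iso_code, " ", year)
    }
    x <- (as.numeric(row[1, ]) - fit$center) / fit$scale
    for (p in seq_len(P)) {
      eta[, -1] <- eta[, -1] + fit$beta[, , p, drop = TRUE] * x[p]
    }
  }
  if (iso_code %in% fit$countries) {
    eta[, -1] <- eta[, -1] + fit$u[, iso_code, ]
  }
  ex <- exp(eta - apply(eta, 1, max))
  ex / rowSums(ex)
}

#' Predict CSMF draws over a country-year grid
#'
#' @param fit A `csmf_fit`.
#' @param covariates Covariate panel (must cover every requested cell).
#' @param iso_codes Countries to predict; default every country in the panel.
#' @param years Years to predict; default every panel year.
#' @return A `csmf_draws` tibble: `iso_code`, `year`, `group`, and a `draws`
#'   list-column of `[n_draw x n_cause]` simplex matrices.
#' @export
predict_csmf <- function(fit, covariates, iso_codes = NULL, years = NULL) {
  iso_codes <- iso_codes %||% unique(covariates$iso_code)
  years <- years %||% sort(unique(covariates$year))
  missing_iso <- setdiff(iso_codes, unique(covariates$iso_code))
  if (length(missing_iso)) {
    stop("country missing from covariate panel: ",
         paste(missing_iso, collapse = ", "))
  }
  grid <- tidyr::expand_grid(iso_code = iso_codes, year = years)
  draws <- purrr::map2(grid$iso_code, grid$year, function(j, y) {
    posterior_csmf_draws(fit, covariates, j, y)
  })
  out <- tibble::tibble(iso_code = grid$iso_code, year = grid$year,
                        group = fit$group, draws = draws)
  class(out) <- c("csmf_draws", class(out))
  out
}

#' Apply malaria structural rules to CSMF draws
#'
#' In the 15-19 groups malaria is never modelled (it is absent from the
#' taxonomy, hence structurally zero). For the 5-9 and 10-14 groups: where
#' malaria incidence is zero the malaria fraction is set to zero and its
#' mass redistributed pro rata over the remaining causes; elsewhere the
#' malaria fraction is capped at the corresponding country-year under-5
#' malaria fraction, with the excess redistributed pro rata.
#'
#' @param csmf A `csmf_draws` tibble.
#' @param constraints Tibble with `iso_code`, `under5_cap`,
#'   `incidence_zero`, optionally `year` (year-specific constraints).
#' @return The adjusted `csmf_draws` (unchanged when malaria is not a
#'   column).
#' @export
apply_malaria_rules <- function(csmf, constraints) {
  if (!nrow(csmf) || !"malaria" %in% colnames(csmf$draws[[1]])) return(csmf)
  by_year <- "year" %in% names(constraints)
  csmf$draws <- purrr::pmap(
    list(csmf$iso_code, csmf$year, csmf$draws),
    function(j, y, d) {
      con <- constraints[constraints$iso_code == j, ]
      if (by_year) con <- con[con$year == y, ]
      if (!nrow(con)) return(d)
      cap <- if (con$incidence_zero[1]) 0 else con$under5_cap[1]
      cap_fraction(d, "malaria", cap)
    })
  csmf
}

#' Convert CSMF draws to deaths and rates via the all-cause envelope
#'
#' Pairs CSMF draw k with envelope draw k (recycling envelope draws when
#' fewer are available) and multiplies: cause deaths are the fraction times
#' envelope deaths, cause rates the fraction times the envelope rate, so
#' cause deaths sum exactly to the envelope in every draw.
#'
#' @param csmf A `csmf_draws` tibble (fractions over the full cause list).
#' @param envelopes Envelope list (`point` and optionally `draws` tibbles,
#'   see [read_envelopes()]); without draws the point values are used for
#'   every draw.
#' @return An `estimate_cube`: tibble with `iso_code`, `year`, `group`,
#'   list-columns `frac_draws`, `death_draws`, `rate_draws` (matrices
#'   `[n_draw x n_cause]`) and vectors `env_deaths`, `env_rate` of per-draw
#'   envelope totals.
#' @export
apply_envelope <- function(csmf, envelopes) {
  pt <- envelopes$point
  dr <- envelopes$draws
  rows <- purrr::pmap(
    list(csmf$iso_code, csmf$year, csmf$group, csmf$draws),
    function(j, y, g, d) {
      K <- nrow(d)
      p <- pt[pt$iso_code == j & pt$year == y & pt$group == g, ]
      if (!nrow(p)) stop("no envelope for ", j, " ", y, " ", g)
      if (p$deaths < 0 || p$rate < 0) stop("negative envelope")
      if (!is.null(dr)) {
        e <- dr[dr$iso_code == j & dr$year == y & dr$group == g, ]
        idx <- ((seq_len(K) - 1) %% nrow(e)) + 1
        ed <- e$deaths[idx]; er <- e$rate[idx]
      } else {
        ed <- rep(p$deaths, K); er <- rep(p$rate, K)
      }
      list(deaths = d * ed, rates = d * er, env_deaths = ed, env_rate = er)
    })
  out <- tibble::tibble(
    iso_code = csmf$iso_code, year = csmf$year, group = csmf$group,
    frac_draws = csmf$draws,
    death_draws = purrr::map(rows, "deaths"),
    rate_draws = purrr::map(rows, "rates"),
    env_deaths = purrr::map(rows, "env_deaths"),
    env_rate = purrr::map(rows, "env_rate")
  )
  class(out) <- c("estimate_cube", class(out))
  out
}
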