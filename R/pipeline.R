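# End-to-end orchestration: validation -> model fit (per stratum) ->
# prediction -> malaria rules -> single-cause squeezing -> envelopes ->
# aggregation and trend summaries. HQVR countries bypass the model: their
# observed CSMFs pass straight to envelope application.

#' Run the full CSMF estimation pipeline for one age-sex group
#'
#' @param studies Long study tibble (model inputs, modelled causes).
#' @param covariates Covariate panel covering every country-year to predict.
#' @param envelopes Envelope list (`point`, optionally `draws`).
#' @param single_causes Single-cause series tibble.
#' @param countries Country metadata: `iso_code`, `region`, `category`
#'   (HQVR/LMM/HMM).
#' @param vr Long HQVR death counts (`iso_code, year, group, cause,
#'   deaths`), used for pass-through CSMFs and residual floors.
#' @param group Age-sex group (default taken from the studies).
#' @param lambda LASSO penalty; if `NULL`, selected from `lambda_grid` by
#'   cross-validation.
#' @param lambda_grid,n_folds Cross-validation settings when `lambda` is
#'   `NULL`.
#' @param malaria_constraints Tibble `iso_code, under5_cap, incidence_zero`
#'   (optionally `year`); `NULL` skips the malaria rules.
#' @param crisis_caps Tibble `iso_code, year, ghe_max`; `NULL` means no cap.
#' @param years Years to estimate (default the envelope years).
#' @param per_stratum Fit LMM and HMM strata separately (default TRUE); a
#'   stratum without studies borrows the other stratum's fit.
#' @param chains,warmup,iter MCMC controls passed to [fit_csmf_model()].
#' @param seed Master seed for MCMC, folds, and interval sampling.
#' @return A list of class `csmf_pipeline`: `cube` (country-level
#'   `estimate_cube`), `regional`, `global`, `summary` (country summaries),
#'   `aarr` (global trend table), `source_shares`, `fits`, `residuals`,
#'   `lambda`.
#' @export
run_csmf_pipeline <- function(studies, covariates, envelopes, single_causes,
                              countries, vr, group = NULL,
                              lambda = NULL, lambda_grid = c(1, 10, 100),
                              n_folds = 5, malaria_constraints = NULL,
                              crisis_caps = NULL, years = NULL,
                              per_stratum = TRUE,
                              chains = 4, warmup = 1000, iter = 1000,
                              seed = 1) {
  group <- group %||% unique(studies$group)[1]
  taxonomy <- cause_taxonomy(group)
  years <- years %||% sort(unique(envelopes$point$year))

  ok <- validate_studies(studies, taxonomy)
  studies <- ok$accepted
  residuals <- residuals_from_vr(vr[vr$group == group, ])

  cv <- NULL
  if (is.null(lambda)) {
    cv <- select_lambda(studies, covariates, taxonomy, lambda_grid,
                        n_folds = n_folds, seed = seed, chains = chains,
                        warmup = warmup, iter = iter)
    lambda <- cv$lambda
  }

  fit_for <- list()
  if (per_stratum) {
    for (cat in c("LMM", "HMM")) {
      iso_cat <- countries$iso_code[countries$category == cat]
      st <- studies[studies$iso_code %in% iso_cat, ]
      if (nrow(st)) {
        fit_for[[cat]] <- fit_csmf_model(st, covariates, taxonomy, lambda,
                                         chains = chains, warmup = warmup,
                                         iter = iter, seed = seed)
      }
    }
    if (is.null(fit_for$LMM) && is.null(fit_for$HMM)) {
      stop("no studies in any modelled stratum")
    }
    if (is.null(fit_for$LMM)) fit_for$LMM <- fit_for$HMM
    if (is.null(fit_for$HMM)) fit_for$HMM <- fit_for$LMM
  } else {
    f <- fit_csmf_model(studies, covariates, taxonomy, lambda,
                        chains = chains, warmup = warmup, iter = iter,
                        seed = seed)
    fit_for <- list(LMM = f, HMM = f)
  }

  modelled_iso <- countries$iso_code[countries$category != "HQVR"]
  pred <- dplyr::bind_rows(lapply(c("LMM", "HMM"), function(cat) {
    iso_cat <- intersect(modelled_iso,
                         countries$iso_code[countries$category == cat])
    if (!length(iso_cat)) return(NULL)
    predict_csmf(fit_for[[cat]], covariates, iso_codes = iso_cat,
                 years = years)
  }))
  class(pred) <- c("csmf_draws", class(pred))
  if (!is.null(malaria_constraints)) {
    pred <- apply_malaria_rules(pred, malaria_constraints)
  }
  K <- nrow(pred$draws[[1]])
  cube_mod <- propagate(pred, envelopes, single_causes, residuals, taxonomy,
                        crisis_caps = crisis_caps, seed = seed + 1)

  # HQVR pass-through: observed full-cause CSMFs, envelope uncertainty only
  hq <- vr[vr$group == group &
             vr$iso_code %in% countries$iso_code[countries$category == "HQVR"], ]
  cube_hq <- NULL
  if (nrow(hq)) {
    cells <- dplyr::distinct(hq, .data$iso_code, .data$year)
    obs <- purrr::pmap(cells, function(iso_code, year) {
      sub <- hq[hq$iso_code == iso_code & hq$year == year, ]
      f <- stats::setNames(sub$deaths / sum(sub$deaths), sub$cause)
      f <- f[taxonomy$cause]
      matrix(rep(f, each = K), K, length(f),
             dimnames = list(NULL, taxonomy$cause))
    })
    hq_draws <- tibble::tibble(iso_code = cells$iso_code, year = cells$year,
                               group = group, draws = obs)
    class(hq_draws) <- c("csmf_draws", class(hq_draws))
    cube_hq <- apply_envelope(hq_draws, envelopes)
  }
  cube <- dplyr::bind_rows(cube_mod, cube_hq)
  class(cube) <- c("estimate_cube", class(cube))

  region_map <- countries[, c("iso_code", "region")]
  regional <- aggregate_cube(cube, region_map)
  global <- aggregate_cube(cube, tibble::tibble(
    iso_code = countries$iso_code, region = "global"))

  env_latest <- envelopes$point[envelopes$point$year == max(years) &
                                  envelopes$point$group == group, ]
  shares <- env_latest |>
    dplyr::left_join(countries[, c("iso_code", "category")], by = "iso_code") |>
    dplyr::group_by(stratum = .data$category) |>
    dplyr::summarise(deaths = sum(.data$deaths), .groups = "drop")

  structure(list(
    cube = cube, regional = regional, global = global,
    summary = summarise_cube(cube),
    aarr = aarr_table(global, t1 = min(years), t2 = max(years)),
    source_shares = source_share_table(shares),
    fits = fit_for, residuals = residuals, lambda = lambda, cv = cv,
    group = group, taxonomy = taxonomy, seed = seed
  ), class = "csmf_pipeline")
}

#' @export
print.csmf_pipeline <- function(x, ...) {
  cat("<csmf_pipeline> group", x$group, "-", nrow(x$cube), "country-year cells,",
      length(unique(x$cube$iso_code)), "countries\n")
  cat("  lambda =", x$lambda, " residual other-CMPN =",
      signif(x$residuals$residual_other_cmpn[1], 3), "\n")
  invisible(x)
}

#' Glance at a pipeline run
#'
#' @param x A `csmf_pipeline`.
#' @param ... Unused.
#' @return One-row tibble of run-level facts.
#' @method glance csmf_pipeline
#' @export
glance.csmf_pipeline <- function(x, ...) {
  tibble::tibble(
    group = x$group, lambda = x$lambda,
    n_countries = length(unique(x$cube$iso_code)),
    n_years = length(unique(x$cube$year)),
    n_causes = nrow(x$taxonomy),
    n_draws = nrow(x$cube$frac_draws[[1]]),
    residual_lri = x$residuals$residual_lri[1],
    residual_other_cmpn = x$residuals$residual_other_cmpn[1]
  )
}

#' Tidy a pipeline run
#'
#' Returns the country-level estimate summary (medians and 95% intervals
#' for deaths, rates and fractions).
#'
#' @param x A `csmf_pipeline`.
#' @param ... Unused.
#' @return Long tibble, see [summarise_cube()].
#' @method tidy csmf_pipeline
#' @export
tidy.csmf_pipeline <- function(x, ...) x$summary
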