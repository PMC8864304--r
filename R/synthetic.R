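# Synthetic-data generator: emulates the five input streams (studies,
# covariate panel, envelopes, single-cause series, country metadata) from a
# known ground truth so every downstream stage is testable end to end.

softmax <- function(eta) {
  e <- exp(eta - max(eta))
  e / sum(e)
}

#' Generate a ground-truth specification
#'
#' Draws the true data-generating process for one age-sex group: sparse
#' multinomial-logistic coefficients over `P` covariates, country random
#' effects with SD `sigma_u`, country metadata (region, stratum, population),
#' smooth declining all-cause mortality envelopes, single-cause fraction
#' surfaces (HIV, pulmonary/extrapulmonary TB, endemic measles where in
#' scope), malaria caps, and sparse crisis events. Defaults describe the
#' study conditions the pipeline is validated under: 30 countries of which 12
#' contribute studies, 20 years (2000-2019), random-effect SD 0.07, and
#' engineered stress cases (a country whose single-cause fractions exceed the
#' modelled room, a crisis fraction above its cap) so that squeezing and
#' capping are exercised.
#'
#' @param n_countries Number of countries (default 30).
#' @param n_study_countries Countries contributing studies (default 12).
#' @param n_hqvr Countries with high-quality vital registration (default 6).
#' @param P Number of covariates (default 6).
#' @param sparsity Fraction of covariate effects that are exactly zero per
#'   cause (default 0.5).
#' @param group Age-sex group the truth describes (default "5to9").
#' @param sigma_u SD of country random effects (default 0.07).
#' @param beta_scale Magnitude of nonzero covariate effects (default 0.5).
#' @param years Calendar years covered (default 2000:2019).
#' @param seed RNG seed; the whole specification is reproducible from it.
#' @return An object of class `truth_spec`.
#' @export
make_truth <- function(n_countries = 30, n_study_countries = 12, n_hqvr = 6,
                       P = 6, sparsity = 0.5, group = "5to9",
                       sigma_u = 0.07, beta_scale = 0.5,
                       years = 2000:2019, seed = 1) {
  stopifnot(P >= 1, sparsity >= 0, sparsity <= 1,
            n_study_countries + n_hqvr <= n_countries)
  set.seed(seed)
  tax <- cause_taxonomy(group)
  causes <- modelled_causes(tax)
  C <- length(causes)

  iso <- sprintf("C%02d", seq_len(n_countries))
  regions <- rep(region_labels(), length.out = n_countries)
  hqvr <- seq_len(n_countries) <= n_hqvr
  # prob of death 5-19 per 1000: HQVR low, others straddle the 10/1000 cutoff
  prob_death <- ifelse(hqvr, stats::runif(n_countries, 1, 4),
                       stats::runif(n_countries, 4, 30))
  category <- classify_country(prob_death, hqvr)
  # modelled countries contributing studies: prefer HMM then LMM
  modelled_idx <- which(!hqvr)
  study_idx <- modelled_idx[order(category[modelled_idx] != "HMM",
                                  modelled_idx)][seq_len(n_study_countries)]
  countries <- tibble::tibble(
    iso_code = iso, region = regions, category = category,
    prob_death_5_19 = prob_death,
    population = round(stats::rlnorm(n_countries, log(2e6), 0.6)),
    has_studies = seq_len(n_countries) %in% study_idx
  )

  # sparse coefficients; reference cause (first) is identically zero and is
  # represented implicitly
  n_nonzero <- round((1 - sparsity) * P)
  beta0 <- stats::rnorm(C - 1, 0, 0.7)
  beta <- matrix(0, C - 1, P,
                 dimnames = list(causes[-1], paste0("x", seq_len(P))))
  support <- matrix(FALSE, C - 1, P, dimnames = dimnames(beta))
  for (c in seq_len(C - 1)) {
    if (n_nonzero > 0) {
      on <- sample.int(P, n_nonzero)
      support[c, on] <- TRUE
      beta[c, on] <- sample(c(-1, 1), n_nonzero, replace = TRUE) * beta_scale
    }
  }
  u <- matrix(stats::rnorm(n_countries * (C - 1), 0, sigma_u),
              n_countries, C - 1, dimnames = list(iso, causes[-1]))

  # envelope trajectories: log-linear decline in the all-cause rate
  rate0 <- 1 + prob_death / 3          # deaths per 1000 person-years in 2000
  decline <- stats::runif(n_countries, 0.01, 0.04)

  # single-cause fraction surfaces (constant over years, per country);
  # country in study_idx[1] gets fractions engineered to exceed the room in
  # the modelled composites, exercising the pro-rata squeeze
  sc_causes <- c("hiv_frac", "tb_pulmonary_frac", "tb_extrapulmonary_frac",
                 "measles_endemic_frac")
  sc <- tibble::tibble(
    iso_code = iso,
    hiv_frac = stats::runif(n_countries, 0.005, 0.04),
    tb_pulmonary_frac = stats::runif(n_countries, 0.005, 0.03),
    tb_extrapulmonary_frac = stats::runif(n_countries, 0.002, 0.015),
    measles_endemic_frac = if (group == "5to9")
      stats::runif(n_countries, 0.002, 0.02) else 0
  )
  squeeze_iso <- iso[study_idx[1]]
  sc[sc$iso_code == squeeze_iso,
     c("hiv_frac", "tb_extrapulmonary_frac")] <- list(0.30, 0.10)

  # malaria constraints (5-14 groups only): under-5 cap per country, binding
  # for one engineered country; a couple of zero-incidence countries
  has_malaria <- "malaria" %in% causes
  malaria <- tibble::tibble(
    iso_code = iso,
    under5_cap = stats::runif(n_countries, 0.15, 0.35),
    incidence_zero = FALSE
  )
  if (has_malaria) {
    malaria$incidence_zero[utils::tail(modelled_idx, 2)] <- TRUE
    malaria$under5_cap[study_idx[2]] <- 0.02   # binding cap
  }

  # crisis events: sparse; one raw fraction far above its cap
  crisis_iso <- iso[c(study_idx[3], study_idx[4], n_hqvr + 1)]
  crisis <- tibble::tibble(
    iso_code = crisis_iso,
    year = years[pmax(1, ceiling(length(years) * c(0.25, 0.6, 0.4)))],
    nature = c("collective_violence", "natural_disaster", "collective_violence"),
    frac_raw = c(0.08, 0.05, 0.90),
    ghe_max = c(0.30, 0.30, 0.30),
    in_envelope = c(TRUE, TRUE, TRUE)
  )

  structure(list(
    group = group, taxonomy = tax, causes = causes, P = P,
    beta0 = beta0, beta = beta, support = support,
    sigma_u = sigma_u, u = u,
    countries = countries, years = years,
    rate0 = stats::setNames(rate0, iso),
    decline = stats::setNames(decline, iso),
    single_cause_fracs = sc, malaria = malaria, crisis = crisis,
    seed = seed
  ), class = "truth_spec")
}

#' True modelled-cause CSMF at a covariate row
#'
#' Evaluates the generating multinomial-logistic surface: linear predictors
#' eta_c = beta0_c + x . beta_c + u_{j,c} for non-reference causes (0 for the
#' reference) mapped through the softmax onto the simplex.
#'
#' @param truth A `truth_spec`.
#' @param x Numeric covariate vector of length `truth$P` (standardised scale).
#' @param iso_code Country whose random effect applies; `NULL` for u = 0.
#' @return Named numeric simplex over the modelled causes.
#' @export
true_csmf <- function(truth, x, iso_code = NULL) {
  stopifnot(length(x) == truth$P)
  u <- if (is.null(iso_code)) 0 else truth$u[iso_code, ]
  eta <- c(0, truth$beta0 + as.numeric(truth$beta %*% x) + u)
  stats::setNames(softmax(eta), truth$causes)
}

#' Simulate a covariate panel
#'
#' Covariates evolve as stationary AR(1) series over years within each
#' country (autocorrelation `rho`, standard-normal marginals), mimicking
#' slowly varying country indicators.
#'
#' @param truth A `truth_spec`.
#' @param rho Year-to-year autocorrelation (default 0.9).
#' @param seed RNG seed.
#' @return Tibble with `iso_code`, `year`, and covariate columns `x1..xP`.
#' @export
simulate_covariates <- function(truth, rho = 0.9, seed = truth$seed + 1) {
  set.seed(seed)
  iso <- truth$countries$iso_code
  yrs <- truth$years
  P <- truth$P
  rows <- purrr::map_dfr(iso, function(j) {
    x <- matrix(0, length(yrs), P)
    x[1, ] <- stats::rnorm(P)
    for (t in seq_along(yrs)[-1]) {
      x[t, ] <- rho * x[t - 1, ] + sqrt(1 - rho^2) * stats::rnorm(P)
    }
    colnames(x) <- paste0("x", seq_len(P))
    dplyr::bind_cols(tibble::tibble(iso_code = j, year = yrs),
                     tibble::as_tibble(x))
  })
  rows
}

#' Simulate multi-cause death-count studies
#'
#' Draws study records from the true CSMF surface: each study-contributing
#' country gets `studies_per_country` studies at random years, each with a
#' total death count ~ Poisson(`mean_size`) (floored at `min_size`), and
#' cause counts multinomial around the country-year's true modelled CSMF.
#'
#' @param truth A `truth_spec`.
#' @param panel Covariate panel from [simulate_covariates()].
#' @param studies_per_country Studies per contributing country (default 4).
#' @param mean_size Mean total deaths per study (default 185, the scale of
#'   real verbal-autopsy inputs for this age band).
#' @param min_size Floor on study size (default 15, the inclusion threshold).
#' @param seed RNG seed.
#' @return Long tibble of study rows (`study_id, iso_code, group, year_mid,
#'   cause, deaths`).
#' @export
simulate_studies <- function(truth, panel, studies_per_country = 4,
                             mean_size = 185, min_size = 15,
                             seed = truth$seed + 2) {
  set.seed(seed)
  iso <- truth$countries$iso_code[truth$countries$has_studies]
  out <- list()
  k <- 0L
  for (j in iso) {
    yrs <- sample(truth$years, studies_per_country, replace = TRUE)
    for (y in yrs) {
      k <- k + 1L
      x <- as.numeric(panel[panel$iso_code == j & panel$year == y,
                            paste0("x", seq_len(truth$P))])
      p <- true_csmf(truth, x, j)
      n <- max(min_size, stats::rpois(1, mean_size))
      cnt <- as.integer(stats::rmultinom(1, n, p))
      out[[k]] <- tibble::tibble(
        study_id = sprintf("S%03d", k), iso_code = j, group = truth$group,
        year_mid = y, cause = truth$causes, deaths = cnt
      )
    }
  }
  dplyr::bind_rows(out)
}

#' Simulate all-cause mortality envelopes with uncertainty draws
#'
#' Each country's all-cause mortality rate declines log-linearly over the
#' period; deaths = rate/1000 x population. Draws are multiplicative
#' lognormal perturbations centred on the point values, emulating envelope
#' sampling uncertainty.
#'
#' @param truth A `truth_spec`.
#' @param K Number of draws per cell (default 200; must be >= 2).
#' @param cv Coefficient of variation of the draws (default 0.03; 0 gives
#'   degenerate draws equal to the point values).
#' @param seed RNG seed.
#' @return A list with `point` and `draws` tibbles (see [read_envelopes()]).
#' @export
simulate_envelopes <- function(truth, K = 200, cv = 0.03,
                               seed = truth$seed + 3) {
  stopifnot(K >= 2)
  set.seed(seed)
  grid <- tidyr::expand_grid(iso_code = truth$countries$iso_code,
                             year = truth$years)
  grid$group <- truth$group
  t0 <- min(truth$years)
  grid$rate <- unname(truth$rate0[grid$iso_code] *
                        exp(-truth$decline[grid$iso_code] * (grid$year - t0)))
  pop <- stats::setNames(truth$countries$population,
                         truth$countries$iso_code)
  grid$deaths <- unname(grid$rate / 1000 * pop[grid$iso_code])
  sdlog <- sqrt(log(1 + cv^2))
  draws <- tidyr::expand_grid(grid, draw = seq_len(K))
  mult <- if (cv > 0) {
    stats::rlnorm(nrow(draws), -sdlog^2 / 2, sdlog)
  } else rep(1, nrow(draws))
  draws$deaths <- draws$deaths * mult
  draws$rate <- draws$rate * mult
  list(point = grid[, c("iso_code", "year", "group", "deaths", "rate")],
       draws = draws[, c("iso_code", "year", "group", "draw", "deaths", "rate")])
}

#' Simulate single-cause death series
#'
#' Converts the truth's single-cause fraction surfaces into death series on
#' the envelope scale, with 95% uncertainty intervals (multiplicative,
#' roughly +-20%), and appends crisis events (with their nature, cap and
#' in-envelope flag). Some series are engineered to exceed the room in the
#' modelled composites so the pro-rata squeeze is exercised.
#'
#' @param truth A `truth_spec`.
#' @param envelopes Envelope list from [simulate_envelopes()].
#' @param ui_rel Half-width of the relative 95% interval (default 0.2).
#' @param seed RNG seed (perturbs the reported points around truth).
#' @return Tibble in [read_single_causes()] layout.
#' @export
simulate_single_causes <- function(truth, envelopes, ui_rel = 0.2,
                                   seed = truth$seed + 4) {
  set.seed(seed)
  pt <- envelopes$point
  sc <- dplyr::left_join(pt, truth$single_cause_fracs, by = "iso_code")
  long <- dplyr::bind_rows(
    dplyr::transmute(sc, cause = "hiv", .data$iso_code, .data$year,
                     .data$group, deaths = .data$deaths * .data$hiv_frac),
    dplyr::transmute(sc, cause = "tb_pulmonary", .data$iso_code, .data$year,
                     .data$group, deaths = .data$deaths * .data$tb_pulmonary_frac),
    dplyr::transmute(sc, cause = "tb_extrapulmonary", .data$iso_code,
                     .data$year, .data$group,
                     deaths = .data$deaths * .data$tb_extrapulmonary_frac),
    dplyr::transmute(sc, cause = "measles_endemic", .data$iso_code,
                     .data$year, .data$group,
                     deaths = .data$deaths * .data$measles_endemic_frac)
  )
  long <- long[long$deaths > 0, ]
  long$lower <- long$deaths * (1 - ui_rel)
  long$upper <- long$deaths * (1 + ui_rel)
  long$crisis_nature <- NA_character_
  long$in_envelope <- TRUE

  cr <- dplyr::inner_join(truth$crisis, pt,
                          by = c("iso_code", "year")) |>
    dplyr::transmute(cause = "crisis", .data$iso_code, .data$year,
                     .data$group, deaths = .data$frac_raw * .data$deaths,
                     lower = .data$frac_raw * .data$deaths * (1 - ui_rel),
                     upper = .data$frac_raw * .data$deaths * (1 + ui_rel),
                     crisis_nature = .data$nature,
                     in_envelope = .data$in_envelope)
  dplyr::bind_rows(long, cr)
}

#' Simulate high-quality vital-registration CSMFs
#'
#' HQVR countries bypass the model: their observed cause distributions are
#' used directly and also supply the residual LRI / other-CMPN floors. The
#' generator draws large multinomial samples (default 5000 deaths per
#' country-year) from the true full-cause CSMF.
#'
#' @param truth A `truth_spec`.
#' @param panel Covariate panel.
#' @param deaths_per_year Multinomial size per country-year (default 5000).
#' @param seed RNG seed.
#' @return Long tibble (`iso_code, year, group, cause, deaths`).
#' @export
simulate_vr <- function(truth, panel, deaths_per_year = 5000,
                        seed = truth$seed + 5) {
  set.seed(seed)
  full <- true_full_csmf(truth, panel)
  hq <- truth$countries$iso_code[truth$countries$category == "HQVR"]
  full <- full[full$iso_code %in% hq, ]
  purrr::pmap_dfr(full, function(iso_code, year, group, fractions) {
    cnt <- as.integer(stats::rmultinom(1, deaths_per_year, fractions))
    tibble::tibble(iso_code = iso_code, year = year, group = group,
                   cause = names(fractions), deaths = cnt)
  })
}

#' True full-cause CSMFs for every country-year
#'
#' Composes the ground truth for the complete cause list: the modelled-cause
#' softmax surface with the true malaria constraints applied, true
#' single-cause fractions carved out of the composites by the same squeeze
#' algebra the pipeline uses (the algebra itself is deterministic and is
#' verified against an independent oracle elsewhere), and true crisis
#' fractions capped and inserted. This is the reference surface for
#' parameter-recovery and coverage checks.
#'
#' @param truth A `truth_spec`.
#' @param panel Covariate panel.
#' @param residual_lri,residual_other_cmpn Residual floors used in the truth
#'   composition (defaults 0.02 and 0.01).
#' @return Tibble with `iso_code, year, group` and a `fractions` list-column
#'   of named simplex vectors over the full taxonomy.
#' @export
true_full_csmf <- function(truth, panel, residual_lri = 0.02,
                           residual_other_cmpn = 0.01) {
  xcols <- paste0("x", seq_len(truth$P))
  sc <- truth$single_cause_fracs
  has_lri <- "lri" %in% truth$causes
  rows <- panel[panel$iso_code %in% truth$countries$iso_code, ]
  fr <- purrr::map2(rows$iso_code, rows$year, function(j, y) {
    x <- as.numeric(rows[rows$iso_code == j & rows$year == y, xcols][1, ])
    m <- true_csmf(truth, x, j)
    # malaria structural rules
    if ("malaria" %in% names(m)) {
      mal <- truth$malaria[truth$malaria$iso_code == j, ]
      cap <- if (mal$incidence_zero) 0 else mal$under5_cap
      m <- cap_fraction(m, "malaria", cap)
    }
    s <- sc[sc$iso_code == j, ]
    # carve single causes out of the composites
    oc <- squeeze_other_cmpn(m[["other_cmpn"]], s$hiv_frac,
                             s$measles_endemic_frac,
                             if (has_lri) s$tb_extrapulmonary_frac
                             else s$tb_extrapulmonary_frac + s$tb_pulmonary_frac,
                             residual_other_cmpn)
    out <- m[setdiff(names(m), c("other_cmpn", "lri"))]
    out["other_cmpn"] <- oc$other_cmpn
    out["hiv"] <- oc$hiv
    tb <- oc$tb_extrapulmonary
    if (has_lri) {
      lr <- squeeze_lri(m[["lri"]], s$tb_pulmonary_frac, residual_lri)
      out["lri"] <- lr$lri
      tb <- tb + lr$tb_pulmonary
    }
    out["tuberculosis"] <- tb
    if ("measles" %in% truth$taxonomy$cause) out["measles"] <- oc$measles_endemic
    out["collective_violence"] <- 0
    out["natural_disasters"] <- 0
    # crisis truth
    cr <- truth$crisis[truth$crisis$iso_code == j & truth$crisis$year == y, ]
    if (nrow(cr)) {
      for (i in seq_len(nrow(cr))) {
        f <- min(cr$frac_raw[i], cr$ghe_max[i])
        target <- switch(cr$nature[i],
                         collective_violence = "collective_violence",
                         natural_disaster = "natural_disasters",
                         epidemic = if ("measles" %in% names(out)) "measles"
                                    else "other_cmpn")
        keep <- setdiff(names(out), target)
        out[keep] <- out[keep] * (1 - f) / sum(out[keep])
        out[target] <- out[target] + f
      }
    }
    out[truth$taxonomy$cause]
  })
  tibble::tibble(iso_code = rows$iso_code, year = rows$year,
                 group = truth$group, fractions = fr)
}

#' Simulate a complete scenario
#'
#' One call generating every input stream the pipeline needs, with the truth
#' attached for validation.
#'
#' @param seed Master RNG seed.
#' @param K Envelope draw count.
#' @param ... Passed to [make_truth()].
#' @return A list: `truth`, `panel`, `studies`, `vr`, `envelopes`,
#'   `single_causes`, `countries`.
#' @export
simulate_scenario <- function(seed = 1, K = 200, ...) {
  truth <- make_truth(seed = seed, ...)
  panel <- simulate_covariates(truth)
  studies <- simulate_studies(truth, panel)
  envelopes <- simulate_envelopes(truth, K = K)
  single_causes <- simulate_single_causes(truth, envelopes)
  vr <- simulate_vr(truth, panel)
  list(truth = truth, panel = panel, studies = studies, vr = vr,
       envelopes = envelopes, single_causes = single_causes,
       countries = truth$countries)
}
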