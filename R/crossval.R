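# Penalty selection by cross-validated out-of-sample RMSE.

#' Out-of-sample RMSE of CSMF predictions
#'
#' Root mean squared error over held-out (study x cause) cells between the
#' posterior-mean predicted fraction and the observed study fraction.
#' Held-out studies from countries absent from the training data are
#' predicted with a zero random effect.
#'
#' @param fit A `csmf_fit`.
#' @param heldout_studies Long tibble of held-out studies (must be disjoint
#'   from the training set).
#' @param covariates Covariate panel.
#' @return Nonnegative scalar RMSE.
#' @export
oos_rmse <- function(fit, heldout_studies, covariates) {
  if (!nrow(heldout_studies)) stop("empty held-out set")
  wide <- heldout_studies |>
    tidyr::pivot_wider(id_cols = c("study_id", "iso_code", "year_mid"),
                       names_from = "cause", values_from = "deaths",
                       values_fill = 0)
  for (cs in setdiff(fit$causes, names(wide))) wide[[cs]] <- 0L
  y <- as.matrix(wide[, fit$causes])
  obs <- y / rowSums(y)
  pred <- t(vapply(seq_len(nrow(wide)), function(i) {
    colMeans(posterior_csmf_draws(fit, covariates, wide$iso_code[i],
                                  wide$year_mid[i]))
  }, numeric(length(fit$causes))))
  sqrt(mean((pred - obs)^2))
}

#' Country-stratified study-level cross-validation folds
#'
#' Folds partition studies (the fold unit is the study, never the row), with
#' assignment stratified by country so each country's studies spread across
#' folds. Reproducible from the seed.
#'
#' @param studies Long study tibble.
#' @param n_folds Number of folds.
#' @param seed RNG seed.
#' @return Tibble `study_id`, `fold`.
#' @export
make_cv_folds <- function(studies, n_folds, seed = 1) {
  set.seed(seed)
  ids <- studies |>
    dplyr::distinct(.data$study_id, .data$iso_code) |>
    dplyr::group_by(.data$iso_code) |>
    dplyr::mutate(fold = sample(rep_len(sample.int(n_folds), dplyr::n()))) |>
    dplyr::ungroup()
  ids[, c("study_id", "fold")]
}

#' Select the LASSO penalty by cross-validation
#'
#' For each penalty on the grid, fits the model on each training split and
#' measures out-of-fold RMSE; returns the penalty minimising the mean RMSE.
#' Ties (within `tie_tol`) are broken toward the larger penalty, i.e. more
#' shrinkage.
#'
#' @param studies,covariates,taxonomy As for [fit_csmf_model()].
#' @param lambda_grid Nonempty vector of candidate penalties.
#' @param n_folds Number of folds (default 5).
#' @param seed Seed controlling fold assignment and MCMC.
#' @param tie_tol Absolute RMSE difference treated as a tie (default 1e-8).
#' @param ... Passed to [fit_csmf_model()] (e.g. reduced MCMC settings).
#' @return List: `lambda` (selected), `rmse_table` (tibble `lambda`,
#'   `mean_rmse`, and per-fold columns), `folds`.
#' @export
select_lambda <- function(studies, covariates, taxonomy, lambda_grid,
                          n_folds = 5, seed = 1, tie_tol = 1e-8, ...) {
  if (!length(lambda_grid)) stop("empty lambda grid")
  folds <- make_cv_folds(studies, n_folds, seed = seed)
  st <- dplyr::left_join(studies, folds, by = "study_id")
  res <- purrr::map_dfr(sort(lambda_grid), function(lam) {
    fold_rmse <- vapply(sort(unique(folds$fold)), function(k) {
      train <- st[st$fold != k, ]
      test <- st[st$fold == k, ]
      if (!nrow(test)) return(NA_real_)
      fit <- fit_csmf_model(train, covariates, taxonomy, lambda = lam,
                            seed = seed, ...)
      oos_rmse(fit, test, covariates)
    }, numeric(1))
    tibble::tibble(lambda = lam, mean_rmse = mean(fold_rmse, na.rm = TRUE),
                   fold_rmse = list(fold_rmse))
  })
  best_rmse <- min(res$mean_rmse)
  # ties broken toward more shrinkage
  best <- max(res$lambda[res$mean_rmse <= best_rmse + tie_tol])
  list(lambda = best, rmse_table = res, folds = folds)
}
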