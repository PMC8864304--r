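# Bayesian multinomial-logistic LASSO with country random effects.
# Likelihood, per study i over modelled causes c (reference first):
#   deaths_i ~ multinomial(total_i, p_i),  p_ic = softmax(eta_ic)
#   eta_i1 = 0;  eta_ic = beta0_c + x_i . beta_c + u_{j(i),c}  (c > 1)
# Priors: beta_cp ~ double-exponential(0, lambda)  [the Bayesian LASSO],
#   intercepts weakly informative Normal(0, 10^2), u_jc ~ Normal(0, sigma_u),
#   random effects only for countries contributing studies.

.jags_model_code <- function(P) {
  covariate_term <- if (P > 0) " + inprod(x[i,1:P], beta[c-1,1:P])" else ""
  beta_prior <- if (P > 0) paste0(
    "    for (p in 1:P) { beta[c-1,p] ~ ddexp(0, lambda) }\n") else ""
  paste0(
    "model {\n",
    "  for (i in 1:N) {\n",
    "    y[i,1:C] ~ dmulti(prob[i,1:C], n[i])\n",
    "    for (c in 1:C) {\n",
    "      prob[i,c] <- expeta[i,c] / sum(expeta[i,1:C])\n",
    "      expeta[i,c] <- exp(eta[i,c])\n",
    "    }\n",
    "    eta[i,1] <- 0\n",
    "    for (c in 2:C) {\n",
    "      eta[i,c] <- beta0[c-1]", covariate_term, " + u[country[i], c-1]\n",
    "    }\n",
    "  }\n",
    "  for (c in 2:C) {\n",
    "    beta0[c-1] ~ dnorm(0, 0.01)\n",
    beta_prior,
    "  }\n",
    "  for (j in 1:J) {\n",
    "    for (c in 2:C) { u[j,c-1] ~ dnorm(0, tau_u) }\n",
    "  }\n",
    "  tau_u <- pow(sigma_u, -2)\n",
    "}\n")
}

# split-chain potential scale reduction factor (rank-plain Rhat); works for a
# single chain by splitting it in half
split_rhat <- function(draws_matrix, n_chains) {
  S <- nrow(draws_matrix)
  per <- S %/% n_chains
  halves <- list()
  for (ch in seq_len(n_chains)) {
    idx <- (ch - 1) * per + seq_len(per)
    half <- per %/% 2
    halves[[2 * ch - 1]] <- draws_matrix[idx[seq_len(half)], , drop = FALSE]
    halves[[2 * ch]] <- draws_matrix[idx[half + seq_len(half)], , drop = FALSE]
  }
  m <- length(halves)
  nh <- nrow(halves[[1]])
  means <- sapply(halves, colMeans)
  vars <- sapply(halves, function(h) apply(h, 2, stats::var))
  if (is.null(dim(means))) { means <- rbind(means); vars <- rbind(vars) }
  B <- nh * apply(means, 1, stats::var)
  W <- rowMeans(vars)
  sqrt(((nh - 1) / nh * W + B / nh) / W)
}

#' Fit the Bayesian multinomial-logistic LASSO
#'
#' Fits the CSMF model to accepted study records: a multinomial likelihood
#' over the modelled causes with a softmax link, covariate coefficients under
#' a double-exponential (Laplace) shrinkage prior with rate `lambda`, weakly
#' informative intercepts, and country random effects with fixed SD
#' `sigma_u` for countries contributing studies. Covariates are standardised
#' on the training data and the transform is stored for prediction.
#'
#' @param studies Long study tibble (accepted rows; see [validate_studies()]).
#' @param covariates Covariate panel with `iso_code`, `year`, and covariate
#'   columns.
#' @param taxonomy Taxonomy for the studies' group.
#' @param lambda LASSO penalty (rate of the Laplace prior); must be > 0.
#' @param sigma_u Random-effect SD (default 0.07).
#' @param covariate_names Covariate columns to use; default every `x*` column
#'   of `covariates`. May be empty for an intercept-only model.
#' @param chains,warmup,iter MCMC controls: number of chains, adaptation +
#'   burn-in iterations, and kept iterations per chain (defaults 4, 1000,
#'   1000).
#' @param seed RNG seed; fixed seed and chain count give identical draws.
#' @param quiet Suppress JAGS progress output (default TRUE).
#' @return An object of class `csmf_fit`: posterior draw matrices for
#'   intercepts (`b0`), covariate coefficients (`beta`), and random effects
#'   (`u`), plus the cause order, covariate scaling, training country list,
#'   and split-chain Rhat per parameter. Non-convergence (Rhat > 1.1) raises
#'   a warning, not an error.
#' @export
fit_csmf_model <- function(studies, covariates, taxonomy, lambda,
                           sigma_u = 0.07, covariate_names = NULL,
                           chains = 4, warmup = 1000, iter = 1000,
                           seed = 1, quiet = TRUE) {
  stopifnot(nrow(studies) > 0, lambda > 0, sigma_u > 0)
  causes <- modelled_causes(taxonomy)
  C <- length(causes)
  bad <- setdiff(unique(studies$cause), causes)
  if (length(bad)) stop("study cause(s) outside modelled taxonomy: ",
                        paste(bad, collapse = ", "))
  if (is.null(covariate_names)) {
    covariate_names <- grep("^x", names(covariates), value = TRUE)
  }
  P <- length(covariate_names)

  wide <- studies |>
    tidyr::pivot_wider(id_cols = c("study_id", "iso_code", "year_mid"),
                       names_from = "cause", values_from = "deaths",
                       values_fill = 0)
  for (cs in setdiff(causes, names(wide))) wide[[cs]] <- 0L
  y <- as.matrix(wide[, causes])
  n <- rowSums(y)
  iso_train <- sort(unique(wide$iso_code))
  country <- match(wide$iso_code, iso_train)

  if (P > 0) {
    key <- dplyr::left_join(
      wide[, c("iso_code", "year_mid")],
      covariates[, c("iso_code", "year", covariate_names)],
      by = c(iso_code = "iso_code", year_mid = "year"))
    xr <- as.matrix(key[, covariate_names])
    if (anyNA(xr)) {
      stop("missing covariate row for study (iso_code, year_mid): ",
           wide$iso_code[which(rowSums(is.na(xr)) > 0)[1]])
    }
    center <- colMeans(xr)
    scale_ <- apply(xr, 2, stats::sd)
    scale_[scale_ == 0] <- 1
    x <- sweep(sweep(xr, 2, center), 2, scale_, "/")
  } else {
    x <- matrix(0, nrow(y), 0); center <- numeric(0); scale_ <- numeric(0)
  }

  data <- list(y = y, n = n, N = nrow(y), C = C, country = country,
               J = length(iso_train), lambda = lambda, sigma_u = sigma_u)
  if (P > 0) { data$x <- x; data$P <- P }
  inits <- lapply(seq_len(chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed + ch))
  })
  jm <- rjags::jags.model(textConnection(.jags_model_code(P)), data = data,
                          inits = inits, n.chains = chains,
                          n.adapt = max(100, warmup %/% 2), quiet = quiet)
  stats::update(jm, n.iter = warmup, progress.bar = "none")
  monitors <- c("beta0", if (P > 0) "beta", "u")
  samp <- rjags::coda.samples(jm, monitors, n.iter = iter,
                              progress.bar = "none")
  mat <- do.call(rbind, lapply(samp, as.matrix))

  b0 <- mat[, paste0("beta0[", seq_len(C - 1), "]"), drop = FALSE]
  colnames(b0) <- causes[-1]
  beta <- array(0, dim = c(nrow(mat), C - 1, P),
                dimnames = list(NULL, causes[-1], covariate_names))
  if (P > 0) {
    for (p in seq_len(P)) {
      beta[, , p] <- mat[, paste0("beta[", seq_len(C - 1), ",", p, "]")]
    }
  }
  u <- array(0, dim = c(nrow(mat), length(iso_train), C - 1),
             dimnames = list(NULL, iso_train, causes[-1]))
  for (j in seq_along(iso_train)) {
    u[, j, ] <- mat[, paste0("u[", j, ",", seq_len(C - 1), "]")]
  }

  rhat <- split_rhat(mat, chains)
  if (any(rhat > 1.1, na.rm = TRUE)) {
    warning(sum(rhat > 1.1, na.rm = TRUE),
            " parameter(s) with split-chain Rhat > 1.1; ",
            "consider longer chains")
  }

  structure(list(
    b0 = b0, beta = beta, u = u, causes = causes,
    covariate_names = covariate_names, center = center, scale = scale_,
    countries = iso_train, lambda = lambda, sigma_u = sigma_u,
    group = attr(taxonomy, "group") %||% unique(studies$group)[1],
    taxonomy = taxonomy, rhat = rhat, chains = chains, iter = iter,
    seed = seed, n_studies = nrow(y)
  ), class = "csmf_fit")
}

#' @export
print.csmf_fit <- function(x, ...) {
  cat("<csmf_fit>", length(x$causes), "modelled causes,",
      length(x$covariate_names), "covariates,", x$n_studies, "studies\n")
  cat("  lambda =", x$lambda, " sigma_u =", x$sigma_u,
      " draws =", nrow(x$b0), " max Rhat =",
      round(max(x$rhat, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Tidy a fitted CSMF model
#'
#' One row per parameter (intercepts, covariate coefficients, random
#' effects) with posterior mean, SD, 95% credible interval, and Rhat.
#'
#' @param x A `csmf_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy csmf_fit
#' @export
tidy.csmf_fit <- function(x, ...) {
  summ <- function(v) {
    q <- stats::quantile(v, c(0.025, 0.975), names = FALSE)
    tibble::tibble(estimate = mean(v), std.error = stats::sd(v),
                   conf.low = q[1], conf.high = q[2])
  }
  rows <- list()
  for (cs in colnames(x$b0)) {
    rows[[length(rows) + 1]] <- dplyr::bind_cols(
      tibble::tibble(term = "(Intercept)", cause = cs), summ(x$b0[, cs]))
  }
  for (cs in dimnames(x$beta)[[2]]) {
    for (p in dimnames(x$beta)[[3]]) {
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(term = p, cause = cs), summ(x$beta[, cs, p]))
    }
  }
  for (j in dimnames(x$u)[[2]]) {
    for (cs in dimnames(x$u)[[3]]) {
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(term = paste0("u[", j, "]"), cause = cs),
        summ(x$u[, j, cs]))
    }
  }
  dplyr::bind_rows(rows)
}

#' Glance at a fitted CSMF model
#'
#' @param x A `csmf_fit`.
#' @param ... Unused.
#' @return One-row tibble with penalty, dimensions and convergence summary.
#' @method glance csmf_fit
#' @export
glance.csmf_fit <- function(x, ...) {
  tibble::tibble(
    lambda = x$lambda, sigma_u = x$sigma_u,
    n_studies = x$n_studies, n_causes = length(x$causes),
    n_covariates = length(x$covariate_names),
    n_draws = nrow(x$b0), chains = x$chains,
    max_rhat = max(x$rhat, na.rm = TRUE)
  )
}
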