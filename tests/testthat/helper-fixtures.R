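# Shared fixtures, built once per test run.

# small scenario: fewer countries/years than the default study conditions so
# model-dependent tests stay quick; generator parameters otherwise default
small_scenario <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_scenario(seed = 421, K = 80, n_countries = 12,
                                  n_study_countries = 6, n_hqvr = 3,
                                  P = 3, group = "5to9",
                                  years = 2000:2009)
    }
    cache
  }
})

# a reduced-MCMC fit on the small scenario, shared across tests
small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- small_scenario()
      cache <<- fit_csmf_model(sc$studies, sc$panel, sc$truth$taxonomy,
                               lambda = 5, chains = 2, warmup = 300,
                               iter = 300, seed = 99)
    }
    cache
  }
})

# hand-built degenerate posterior: every draw identical, so predictions are
# exact and independent of any sampler
fake_fit <- function(probs, causes = names(probs), n_draw = 4) {
  eta <- log(probs / probs[1])
  structure(list(
    b0 = matrix(rep(eta[-1], each = n_draw), n_draw, length(causes) - 1,
                dimnames = list(NULL, causes[-1])),
    beta = array(0, c(n_draw, length(causes) - 1, 0),
                 dimnames = list(NULL, causes[-1], NULL)),
    u = array(0, c(n_draw, 0, length(causes) - 1),
              dimnames = list(NULL, NULL, causes[-1])),
    causes = causes, covariate_names = character(0),
    center = numeric(0), scale = numeric(0), countries = character(0),
    lambda = 1, sigma_u = 0.07, group = "5to9", rhat = 1,
    chains = 1, iter = n_draw, seed = 1, n_studies = 0
  ), class = "csmf_fit")
}

random_simplex <- function(n, k) {
  m <- matrix(stats::rexp(n * k), n, k)
  m / rowSums(m)
}
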