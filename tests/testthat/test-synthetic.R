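test_that("truth specification is reproducible and honours sparsity", {
  t1 <- make_truth(seed = 11, P = 10, sparsity = 0.5, n_countries = 8,
                   n_study_countries = 3, n_hqvr = 2)
  t2 <- make_truth(seed = 11, P = 10, sparsity = 0.5, n_countries = 8,
                   n_study_countries = 3, n_hqvr = 2)
  expect_identical(t1, t2)
  expect_true(all(rowSums(t1$beta != 0) == 5))  # 5 of 10 effects per cause
  t0 <- make_truth(seed = 11, P = 4, sparsity = 1, n_countries = 8,
                   n_study_countries = 3, n_hqvr = 2)
  expect_true(all(t0$beta == 0))
})

test_that("true_csmf is the softmax of the linear predictors", {
  tr <- make_truth(seed = 5, P = 3, n_countries = 6, n_study_countries = 2,
                   n_hqvr = 2)
  x <- c(0.3, -1.2, 0.8)
  p <- true_csmf(tr, x, "C03")
  # independent recomputation
  eta <- c(0, tr$beta0 + as.numeric(tr$beta %*% x) + tr$u["C03", ])
  expect_equal(unname(p), unname(exp(eta) / sum(exp(eta))), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)

  # symmetry: zeroed intercepts, effects and random effects give uniform
  tr0 <- tr
  tr0$beta0[] <- 0; tr0$beta[] <- 0; tr0$u[] <- 0
  expect_equal(unname(true_csmf(tr0, x, "C01")),
               rep(1 / length(tr$causes), length(tr$causes)))
  # softmax monotonicity: raising one intercept raises that fraction
  tr_up <- tr
  tr_up$beta0[2] <- tr_up$beta0[2] + 0.5
  expect_gt(true_csmf(tr_up, x, "C03")[3], p[3])
})

test_that("simulated studies are multinomial around the true surface", {
  sc <- small_scenario()
  tr <- sc$truth
  expect_identical(simulate_studies(tr, sc$panel, seed = 3),
                   simulate_studies(tr, sc$panel, seed = 3))
  # a single-death study has exactly one nonzero cause
  one <- simulate_studies(tr, sc$panel, studies_per_country = 1,
                          mean_size = 0, min_size = 1, seed = 4)
  totals <- tapply(one$deaths, one$study_id, sum)
  expect_true(all(totals == 1))
  expect_true(all(tapply(one$deaths > 0, one$study_id, sum) == 1))
  # law of large numbers: one huge study's fractions approach the truth
  big <- simulate_studies(tr, sc$panel, studies_per_country = 1,
                          mean_size = 2e5, seed = 5)
  s1 <- big[big$study_id == "S001", ]
  x <- as.numeric(sc$panel[sc$panel$iso_code == s1$iso_code[1] &
                             sc$panel$year == s1$year_mid[1],
                           paste0("x", 1:tr$P)])
  p <- true_csmf(tr, x, s1$iso_code[1])
  n <- sum(s1$deaths)
  obs <- s1$deaths / n
  expect_true(all(abs(obs - p[s1$cause]) <=
                    3 * sqrt(p[s1$cause] * (1 - p[s1$cause]) / n) + 1e-9))
})

test_that("simulated envelopes decline smoothly and draws centre on points", {
  sc <- small_scenario()
  tr <- sc$truth
  tr0 <- tr
  tr0$decline[] <- 0
  env0 <- simulate_envelopes(tr0, K = 5)
  one <- env0$point[env0$point$iso_code == "C01", ]
  expect_equal(unname(diff(one$deaths)), rep(0, nrow(one) - 1),
               tolerance = 1e-12)

  env <- simulate_envelopes(tr, K = 4000, cv = 0.05)
  cell <- env$draws[env$draws$iso_code == "C02" & env$draws$year == 2003, ]
  pt <- env$point$deaths[env$point$iso_code == "C02" & env$point$year == 2003]
  se <- stats::sd(cell$deaths) / sqrt(nrow(cell))
  expect_lt(abs(mean(cell$deaths) - pt), 3 * se + 1e-9)
  # zero-noise draws are degenerate at the point
  envd <- simulate_envelopes(tr, K = 3, cv = 0)
  expect_equal(envd$draws$deaths[1:3],
               rep(envd$point$deaths[1], 3), tolerance = 1e-12)
})

test_that("the generator engineers squeezing and capping stress cases", {
  sc <- small_scenario()
  tr <- sc$truth
  # a crisis with raw fraction far above its cap exists by construction
  expect_true(any(tr$crisis$frac_raw > tr$crisis$ghe_max))
  # one country's single-cause fractions exceed plausible composite room
  expect_true(any(tr$single_cause_fracs$hiv_frac >= 0.25))
  # malaria: at least one binding cap and one zero-incidence country
  expect_true(any(tr$malaria$incidence_zero))
  expect_true(any(tr$malaria$under5_cap <= 0.02))
})
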