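test_that("other-CMPN squeeze matches worked arithmetic", {
  # room available: single causes pass through unchanged
  r1 <- squeeze_other_cmpn(0.30, 0.05, 0.03, 0.02, residual = 0.10)
  expect_equal(unlist(r1), c(hiv = 0.05, measles_endemic = 0.03,
                             tb_extrapulmonary = 0.02, other_cmpn = 0.20),
               tolerance = 1e-12)
  # overflow: scaled by available/s = 0.20/0.25 = 0.8
  r2 <- squeeze_other_cmpn(0.30, 0.15, 0.06, 0.04, residual = 0.10)
  expect_equal(unlist(r2), c(hiv = 0.12, measles_endemic = 0.048,
                             tb_extrapulmonary = 0.032, other_cmpn = 0.10),
               tolerance = 1e-12)
  # all-zero single causes leave the composite whole
  r3 <- squeeze_other_cmpn(0.30, 0, 0, 0, residual = 0.10)
  expect_equal(r3$other_cmpn, 0.30)
  expect_error(squeeze_other_cmpn(0.3, -0.1, 0, 0, 0.1), "negative")
})

test_that("LRI squeeze matches worked arithmetic", {
  r1 <- squeeze_lri(0.10, 0.03, residual = 0.04)
  expect_equal(unlist(r1), c(tb_pulmonary = 0.03, lri = 0.07),
               tolerance = 1e-12)
  r2 <- squeeze_lri(0.10, 0.09, residual = 0.04)
  expect_equal(unlist(r2), c(tb_pulmonary = 0.06, lri = 0.04),
               tolerance = 1e-12)
  expect_equal(squeeze_lri(0.10, 0, residual = 0.04)$lri, 0.10)
})

test_that("malaria capping redistributes excess pro rata", {
  f <- c(malaria = 0.5, diarrhoea = 0.3, other_cmpn = 0.2)
  expect_equal(cap_fraction(f, "malaria", 0.2),
               c(malaria = 0.2, diarrhoea = 0.48, other_cmpn = 0.32),
               tolerance = 1e-12)
  expect_equal(cap_fraction(c(malaria = 0.1, diarrhoea = 0.9), "malaria", 0.2),
               c(malaria = 0.1, diarrhoea = 0.9))
  # zero incidence: renormalisation p/(1-m)
  z <- cap_fraction(f, "malaria", 0)
  expect_equal(unname(z), c(0, 0.3 / 0.5, 0.2 / 0.5), tolerance = 1e-12)
  # degenerate all-malaria input spreads uniformly
  d <- cap_fraction(c(malaria = 1, a = 0, b = 0), "malaria", 0.4)
  expect_equal(unname(d), c(0.4, 0.3, 0.3), tolerance = 1e-12)
  expect_error(cap_fraction(f, "malaria", 1.5), "cap")
})

test_that("crisis capping follows the stated insertion rule", {
  f <- c(collective_violence = 0, diarrhoea = 0.6, other_cmpn = 0.4)
  r <- apply_crisis(f, 0.9, 0.3, "collective_violence", in_envelope = TRUE)
  expect_equal(r$fractions,
               c(collective_violence = 0.3, diarrhoea = 0.42,
                 other_cmpn = 0.28), tolerance = 1e-12)
  expect_equal(r$envelope_scale, 1)
  expect_equal(apply_crisis(f, 0, 0.3, "collective_violence")$fractions, f)
  # cap above raw: raw used
  r2 <- apply_crisis(f, 0.1, 0.3, "collective_violence")
  expect_equal(r2$fractions[["collective_violence"]], 0.1)
  # outside the envelope: mass added on top, envelope inflated
  r3 <- apply_crisis(f, 0.25, 1, "collective_violence", in_envelope = FALSE)
  expect_equal(r3$envelope_scale, 1.25)
  expect_equal(sum(r3$fractions), 1, tolerance = 1e-12)
  # target deaths = f' * E' = (0.25/1.25) * 1.25E = 0.25E, as supplied
  expect_equal(r3$fractions[["collective_violence"]] * r3$envelope_scale,
               0.25, tolerance = 1e-12)
  expect_error(apply_crisis(f, 0.1, 0.3, "unknown_cause"), "unknown")
})

test_that("residual floors come from the HQVR median", {
  vr1 <- tidyr::expand_grid(iso_code = c("A", "B", "C"), year = 2000,
                            group = "5to9", cause = c("lri", "other_cmpn",
                                                      "rest"))
  vr1$deaths <- rep(c(10, 20, 70), 3)
  r <- residuals_from_vr(vr1)
  expect_equal(r$residual_lri, 0.10)
  expect_equal(r$residual_other_cmpn, 0.20)
  # {1%, 2%, 3%} -> 2%
  vr2 <- vr1
  vr2$deaths <- c(1, 19, 80, 2, 18, 80, 3, 17, 80)
  expect_equal(residuals_from_vr(vr2)$residual_lri, 0.02)
  # random fractions vs an independent sort-based median
  set.seed(9)
  fr <- random_simplex(7, 3)
  vr3 <- tidyr::expand_grid(iso_code = sprintf("X%d", 1:7), year = 2000,
                            group = "5to9",
                            cause = c("lri", "other_cmpn", "rest"))
  vr3$deaths <- as.vector(t(fr)) * 1000
  sorted <- sort(fr[, 1])
  expect_equal(residuals_from_vr(vr3)$residual_lri, sorted[4],
               tolerance = 1e-12)
  expect_error(residuals_from_vr(vr1[0, ]), "no vital")
})

test_that("single-cause fractions are envelope ratios truncated to [0,1]", {
  expect_equal(single_cause_fraction(50, 1000), 0.05)
  expect_equal(single_cause_fraction(NA, 1000), 0)
  expect_equal(single_cause_fraction(1200, 1000), 1)
  expect_error(single_cause_fraction(5, 0), "zero envelope")
  expect_equal(single_cause_fraction(0, 0), 0)
})

test_that("squeeze partitions conserve mass, floors and ratios on random input", {
  set.seed(31)
  n <- 500
  m <- runif(n, 0.05, 0.6)
  res <- runif(n, 0, 0.9) * m
  hiv <- runif(n, 0, 0.4); mse <- runif(n, 0, 0.2); tbe <- runif(n, 0, 0.2)
  out <- squeeze_other_cmpn(m, hiv, mse, tbe, res)
  expect_equal(out$hiv + out$measles_endemic + out$tb_extrapulmonary +
                 out$other_cmpn, m, tolerance = 1e-12)
  expect_true(all(out$other_cmpn >= res - 1e-12))
  # pro-rata scaling preserves ratios among the squeezed causes
  ok <- hiv > 0 & tbe > 0
  expect_equal(out$hiv[ok] / out$tb_extrapulmonary[ok], hiv[ok] / tbe[ok],
               tolerance = 1e-9)

  tbp <- runif(n, 0, 0.3)
  lr <- squeeze_lri(m, tbp, res)
  expect_equal(lr$tb_pulmonary + lr$lri, m, tolerance = 1e-12)
  expect_true(all(lr$lri >= res - 1e-12))
})
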