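test_that("interval sampling matches stated bounds and is reproducible", {
  expect_equal(sample_single_cause(7, 7, 7, 5), rep(7, 5))
  d <- sample_single_cause(100, 80, 125, 1e5, seed = 2)
  q <- quantile(d, c(0.025, 0.975), names = FALSE)
  expect_lt(abs(q[1] - 80) / 80, 0.10)
  expect_lt(abs(q[2] - 125) / 125, 0.10)
  expect_equal(median(d), 100, tolerance = 2)
  expect_identical(sample_single_cause(100, 80, 125, 10, seed = 5),
                   sample_single_cause(100, 80, 125, 10, seed = 5))
  # zero lower bound: truncated normal, all draws nonnegative
  d0 <- sample_single_cause(10, 0, 40, 1e4, seed = 3)
  expect_true(all(d0 >= 0))
  expect_error(sample_single_cause(5, 10, 2, 3), "upper < lower")
})

make_cell_inputs <- function(frac, K, env_deaths = 1000) {
  csmf <- tibble::tibble(iso_code = "A", year = 2005, group = "5to9",
                         draws = list(matrix(rep(frac, each = K), K,
                                             length(frac),
                                             dimnames = list(NULL, names(frac)))))
  class(csmf) <- c("csmf_draws", class(csmf))
  env <- list(point = tibble::tibble(iso_code = "A", year = 2005,
                                     group = "5to9", deaths = env_deaths,
                                     rate = 2))
  list(csmf = csmf, env = env)
}

test_that("propagation with degenerate inputs yields zero-width intervals", {
  tax <- cause_taxonomy("5to9")
  mc <- modelled_causes(tax)
  frac <- stats::setNames(rep(1 / length(mc), length(mc)), mc)
  inp <- make_cell_inputs(frac, K = 8)
  sc_empty <- tibble::tibble(cause = character(), iso_code = character(),
                             year = integer(), group = character(),
                             deaths = numeric(), lower = numeric(),
                             upper = numeric())
  cube <- propagate(inp$csmf, inp$env, sc_empty,
                    list(residual_lri = 0.01, residual_other_cmpn = 0.01),
                    tax, seed = 4)
  s <- summarise_cube(cube)
  expect_equal(s$deaths_lower, s$deaths_upper, tolerance = 1e-9)
  expect_equal(sum(s$fraction), 1, tolerance = 1e-9)
  # per-draw conservation
  expect_equal(rowSums(cube$death_draws[[1]]), cube$env_deaths[[1]],
               tolerance = 1e-9)
})

test_that("propagation errors on mismatched draw counts", {
  tax <- cause_taxonomy("5to9")
  mc <- modelled_causes(tax)
  frac <- stats::setNames(rep(1 / length(mc), length(mc)), mc)
  a <- make_cell_inputs(frac, K = 8)$csmf
  b <- make_cell_inputs(frac, K = 4)$csmf
  b$iso_code <- "B"
  both <- dplyr::bind_rows(a, b)
  class(both) <- c("csmf_draws", class(both))
  env <- make_cell_inputs(frac, K = 8)$env
  expect_error(propagate(both, env, tibble::tibble(), list(), tax),
               "misalignment")
})

test_that("aggregation conserves deaths and weights fractions correctly", {
  sc <- small_scenario()
  pipe_cube <- local({
    fit <- small_fit()
    pred <- predict_csmf(fit, sc$panel, iso_codes = c("C04", "C05", "C06"),
                         years = c(2000, 2001))
    propagate(pred, sc$envelopes, sc$single_causes,
              list(residual_lri = 0.02, residual_other_cmpn = 0.01),
              sc$truth$taxonomy, seed = 5)
  })
  rm1 <- tibble::tibble(iso_code = c("C04", "C05", "C06"),
                        region = c("r1", "r1", "r2"))
  reg <- aggregate_cube(pipe_cube, rm1)
  # single-country region equals the country
  expect_equal(reg$death_draws[[which(reg$iso_code == "r2" &
                                        reg$year == 2000)]],
               pipe_cube$death_draws[[which(pipe_cube$iso_code == "C06" &
                                              pipe_cube$year == 2000)]],
               tolerance = 1e-12)
  glob <- aggregate_cube(pipe_cube, tibble::tibble(
    iso_code = c("C04", "C05", "C06"), region = "global"))
  # global all-cause equals the sum of regional all-cause, per draw
  g <- glob$env_deaths[[which(glob$year == 2000)]]
  r <- Reduce(`+`, reg$env_deaths[reg$year == 2000])
  expect_equal(g, r, tolerance = 1e-9)
  # regional fraction is the death-weighted mean of country fractions
  i4 <- which(pipe_cube$iso_code == "C04" & pipe_cube$year == 2000)
  i5 <- which(pipe_cube$iso_code == "C05" & pipe_cube$year == 2000)
  w4 <- pipe_cube$env_deaths[[i4]]; w5 <- pipe_cube$env_deaths[[i5]]
  manual <- (pipe_cube$frac_draws[[i4]] * w4 +
               pipe_cube$frac_draws[[i5]] * w5) / (w4 + w5)
  r1row <- which(reg$iso_code == "r1" & reg$year == 2000)
  expect_equal(reg$frac_draws[[r1row]], manual, tolerance = 1e-9)
  expect_error(aggregate_cube(pipe_cube, rm1[1:2, ]), "unmapped")
})

test_that("broad-group totals and source shares follow the maps", {
  counts <- tibble::tibble(cause = c("malaria", "neoplasms", "road_traffic",
                                     "drowning"),
                           deaths = c(60, 25, 10, 5))
  bg <- broad_group_totals(counts)
  expect_equal(bg$deaths[bg$broad_group == "cmpn"], 60)
  expect_equal(bg$deaths[bg$broad_group == "injury"], 15)
  expect_equal(sum(bg$fraction), 1, tolerance = 1e-12)
  expect_error(broad_group_totals(tibble::tibble(cause = "zzz", deaths = 1)),
               "without broad group")
  sh <- source_share_table(c(a = 25, b = 75))
  expect_equal(sh$percent, c(25, 75))
  expect_equal(sum(sh$percent), 100, tolerance = 1e-9)
})

test_that("AARR uses the log formulation with the decline-positive sign", {
  expect_equal(compute_aarr(2, 1, 2000, 2019), 100 * log(2) / 19,
               tolerance = 1e-12)
  expect_equal(compute_aarr(5, 5, 2000, 2019), 0)
  expect_equal(compute_aarr(1, 2, 2000, 2019), -100 * log(2) / 19,
               tolerance = 1e-12)
  expect_error(compute_aarr(0, 1, 2000, 2019), "positive")
  expect_error(compute_aarr(1, 1, 2019, 2000), "exceed")
})

test_that("summaries nest their intervals around the median", {
  sc <- small_scenario()
  fit <- small_fit()
  pred <- predict_csmf(fit, sc$panel, iso_codes = "C04", years = 2000)
  cube <- propagate(pred, sc$envelopes, sc$single_causes,
                    list(residual_lri = 0.02, residual_other_cmpn = 0.01),
                    sc$truth$taxonomy, seed = 6)
  s <- summarise_cube(cube)
  expect_true(all(s$deaths_lower <= s$deaths + 1e-12))
  expect_true(all(s$deaths <= s$deaths_upper + 1e-12))
  expect_true(all(s$fraction_lower <= s$fraction + 1e-12))
  expect_true(all(s$fraction <= s$fraction_upper + 1e-12))
})
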