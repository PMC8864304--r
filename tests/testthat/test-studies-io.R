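tax59 <- cause_taxonomy("5to9")

mk_study <- function(id, causes, deaths, iso = "AAA", year = 2005) {
  tibble::tibble(study_id = id, iso_code = iso, group = "5to9",
                 year_mid = year, cause = causes, deaths = deaths)
}

test_that("study inclusion rules accept and reject correctly", {
  ok <- mk_study("s1", c("malaria", "diarrhoea"), c(10, 8))
  small <- mk_study("s2", c("malaria", "diarrhoea"), c(10, 4))   # total 14
  single <- mk_study("s3", "malaria", 40)
  res <- validate_studies(dplyr::bind_rows(ok, small, single), tax59)
  expect_equal(unique(res$accepted$study_id), "s1")
  expect_setequal(res$rejected$study_id, c("s2", "s3"))
  expect_match(res$rejected$reason[res$rejected$study_id == "s2"], "15 deaths")
  expect_match(res$rejected$reason[res$rejected$study_id == "s3"], "2 reported")
})

test_that("validation is idempotent and errors on bad inputs", {
  ok <- mk_study("s1", c("malaria", "diarrhoea"), c(10, 8))
  once <- validate_studies(ok, tax59)$accepted
  expect_identical(validate_studies(once, tax59)$accepted, once)
  expect_error(validate_studies(mk_study("s4", "plague", 99), tax59), "plague")
  expect_error(validate_studies(mk_study("s5", c("malaria", "lri"), c(-1, 20)),
                                tax59), "negative")
})

test_that("csmf_from_counts reproduces published percentage arithmetic", {
  f <- csmf_from_counts(c(road_traffic = 115843, rest = 1480227 - 115843))
  expect_equal(round(100 * f$fraction[1], 1), 7.8)
  f2 <- csmf_from_counts(c(diarrhoea = 51630, rest = 516971 - 51630))
  expect_equal(round(100 * f2$fraction[1], 1), 10.0)
  expect_equal(sum(f$fraction), 1, tolerance = 1e-12)
  expect_equal(csmf_from_counts(c(x = 7))$fraction, 1)
  expect_error(csmf_from_counts(c(a = 0, b = 0)), "positive")
  expect_error(csmf_from_counts(c(a = 3, b = 4), total = 10), "does not equal")
})

test_that("tabular IO round-trips and rejects malformed files", {
  tmp <- withr::local_tempdir()
  st <- dplyr::bind_rows(
    mk_study("s1", c("malaria", "diarrhoea"), c(10, 8)),
    mk_study("s2", c("malaria", "lri"), c(3, 22), iso = "BBB"),
    mk_study("s3", c("drowning", "other_cmpn"), c(5, 30), year = 2007))
  p <- file.path(tmp, "studies.csv")
  write_studies(st, p)
  expect_equal(as.data.frame(read_studies(p)), as.data.frame(st),
               tolerance = 1e-12)

  dup <- dplyr::bind_rows(st, st[1, ])
  write_studies(dup, p)
  expect_error(read_studies(p), "duplicate")

  aliases <- tibble::tibble(alias = "paludisme", cause = "malaria")
  st2 <- st
  st2$cause[1] <- "paludisme"
  write_studies(st2, p)
  expect_equal(read_studies(p, aliases = aliases)$cause[1], "malaria")

  panel <- tidyr::expand_grid(iso_code = c("AAA", "BBB"), year = 2000:2003)
  panel$x1 <- seq_len(nrow(panel)) / 7
  pp <- file.path(tmp, "panel.csv")
  write_panel(panel, pp)
  expect_equal(as.data.frame(read_panel(pp, require_years = 2000:2003)),
               as.data.frame(panel), tolerance = 1e-12)
  panel$x1[3] <- NA
  write_panel(panel, pp)
  expect_error(read_panel(pp, require_years = 2000:2003), "complete time series")
  write_panel(panel[-2, ], pp)
  expect_error(read_panel(pp, require_years = 2000:2003), "missing year")
})

test_that("single-cause reader enforces interval nesting", {
  tmp <- withr::local_tempfile(fileext = ".csv")
  df <- tibble::tibble(cause = "hiv", iso_code = "AAA", year = 2005,
                       group = "5to9", deaths = 50, lower = 60, upper = 80)
  readr::write_csv(df, tmp)
  expect_error(read_single_causes(tmp), "outside")
  df$lower <- 40
  readr::write_csv(df, tmp)
  expect_equal(read_single_causes(tmp)$deaths, 50)
})
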