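test_that("quality gate applies both rules with inclusive bounds", {
  r <- qc_gate(list(missing_fraction = 0.28, sex_ratio = 1.08))
  expect_false(r$accept)
  expect_match(r$reason, "missing_fraction")
  expect_match(r$reason, "sex_ratio")

  expect_true(qc_gate(list(missing_fraction = 0, sex_ratio = 1.02))$accept)
  expect_true(qc_gate(list(missing_fraction = 0.10, sex_ratio = 1.06))$accept)
  expect_true(qc_gate(list(missing_fraction = 0.10, sex_ratio = 1.00))$accept)
  expect_false(qc_gate(list(missing_fraction = 0.11, sex_ratio = 1.02))$accept)
  expect_false(qc_gate(list(missing_fraction = 0, sex_ratio = 0.99))$accept)

  expect_error(qc_gate(list(missing_fraction = NA, sex_ratio = 1.02)), "missing")
  expect_error(qc_gate(list(sex_ratio = 1.02)), "missing")
  expect_error(qc_gate(list(missing_fraction = 0, sex_ratio = 1.02),
                       missing_cutoff = 0.2), "0.05")
})

make_records <- function(n_alive, death_months = integer(), year = 2010,
                         weight = 1) {
  tibble::tibble(
    birth_time = c(rep(year, n_alive + length(death_months))),
    alive = c(rep(TRUE, n_alive), rep(FALSE, length(death_months))),
    age_at_death_months = c(rep(NA_integer_, n_alive), death_months),
    weight = weight
  )
}

test_that("direct CBH estimation matches the closed-form occurrence/exposure rate", {
  # 999 survivors born at the year start each contribute one person-year;
  # one child dies at 11 completed months, contributing 11.5/12 years
  rec <- make_records(999, death_months = 11L)
  est <- cbh_u5mr(rec, 2010)
  E <- 999 + 11.5 / 12
  m <- 1 / E
  expect_equal(est$value, 1000 * (1 - exp(-5 * m)), tolerance = 1e-12)
  expect_equal(est$design_variance, 1, tolerance = 1e-12)
  # the raw-rate variant
  est_raw <- cbh_u5mr(rec, 2010, conversion = "none")
  expect_equal(est_raw$value, 5000 * m, tolerance = 1e-12)
})

test_that("CBH estimator is invariant to uniform weight rescaling and monotone in deaths", {
  rec <- make_records(500, death_months = c(3L, 25L))
  est1 <- cbh_u5mr(rec, 2010)
  rec$weight <- rec$weight * 0.37
  est2 <- cbh_u5mr(rec, 2010)
  expect_equal(est1$value, est2$value, tolerance = 1e-12)

  more <- make_records(499, death_months = c(3L, 25L, 40L))
  expect_gt(cbh_u5mr(more, 2010)$value, est1$value * 0.99) # more deaths, ~same exposure

  none <- make_records(100)
  est0 <- cbh_u5mr(none, 2010)
  expect_equal(est0$value, 0)
  expect_equal(est0$design_variance, 2) # 1 / (0 + 0.5)

  expect_error(cbh_u5mr(make_records(10), 1990), "person-time")
  bad <- make_records(10)
  bad$age_at_death_months[1] <- 5L
  expect_error(cbh_u5mr(bad, 2010), "iff")
})

test_that("identity coefficients make the indirect estimate the raw ratio", {
  tbl <- tibble::tibble(
    age_group = c("20-24", "25-29", "30-34", "35-39"),
    ceb = c(100L, 200L, 300L, 400L),
    cd = c(2L, 6L, 9L, 16L)
  )
  est <- mac_estimate(tbl, 2017, coefs = identity_coefs(),
                      exclude_groups = character())
  expect_equal(sort(est$value), sort(1000 * tbl$cd / tbl$ceb), tolerance = 1e-12)
  expect_true(all(est$year < 2017))
  expect_equal(est$source, rep("SBH_MAC", 4))

  zero <- tbl
  zero$cd <- 0L
  expect_equal(mac_estimate(zero, 2017, coefs = identity_coefs(),
                            exclude_groups = character())$value,
               rep(0, 4))
})

test_that("period-bucketed estimates pool cohorts consistently", {
  # uniform ratio across groups: every period bucket must reproduce it
  tbl <- tibble::tibble(
    age_group = c("20-24", "25-29", "30-34", "35-39", "40-44", "45-49"),
    ceb = rep(500L, 6), cd = rep(10L, 6)
  )
  est <- map_estimate(tbl, 2017, coefs = identity_coefs(),
                      exclude_groups = character())
  expect_true(all(abs(est$value - 1000 * 10 / 500) < 1e-12))
  expect_lt(nrow(est), 6) # cohorts merged into period buckets
  expect_equal(est$source, rep("SBH_MAP", nrow(est)))
})

test_that("rows with no children ever born are dropped with a warning", {
  tbl <- tibble::tibble(age_group = c("20-24", "25-29", "30-34", "35-39"),
                        ceb = c(0L, 200L, 300L, 250L), cd = c(0L, 6L, 9L, 7L))
  expect_warning(est <- mac_estimate(tbl, 2017, coefs = identity_coefs(),
                                     exclude_groups = character()),
                 "zero children")
  expect_equal(nrow(est), 3)
  small <- tibble::tibble(age_group = c("20-24", "25-29"), ceb = c(10L, 0L),
                          cd = c(1L, 0L))
  expect_error(suppressWarnings(mac_estimate(small, 2017, coefs = identity_coefs(),
                                             exclude_groups = character())),
               "at least 3")
})

test_that("indirect estimates recover a constant true surface", {
  cfg <- synth_config(mean_coefs = c(log(25), 0, 0, 0), spatial_sd = 0,
                      temporal_sd = 0, interaction_sd = 0, seed = 101)
  truth <- generate_truth(cfg)
  coefs <- calibrated_sbh_coefs()
  tbl <- generate_sbh(truth, 2017, n_mothers_per_agegroup = 3000, seed = 55)
  mac <- mac_estimate(tbl, 2017, coefs = coefs)
  mp <- map_estimate(tbl, 2017, coefs = coefs)
  for (est in list(mac, mp)) {
    se <- est$value * sqrt(est$design_variance)
    pooled_se <- sqrt(1 / sum(1 / se^2))
    pooled <- sum(est$value / se^2) / sum(1 / se^2)
    expect_lt(abs(pooled - 25), 3 * pooled_se)
  }
  # MAC and MAP agree with each other on the same table
  expect_equal(mean(mac$value), mean(mp$value), tolerance = 0.1)
})

test_that("direct CBH estimates recover the true surface on a large sample", {
  cfg <- synth_config(mean_coefs = c(log(40), 0, 0, 0), spatial_sd = 0,
                      temporal_sd = 0, interaction_sd = 0, seed = 202)
  truth <- generate_truth(cfg)
  cbh <- generate_cbh(truth, 2017, n_mothers = 12000, seed = 56)
  one <- dplyr::filter(cbh, province == truth$provinces[1])
  est <- cbh_u5mr(one, 2014)
  se <- est$value * sqrt(est$design_variance)
  expect_lt(abs(est$value - truth$true_u5mr[1, 1]), 3 * se)
})

test_that("coefficient sets read from CSV and validate", {
  dir <- withr::local_tempdir()
  f <- file.path(dir, "coefs.csv")
  write.csv(brass_coefs(), f, row.names = FALSE)
  back <- read_coefs(f)
  expect_equal(back$multiplier, brass_coefs()$multiplier)
  bad <- file.path(dir, "bad.csv")
  write.csv(data.frame(x = 1), bad, row.names = FALSE)
  expect_error(read_coefs(bad), "lacks columns")
})
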