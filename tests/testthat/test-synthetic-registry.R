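test_that("generator is deterministic and emits structurally valid records", {
  p <- registry_params(n_spont = 50, n_fresh = 30, n_frozen = 30, seed = 42)
  a <- simulate_cohort(p)
  b <- simulate_cohort(p)
  expect_identical(a, b)
  expect_equal(nrow(a), 110)
  expect_equal(as.integer(table(a$conception_mode)[c("spontaneous",
                                                     "fresh_et",
                                                     "frozen_et")]),
               c(50L, 30L, 30L))

  art <- a$conception_mode != "spontaneous"
  expect_true(all(a$fertilization_date[art] <= a$transfer_date[art]))
  expect_true(all(a$transfer_date[art] < a$birth_date[art]))
  expect_true(all(a$birth_date > a$lmp_date))
  expect_true(all(a$ga_us_birth_days >= 154))
  expect_true(all(a$culture_days[art] %in% c(2L, 3L, 5L)))
  expect_true(all(is.na(a$culture_days[!art])))
  # fresh ET: transfer - fertilization equals the culture duration
  fr <- a$conception_mode == "fresh_et"
  expect_equal(as.integer(a$transfer_date[fr] - a$fertilization_date[fr]),
               a$culture_days[fr])
  # onset classification partitions the records
  expect_true(all(classify_onset(a) %in% c("event", "censored")))
  expect_identical(classify_onset(a) == "event",
                   a$onset_type == "spontaneous")
  # schema validator finds nothing to complain about
  expect_equal(nrow(validate_registry(analysis_input(a))), 0L)
})

test_that("only the requested groups are generated", {
  coh <- simulate_cohort(registry_params(n_fresh = 5, seed = 1))
  expect_equal(nrow(coh), 5L)
  expect_true(all(coh$conception_mode == "fresh_et"))
  expect_true(all(as.integer(coh$transfer_date - coh$fertilization_date)
                  %in% c(2L, 3L, 5L)))
})

test_that("nonspontaneous fraction matches its target", {
  coh <- simulate_cohort(registry_params(n_spont = 50000, seed = 7))
  frac <- mean(classify_onset(coh) == "censored")
  expect_lt(abs(frac - 0.307), 0.01)

  coh2 <- simulate_cohort(registry_params(n_frozen = 20000, seed = 7))
  expect_lt(abs(mean(classify_onset(coh2) == "censored") - 0.441), 0.012)
})

test_that("latent onset medians converge to the configured medians", {
  coh <- simulate_cohort(registry_params(n_spont = 50000, n_frozen = 20000,
                                         seed = 13))
  sp <- coh$latent_onset_ga_days[coh$conception_mode == "spontaneous"]
  fz <- coh$latent_onset_ga_days[coh$conception_mode == "frozen_et"]
  expect_lt(abs(median(sp) - 283), 0.3)
  expect_lt(abs(median(fz) - 286), 0.4)
  # left skew: mean below median
  expect_lt(mean(sp), median(sp))
})

test_that("follicular phase is right-skewed with median 15 days", {
  coh <- simulate_cohort(registry_params(n_fresh = 20000, seed = 19))
  f <- coh$latent_follicular_days
  expect_equal(median(f), 15)
  expect_gt(mean(f), median(f))
  expect_gt(quantile(f, 0.95), 22)
  expect_true(all(f >= 7))
})

test_that("censoring is independent of latent onset unless made informative", {
  coh <- simulate_cohort(registry_params(n_spont = 50000, seed = 23))
  expect_lt(abs(cor(coh$latent_onset_ga_days,
                    coh$latent_intervention_ga_days)), 0.02)

  inf <- simulate_cohort(registry_params(n_spont = 5000, seed = 23,
                                         informative_censoring = TRUE))
  expect_gt(cor(inf$latent_onset_ga_days,
                inf$latent_intervention_ga_days), 0.9)
})

test_that("invalid generator parameters are rejected", {
  expect_error(registry_params(n_spont = -1), "counts")
  expect_error(registry_params(censor_target_fraction = 1), "\\[0, 1\\)")
  expect_error(registry_params(us_error_sd_days = 0), "us_error_sd_days")
  expect_error(registry_params(culture_day_mix_fresh = c(`2` = -1, `3` = 1,
                                                         `5` = 1)),
               "mixture")
  expect_error(simulate_cohort(registry_params(seed = 1)), "no records")
})
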