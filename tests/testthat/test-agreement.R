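test_that("agreement summary bins and quartiles match hand enumeration", {
  s <- summarize_agreement(c(-1, 0, 0, 1, 2), conf = FALSE)
  expect_equal(s$n, 5L)
  expect_equal(unname(s$median_diff), 0)
  expect_equal(unname(s$freq_table["<=1"]), 4L)
  expect_equal(unname(s$freq_table["2"]), 1L)
  expect_equal(sum(s$freq_table), s$n)
  expect_lte(s$q1_offset, 0)
  expect_gte(s$q3_offset, 0)
  expect_error(summarize_agreement(numeric(0)), "non-empty")
})

test_that("fractional differences are rounded half away from zero first", {
  s <- summarize_agreement(c(-1.5, 1.5, 0.4, -0.5), conf = FALSE)
  # -1.5 -> -2, 1.5 -> 2, 0.4 -> 0, -0.5 -> -1
  expect_equal(unname(s$freq_table["2"]), 2L)
  expect_equal(unname(s$freq_table["<=1"]), 2L)
})

test_that("agreement summaries are translation-equivariant", {
  set.seed(9)
  for (i in 1:5) {
    d <- sample(-6:8, 40, replace = TRUE)
    shift <- sample(c(-3, 1, 2), 1)
    a <- summarize_agreement(d, conf = FALSE)
    b <- summarize_agreement(d + shift, conf = FALSE)
    expect_equal(unname(b$median_diff), unname(a$median_diff) + shift)
    expect_equal(b$q1_offset, a$q1_offset)
    expect_equal(b$q3_offset, a$q3_offset)
  }
})

test_that("the k-shift moves the median by exactly one day, shape unchanged", {
  coh <- simulate_cohort(registry_params(n_fresh = 1500, seed = 31))
  s14 <- summarize_agreement(pairwise_ga_difference(coh, 14), conf = FALSE)
  s15 <- summarize_agreement(pairwise_ga_difference(coh, 15), conf = FALSE)
  expect_equal(unname(s15$median_diff), unname(s14$median_diff) - 1)
  expect_equal(s15$q1_offset, s14$q1_offset)
  expect_equal(s15$q3_offset, s14$q3_offset)
  # quartile offsets flank the median with roughly symmetric spread
  # (follicular-phase variation plus ultrasound error)
  expect_true(s14$q1_offset < -1 && s14$q1_offset > -6)
  expect_true(s14$q3_offset > 1 && s14$q3_offset < 6)
})

test_that("bootstrap median CI is reproducible, centered and degenerate-safe", {
  x <- c(3, 3, 3, 3)
  ci <- bootstrap_median_ci(x, B = 1000, seed = 4)
  expect_equal(as.numeric(ci), c(3, 3))
  expect_true(isTRUE(attr(ci, "degenerate")))

  set.seed(11)
  y <- rnorm(300, 2, 1)
  ci1 <- bootstrap_median_ci(y, B = 1000, seed = 8)
  ci2 <- bootstrap_median_ci(y, B = 1000, seed = 8)
  expect_identical(ci1, ci2)
  for (s in 1:5) {
    ci <- bootstrap_median_ci(y, B = 1000, seed = s)
    expect_lte(ci[1], median(y))
    expect_gte(ci[2], median(y))
  }
  expect_error(bootstrap_median_ci(y, B = 10), "B >= 1000")
  expect_error(bootstrap_median_ci(1), "n >= 2")
})

test_that("bootstrap CI width agrees with an independent loop bootstrap", {
  set.seed(21)
  x <- rnorm(2000, 0.6, 2.5)
  ci <- bootstrap_median_ci(x, B = 2000, level = 0.95, seed = 3)
  # plain-loop oracle with its own RNG stream
  set.seed(1234)
  meds <- replicate(2000, median(sample(x, replace = TRUE)))
  oracle <- quantile(meds, c(0.025, 0.975), type = 7)
  expect_lt(abs(diff(ci) / diff(unname(oracle)) - 1), 0.25)
  # and both are in the ballpark of the asymptotic width
  # 2 * 1.96 * 1.253 * sigma / sqrt(n) ~ 0.27
  expect_gt(diff(ci), 0.15)
  expect_lt(diff(ci), 0.45)
})

test_that("GA on the transfer day tracks follicular phase plus culture days", {
  coh <- simulate_cohort(registry_params(n_fresh = 4000, seed = 41,
                                         us_error_sd_days = 1e-9))
  tab <- ga_on_transfer_day_by_culture(coh, B = 1000)
  expect_equal(tab$culture_days, c(2, 3, 5))
  expect_equal(tab$median_ga, c(17, 18, 20))
  expect_equal(tab$median_ga[3] - tab$median_ga[1], 3)
})

test_that("transfer-day GA aligns with a 15-day, not 14-day, follicular phase", {
  coh <- simulate_cohort(registry_params(n_fresh = 4000, n_frozen = 4000,
                                         seed = 43))
  for (g in c("fresh_et", "frozen_et")) {
    tab <- ga_on_transfer_day_by_culture(coh[coh$conception_mode == g, ],
                                         B = 1000)
    dev15 <- abs(tab$median_ga - (15 + tab$culture_days))
    dev14 <- abs(tab$median_ga - (14 + tab$culture_days))
    expect_true(all(dev15 < dev14))
  }
})
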