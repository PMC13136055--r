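test_that("product-limit estimates match hand computation", {
  # all events: empirical survival
  f <- km_fit(c(5, 8, 12), c(TRUE, TRUE, TRUE))
  expect_equal(f$surv, c(2 / 3, 1 / 3, 0))
  expect_equal(f$n_risk, c(3, 2, 1))

  # censoring in the middle
  g <- km_fit(c(5, 8, 12), c(TRUE, FALSE, TRUE))
  expect_equal(g$surv, c(2 / 3, 2 / 3, 0))
  expect_equal(g$n_event, c(1, 0, 1))
  expect_equal(g$n_censor, c(0, 1, 0))
  # Greenwood variance of log S: 1/(3*2) after the first event
  expect_equal(g$var_logs[1:2], c(1 / 6, 1 / 6))
  expect_true(is.na(g$var_logs[3]))  # S = 0: log-scale variance undefined

  expect_error(km_fit(c(1, 2), c(FALSE, FALSE)), "no events")
  expect_error(km_fit(c(-1, 2), c(TRUE, TRUE)), ">= 0")
})

test_that("ties at one day are processed events-first", {
  f <- km_fit(c(7, 7, 7, 9), c(TRUE, FALSE, TRUE, TRUE))
  # at day 7 all four are at risk: S(7) = 1 - 2/4
  expect_equal(f$surv, c(0.5, 0))
  expect_equal(f$n_risk, c(4, 1))
})

test_that("with zero censoring the curve is the empirical survival function", {
  for (seed in 1:5) {
    set.seed(seed)
    t <- sample(1:40, 60, replace = TRUE)
    f <- km_fit(t, rep(TRUE, 60))
    ecdf_s <- 1 - ecdf(t)(f$times)
    expect_equal(f$surv, ecdf_s)
  }
})

test_that("estimates agree with the survival package to 1e-12", {
  skip_if_not_installed("survival")
  for (seed in 1:20) {
    inst <- fuzz_survival_instance(n = sample(20:200, 1), seed = seed)
    mine <- km_fit(inst$times, inst$event)
    ref <- survival::survfit(survival::Surv(inst$times, inst$event) ~ 1)
    expect_equal(mine$times, ref$time)
    expect_equal(mine$surv, ref$surv, tolerance = 1e-12)
    ok <- mine$surv > 0
    expect_equal(mine$var_logs[ok], ref$std.err[ok]^2, tolerance = 1e-12)
  }
})

test_that("cumulative birth distribution is the survival complement", {
  f <- km_fit(c(5, 8, 12), c(TRUE, FALSE, TRUE))
  cb <- cumulative_birth_distribution(f)
  expect_equal(cb$F + cb$S, rep(1, 3))
  expect_equal(cb$F[3], 1)
})

test_that("survival medians: step, interpolation, and degenerate cases", {
  g <- km_fit(c(5, 8, 12), c(TRUE, FALSE, TRUE))
  expect_equal(survival_median(g, interpolate = FALSE), 12)

  # no censoring: the interpolated median is the sample median
  expect_equal(survival_median(km_fit(1:3, rep(TRUE, 3))), 2)
  expect_equal(survival_median(km_fit(1:4, rep(TRUE, 4))), 2.5)
  expect_equal(survival_median(km_fit(c(280, 281, 283, 284, 290),
                                      rep(TRUE, 5))), 283)

  # heavy censoring: S never reaches 0.5
  h <- km_fit(c(5, 6, 7, 8), c(TRUE, FALSE, FALSE, FALSE))
  expect_error(survival_median(h), "median undefined")
})

test_that("quantiles of the fitted distribution bracket the median", {
  coh <- simulate_cohort(registry_params(n_spont = 3000, seed = 55))
  f <- km_fit(coh$ga_us_birth_days, classify_onset(coh) == "event")
  q <- quantile(f, c(0.25, 0.5, 0.75))
  expect_lt(q[[1]], q[[2]])
  expect_lt(q[[2]], q[[3]])
  expect_equal(q[[2]], survival_median(f))
})

test_that("MC median CI collapses to the point median when variance is zero", {
  coh <- simulate_cohort(registry_params(n_spont = 1000, seed = 61))
  f <- km_fit(coh$ga_us_birth_days, classify_onset(coh) == "event")
  f$var_logs[] <- 0
  est <- mc_median_ci(f, n_sim = 200, seed = 2)
  expect_equal(est$ci, rep(est$median, 2))
  expect_equal(est$median, survival_median(f))
})

test_that("MC median CI is reproducible and brackets the point estimate", {
  coh <- simulate_cohort(registry_params(n_spont = 3000, seed = 62))
  f <- km_fit(coh$ga_us_birth_days, classify_onset(coh) == "event")
  a <- mc_median_ci(f, n_sim = 500, seed = 3)
  b <- mc_median_ci(f, n_sim = 500, seed = 3)
  expect_identical(a, b)
  expect_lte(a$ci[1], a$median)
  expect_gte(a$ci[2], a$median)
  expect_error(mc_median_ci(f, n_sim = 500), "seed")
})

test_that("MC CI half-width is comparable to a nonparametric bootstrap", {
  coh <- simulate_cohort(registry_params(n_spont = 3000, seed = 63))
  t <- coh$ga_us_birth_days
  e <- classify_onset(coh) == "event"
  est <- mc_median_ci(km_fit(t, e), n_sim = 2000, seed = 4)
  set.seed(99)
  boot <- replicate(400, {
    i <- sample.int(length(t), replace = TRUE)
    survival_median(km_fit(t[i], e[i]))
  })
  bw <- diff(quantile(boot, c(0.025, 0.975), type = 7))
  expect_lt(abs(diff(est$ci) / bw - 1), 0.3)
})

test_that("difference CIs are symmetric, antisymmetric, and recover shifts", {
  coh <- simulate_cohort(registry_params(n_spont = 3000, seed = 64))
  f <- km_fit(coh$ga_us_birth_days, classify_onset(coh) == "event")
  same <- mc_median_difference_ci(f, f, n_sim = 300, seed = 5)
  expect_equal(same$median, 0)
  expect_lte(same$ci[1], 0)
  expect_gte(same$ci[2], 0)

  coh2 <- simulate_cohort(registry_params(n_frozen = 3000, seed = 65))
  g <- km_fit(coh2$ga_us_birth_days, classify_onset(coh2) == "event")
  ab <- mc_median_difference_ci(f, g, n_sim = 300, seed = 6)
  ba <- mc_median_difference_ci(g, f, n_sim = 300, seed = 6)
  expect_equal(ab$median, -ba$median)
  expect_equal(ab$ci, -rev(ba$ci))
  # ~3-day true separation (286 vs 283) is inside the interval
  expect_lt(ba$ci[1], 3.8)
  expect_gt(ba$ci[2], 2.2)
})

test_that("censoring strategies order as expected and agree when trivial", {
  none <- simulate_cohort(registry_params(n_spont = 800, seed = 66,
                                          censor_target_fraction = 0))
  fits <- lapply(c("censor", "exclude", "as_event"), strategy_compare,
                 records = none)
  expect_identical(fits[[1]], fits[[2]])
  expect_identical(fits[[1]], fits[[3]])

  coh <- simulate_cohort(registry_params(n_spont = 8000, seed = 67))
  m <- vapply(c("censor", "exclude", "as_event"),
              function(s) survival_median(strategy_compare(coh, s)),
              numeric(1))
  expect_lt(m[["exclude"]], m[["censor"]])
  expect_lt(m[["as_event"]], m[["censor"]])
})

test_that("informative censoring visibly biases the KM median", {
  inf <- simulate_cohort(registry_params(n_spont = 10000, seed = 68,
                                         informative_censoring = TRUE))
  m <- survival_median(km_fit(inf$ga_us_birth_days,
                              classify_onset(inf) == "event"))
  # interventions pre-empt imminent onsets, so the survivors look too slow
  expect_gt(m - 283, 1)
})

test_that("Aalen-Johansen matches hand computation and its identities", {
  ic <- aalen_johansen(c(280, 270, 285, 290),
                       c("onset", "preeclampsia", "censored", "onset"))
  expect_equal(ic$times, c(270, 280, 285, 290))
  expect_equal(ic$cif[, "preeclampsia"], c(1 / 4, 1 / 4, 1 / 4, 1 / 4))
  expect_equal(ic$cif[, "onset"], c(0, 1 / 4, 1 / 4, 3 / 4))
  expect_equal(ic$surv, c(3 / 4, 1 / 2, 1 / 2, 0))
  # CIF_onset + CIF_pe + S = 1 at every time
  expect_equal(rowSums(ic$cif) + ic$surv, rep(1, 4), tolerance = 1e-12)

  expect_error(aalen_johansen(c(1, 2), c("censored", "censored")),
               "no events")
})

test_that("single-cause incidence reduces to one minus the KM survival", {
  inst <- fuzz_survival_instance(n = 80, seed = 7)
  cause <- ifelse(inst$event, "onset", "censored")
  ic <- aalen_johansen(inst$times, cause)
  km <- km_fit(inst$times, inst$event)
  expect_equal(ic$cif[, "onset"], 1 - km$surv, tolerance = 1e-12)
  expect_equal(ic$surv, km$surv, tolerance = 1e-12)
})

test_that("cumulative incidence agrees with a multi-state reference fit", {
  skip_if_not_installed("survival")
  for (seed in 1:5) {
    set.seed(seed)
    n <- 120
    t <- sample(250:300, n, replace = TRUE)
    cause <- sample(c("onset", "preeclampsia", "censored"), n,
                    replace = TRUE, prob = c(0.5, 0.2, 0.3))
    ic <- aalen_johansen(t, cause)
    st <- factor(cause, levels = c("censored", "onset", "preeclampsia"))
    ref <- survival::survfit(survival::Surv(t, st) ~ 1)
    idx <- match(ic$times, ref$time)
    expect_equal(ic$cif[, "onset"],
                 ref$pstate[idx, which(ref$states == "onset")],
                 tolerance = 1e-12)
    expect_equal(ic$cif[, "preeclampsia"],
                 ref$pstate[idx, which(ref$states == "preeclampsia")],
                 tolerance = 1e-12)
  }
})

test_that("transfer-to-birth medians reflect the fertilization clock", {
  coh <- simulate_cohort(registry_params(n_fresh = 4000, n_frozen = 4000,
                                         seed = 41, us_error_sd_days = 1e-9))
  rd <- remaining_duration_by_culture(coh, n_sim = 300, seed = 5)
  fresh <- rd[rd$conception_mode == "fresh_et", ]
  frozen <- rd[rd$conception_mode == "frozen_et", ]
  # onset median 283 minus follicular ~15 minus culture days
  expect_lt(abs(fresh$median_days[fresh$culture_days == 2] - 266), 1.5)
  expect_lt(abs(fresh$median_days[fresh$culture_days == 5] - 263), 1.5)
  d25 <- fresh$median_days[fresh$culture_days == 2] -
    fresh$median_days[fresh$culture_days == 5]
  expect_lt(abs(d25 - 3), 1.5)
  # frozen ET runs ~3 days longer at a fixed culture day
  gap5 <- frozen$median_days[frozen$culture_days == 5] -
    fresh$median_days[fresh$culture_days == 5]
  expect_lt(abs(gap5 - 3), 1.5)
})
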