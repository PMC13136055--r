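# Parametric Monte Carlo confidence intervals for survival medians.
#
# The sampling model: around the median, log S(t) is asymptotically normal
# with variance given by Greenwood's formula. Each simulation draws one
# standard normal deviate and shifts log S(t) by that deviate scaled by the
# (monotone) Greenwood SE profile within a window around the point median;
# monotonicity of the perturbed curve is restored by isotonic regression and
# the median is re-extracted. The percentile interval of the re-extracted
# medians is the reported CI. A common deviate across times corresponds to
# test inversion of the pointwise normal band, which is what makes the
# interval's coverage match the nominal level.

# simulated medians for one curve; vector of length n_sim (NA where the
# perturbed curve no longer crosses 0.5)
.mc_medians <- function(curve, n_sim, seed, window = 10,
                        interpolate = TRUE) {
  keep <- curve$n_event > 0
  tt <- curve$times[keep]
  ss <- curve$surv[keep]
  vl <- curve$var_logs[keep]
  m <- .median_from_steps(tt, ss, interpolate = TRUE)
  win <- which(tt >= m - window & tt <= m + window & !is.na(vl))
  if (!length(win))
    stop("no event steps with finite variance near the median",
         call. = FALSE)
  logs <- log(pmax(ss, 1e-300))
  se <- sqrt(vl[win])
  local_rng(seed, {
    z <- rnorm(n_sim)
    vapply(z, function(zi) {
      y <- logs
      y[win] <- y[win] + zi * se
      # restore monotone nonincreasing shape, keep log S <= 0
      y <- pmin(-isoreg(seq_along(y), -y)$yf, 0)
      .median_from_steps(tt, exp(y), interpolate)
    }, numeric(1))
  })
}

#' Monte Carlo confidence interval for a survival median
#'
#' Confidence interval for the median of a [km_fit()] curve by parametric
#' Monte Carlo simulation under the asymptotic normality of the
#' log-transformed survival values around the median: each replicate
#' perturbs `log S(t)` at the event steps within `window` days of the point
#' median by a common Gaussian deviate scaled by the Greenwood SE profile,
#' restores monotonicity by isotonic regression and re-extracts the
#' (interpolated) median; the CI is the percentile interval of the
#' replicate medians.
#'
#' @param curve A `"ga_km"` object with a defined median and finite
#'   Greenwood variance near it.
#' @param n_sim Number of Monte Carlo replicates (default 10,000; fewer than
#'   100 triggers a warning).
#' @param level Confidence level.
#' @param seed Integer seed (required: the pipeline treats every stochastic
#'   step as explicitly seeded).
#' @param window Half-width (days) of the perturbation window around the
#'   point median.
#' @param interpolate Passed to the median extraction, see
#'   [survival_median()].
#' @return An object of class `"median_estimate"`: list with `median`, `ci`
#'   (length-2), `level`, `method = "mc_parametric"`, `n_sim`, `seed`.
#' @examples
#' coh <- simulate_cohort(registry_params(n_spont = 2000, seed = 5))
#' fit <- km_fit(coh$ga_us_birth_days, classify_onset(coh) == "event")
#' mc_median_ci(fit, n_sim = 1000, seed = 1)
#' @export
mc_median_ci <- function(curve, n_sim = 10000, level = 0.95, seed,
                         window = 10, interpolate = TRUE) {
  stopifnot(inherits(curve, "ga_km"))
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  if (n_sim < 100) warning("n_sim < 100 gives unstable percentile CIs")
  med <- survival_median(curve, interpolate = interpolate)
  meds <- .mc_medians(curve, n_sim, seed, window, interpolate)
  if (mean(is.na(meds)) > 0.1)
    warning("more than 10% of perturbed curves had undefined medians")
  ci <- unname(quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, type = 7))
  structure(list(median = med, ci = ci, level = level,
                 method = "mc_parametric", n_sim = n_sim, seed = seed),
            class = "median_estimate")
}

#' Monte Carlo CI for a difference of survival medians
#'
#' Perturbs the two curves independently as in [mc_median_ci()] and returns
#' the percentile CI of the difference of the re-extracted medians
#' (`A - B`). Each curve's perturbation stream is keyed to the curve's own
#' content (and the caller's seed), so swapping the arguments with the same
#' seed negates the estimate and exactly reverses the interval, and two
#' structurally identical curves yield a difference of exactly zero.
#'
#' @param curve_a,curve_b `"ga_km"` objects with defined medians.
#' @inheritParams mc_median_ci
#' @return A `"median_estimate"` whose `median` is the difference of the
#'   point medians.
#' @export
mc_median_difference_ci <- function(curve_a, curve_b, n_sim = 10000,
                                    level = 0.95, seed, window = 10,
                                    interpolate = TRUE) {
  stopifnot(inherits(curve_a, "ga_km"), inherits(curve_b, "ga_km"))
  if (missing(seed)) stop("an explicit seed is required", call. = FALSE)
  meds_a <- .mc_medians(curve_a, n_sim, .curve_seed(seed, curve_a),
                        window, interpolate)
  meds_b <- .mc_medians(curve_b, n_sim, .curve_seed(seed, curve_b),
                        window, interpolate)
  d <- meds_a - meds_b
  ci <- unname(quantile(d, c((1 - level) / 2, 1 - (1 - level) / 2),
                        na.rm = TRUE, type = 7))
  structure(list(
    median = survival_median(curve_a, interpolate) -
      survival_median(curve_b, interpolate),
    ci = ci, level = level, method = "mc_parametric", n_sim = n_sim,
    seed = seed), class = "median_estimate")
}

# deterministic per-curve substream: keyed by the caller's seed and the
# curve content so that argument order does not matter
.curve_seed <- function(seed, curve) {
  h <- (sum(curve$times %% 97) * 31 +
          sum(round(curve$surv * 1e6) %% 1009) + curve$n) %% 1000003
  as.integer(((seed %% 1000003) * 2011 + h) %% 2147483647)
}

#' @export
print.median_estimate <- function(x, ...) {
  cat(sprintf("median %.1f days (%.0f%% CI %.1f to %.1f; %s, n_sim = %d)\n",
              x$median, 100 * x$level, x$ci[1], x$ci[2], x$method,
              x$n_sim))
  invisible(x)
}
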