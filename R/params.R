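#' Parameters for the synthetic birth-registry generator
#'
#' Constructs the full parameterization of [simulate_cohort()]. The defaults
#' encode the study conditions the analysis is designed for: group-specific
#' onset-of-birth distributions with medians 283 days (spontaneous and fresh
#' embryo transfer) and 286 days (frozen embryo transfer), a right-skewed
#' follicular phase with median 15 days, Gaussian ultrasound dating error
#' recorded to whole days, embryo-culture-day mixtures over days \{2, 3, 5\},
#' and an intervention (censoring) process tuned to registry-scale
#' nonspontaneous-birth fractions of 30.7\%, 35.5\% and 44.1\% per group.
#'
#' @param n_spont,n_fresh,n_frozen Number of records per conception group
#'   (spontaneous, fresh embryo transfer, frozen embryo transfer).
#' @param onset_median_days Length-3 numeric (spont, fresh, frozen): median of
#'   the latent spontaneous-onset GA distribution, in days from LMP day 0.
#' @param onset_spread_days Scale (days) of the skew-normal onset
#'   distribution; the default 16.6 puts the central 50\% of onsets within
#'   about +/- 7 days of the median.
#' @param onset_skew Shape of the skew-normal onset distribution; negative
#'   values give a left skew (more early than late outliers).
#' @param follicular_median_days Median days from LMP day 0 to ovulation /
#'   oocyte fertilization.
#' @param follicular_spread_days Scale (days) of the shifted-lognormal
#'   follicular-phase distribution: the median sits `follicular_spread_days`
#'   above the shift, so the shift is
#'   `follicular_median_days - follicular_spread_days`.
#' @param follicular_skew Log-scale shape (lognormal `sdlog`) of the
#'   follicular-phase distribution; the default gives a 5th-95th percentile
#'   range of roughly 10-26 days.
#' @param us_error_sd_days Standard deviation (days) of the ultrasound dating
#'   error added to the true GA at birth before rounding to whole days.
#' @param culture_day_mix_fresh,culture_day_mix_frozen Nonnegative mixture
#'   weights over embryo-culture days \{2, 3, 5\} (need not sum to one).
#' @param censor_target_fraction Length-3 numeric in `[0, 1)`: target fraction
#'   of nonspontaneous births per conception group.
#' @param informative_censoring Logical; if `TRUE` the intervention time is
#'   placed just before the latent onset, so censoring depends on the latent
#'   event time and the independence assumption behind Kaplan-Meier
#'   estimation is deliberately violated.
#' @param preeclampsia_fraction Fraction of nonspontaneous births labeled as
#'   pre-eclamptic (the competing-event label).
#' @param seed Integer RNG seed; the same parameter set (including the seed)
#'   always yields an identical cohort.
#'
#' @return An object of class `"registry_params"` (a named list).
#' @seealso [default_params()] for the study-calibrated defaults,
#'   [simulate_cohort()] for the generator itself.
#' @examples
#' p <- registry_params(n_fresh = 10, seed = 1)
#' p$culture_day_mix_fresh
#' @export
registry_params <- function(n_spont = 0L,
                            n_fresh = 0L,
                            n_frozen = 0L,
                            onset_median_days = c(spontaneous = 283,
                                                  fresh_et = 283,
                                                  frozen_et = 286),
                            onset_spread_days = 16.6,
                            onset_skew = -4,
                            follicular_median_days = 15,
                            follicular_spread_days = 10,
                            follicular_skew = 0.45,
                            us_error_sd_days = 2.5,
                            culture_day_mix_fresh = c(`2` = 922, `3` = 500,
                                                      `5` = 569),
                            culture_day_mix_frozen = c(`2` = 245, `3` = 117,
                                                       `5` = 1630),
                            censor_target_fraction = c(spontaneous = 0.307,
                                                       fresh_et = 0.355,
                                                       frozen_et = 0.441),
                            informative_censoring = FALSE,
                            preeclampsia_fraction = 0.15,
                            seed = 1L) {
  p <- list(
    n_spont = as.integer(n_spont),
    n_fresh = as.integer(n_fresh),
    n_frozen = as.integer(n_frozen),
    onset_median_days = .group3(onset_median_days),
    onset_spread_days = onset_spread_days,
    onset_skew = onset_skew,
    follicular_median_days = follicular_median_days,
    follicular_spread_days = follicular_spread_days,
    follicular_skew = follicular_skew,
    us_error_sd_days = us_error_sd_days,
    culture_day_mix_fresh = culture_day_mix_fresh,
    culture_day_mix_frozen = culture_day_mix_frozen,
    censor_target_fraction = .group3(censor_target_fraction),
    informative_censoring = isTRUE(informative_censoring),
    preeclampsia_fraction = preeclampsia_fraction,
    seed = as.integer(seed)
  )
  class(p) <- "registry_params"
  validate_registry_params(p)
  p
}

# recycle a scalar to the three conception groups, preserve/impose names
.group3 <- function(x) {
  groups <- c("spontaneous", "fresh_et", "frozen_et")
  if (length(x) == 1L) x <- rep(x, 3L)
  if (length(x) != 3L)
    stop("per-group parameters must have length 1 or 3", call. = FALSE)
  if (is.null(names(x))) names(x) <- groups
  x <- x[groups]
  if (anyNA(x)) stop("per-group parameters must be named ",
                     paste(groups, collapse = ", "), call. = FALSE)
  x
}

#' Study-calibrated generator defaults
#'
#' Returns the default [registry_params()] with registry-scale group sizes:
#' 163,544 spontaneous, 2067 fresh-ET and 2080 frozen-ET births. All
#' distributional settings are the `registry_params()` defaults. Deterministic.
#'
#' @param ... Overrides passed on to [registry_params()].
#' @return A `"registry_params"` object.
#' @examples
#' default_params()$censor_target_fraction[["frozen_et"]]
#' default_params(n_spont = 1000)$n_spont
#' @export
default_params <- function(...) {
  args <- list(...)
  base <- list(n_spont = 163544L, n_fresh = 2067L, n_frozen = 2080L)
  base[names(args)] <- args
  do.call(registry_params, base)
}

#' Validate generator parameters
#'
#' Checks the invariants of a `"registry_params"` object: nonnegative counts,
#' normalizable culture-day mixtures, censoring targets in `[0, 1)` and a
#' strictly positive ultrasound error SD.
#'
#' @param params A `"registry_params"` object.
#' @return `params`, invisibly; stops with an informative error otherwise.
#' @export
validate_registry_params <- function(params) {
  stopifnot(inherits(params, "registry_params"))
  with(params, {
    if (any(c(n_spont, n_fresh, n_frozen) < 0L))
      stop("group counts must be >= 0", call. = FALSE)
    for (m in list(culture_day_mix_fresh, culture_day_mix_frozen)) {
      if (any(m < 0) || sum(m) <= 0)
        stop("culture-day mixture weights must be nonnegative with a ",
             "positive sum", call. = FALSE)
      if (!all(names(m) %in% c("2", "3", "5")))
        stop("culture-day mixtures are over days {2, 3, 5}", call. = FALSE)
    }
    if (any(censor_target_fraction < 0 | censor_target_fraction >= 1))
      stop("censor_target_fraction must be in [0, 1)", call. = FALSE)
    if (us_error_sd_days <= 0)
      stop("us_error_sd_days must be > 0", call. = FALSE)
    if (follicular_spread_days <= 0 || follicular_skew <= 0 ||
        onset_spread_days <= 0)
      stop("distribution scale parameters must be > 0", call. = FALSE)
    if (preeclampsia_fraction < 0 || preeclampsia_fraction > 1)
      stop("preeclampsia_fraction must be in [0, 1]", call. = FALSE)
  })
  invisible(params)
}

#' @export
print.registry_params <- function(x, ...) {
  cat("Synthetic birth-registry parameters\n")
  cat(sprintf("  records: %d spontaneous, %d fresh ET, %d frozen ET\n",
              x$n_spont, x$n_fresh, x$n_frozen))
  cat(sprintf("  onset medians (d): %s; spread %.1f, skew %.1f\n",
              paste(x$onset_median_days, collapse = "/"),
              x$onset_spread_days, x$onset_skew))
  cat(sprintf("  follicular phase: median %.0f d (spread %.0f, skew %.2f)\n",
              x$follicular_median_days, x$follicular_spread_days,
              x$follicular_skew))
  cat(sprintf("  ultrasound error sd: %.1f d\n", x$us_error_sd_days))
  cat(sprintf("  nonspontaneous targets: %s\n",
              paste(sprintf("%.1f%%", 100 * x$censor_target_fraction),
                    collapse = "/")))
  cat(sprintf("  informative censoring: %s; seed %d\n",
              x$informative_censoring, x$seed))
  invisible(x)
}
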