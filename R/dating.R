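#' ART-based gestational age at birth
#'
#' Computes GA at birth on the ART-based scale:
#' `k + culture_days + transfer_to_birth`, where `k` is the assumed median
#' follicular-phase duration (customarily 14 days; 15 days removes the
#' systematic 1-day bias against the calibrated ultrasound scale),
#' `culture_days` counts days from oocyte fertilization to embryo transfer
#' (fresh ET) or to embryo cryopreservation (frozen ET), and
#' `transfer_to_birth` counts days from transfer to birth.
#'
#' @param k Follicular-phase constant in days (any positive integer; see
#'   [K14] and [K15]).
#' @param culture_days Days of in-vitro embryo culture, `>= 0`.
#' @param transfer_to_birth Days from embryo transfer to birth, `>= 0`.
#' @return GA at birth in days. Vectorized.
#' @examples
#' ga_art_at_birth(14, 5, 260)  # 279
#' ga_art_at_birth(15, 5, 260) - ga_art_at_birth(14, 5, 260)  # always 1
#' @export
ga_art_at_birth <- function(k, culture_days, transfer_to_birth) {
  if (any(k <= 0)) stop("k must be a positive number of days", call. = FALSE)
  if (any(culture_days < 0, na.rm = TRUE) ||
      any(transfer_to_birth < 0, na.rm = TRUE))
    stop("culture_days and transfer_to_birth must be >= 0", call. = FALSE)
  k + culture_days + transfer_to_birth
}

#' Propagate a GA estimate to an earlier calendar date
#'
#' A registry records GA at birth; the GA on the same scale at any earlier
#' date follows by subtracting the elapsed days:
#' `ga_at_birth - (birth_date - query_date)`. The operation applies
#' identically to the ultrasound and ART-based scales, so the difference
#' between two scales for the same pregnancy is constant over the whole
#' pregnancy.
#'
#' @param ga_at_birth GA in days at `birth_date`.
#' @param birth_date,query_date Calendar dates (`Date`); `query_date` must
#'   not be after `birth_date`.
#' @return GA in whole days at `query_date`. Vectorized.
#' @examples
#' ga_at_date(280, as.Date("2020-01-29"), as.Date("2020-01-01"))  # 252
#' @export
ga_at_date <- function(ga_at_birth, birth_date, query_date) {
  birth_date <- as.Date(birth_date)
  query_date <- as.Date(query_date)
  if (any(query_date > birth_date, na.rm = TRUE))
    stop("query_date must be on or before birth_date", call. = FALSE)
  ga_at_birth - as.integer(birth_date - query_date)
}

#' Estimated date of delivery on the 283-day calibrated scale
#'
#' The calibrated ultrasound scale puts the median GA at birth at 283 days,
#' so gestational day 283 defines the EDD: `ref_date + (283 - ga_at_ref)`.
#'
#' @param ga_at_ref GA in days at `ref_date`.
#' @param ref_date Calendar date (`Date`) at which `ga_at_ref` holds.
#' @return The EDD as a `Date`. Vectorized.
#' @examples
#' edd(283, as.Date("2020-06-06"))            # already at EDD
#' edd(126, as.Date("2020-01-01"))            # 157 days later
#' @export
edd <- function(ga_at_ref, ref_date) {
  as.Date(ref_date) + (283 - ga_at_ref)
}

#' Pairwise difference between ultrasound and ART-based GA
#'
#' For ART-conceived records, computes `GA_US - GA_ART,k` at birth: the
#' registry-recorded ultrasound GA at birth minus [ga_art_at_birth()] with
#' `transfer_to_birth = birth_date - transfer_date`. Because both scales
#' advance one day per calendar day, this difference is the same at every
#' point of the pregnancy; the sign convention is ultrasound minus ART.
#'
#' @param records A cohort `data.frame` (see [simulate_cohort()]); rows must
#'   be ART-conceived with complete `culture_days`, `transfer_date`,
#'   `birth_date` and `ga_us_birth_days`.
#' @param k Follicular-phase constant in days.
#' @return Numeric vector of per-record differences in days.
#' @examples
#' coh <- simulate_cohort(registry_params(n_fresh = 20, seed = 1))
#' d14 <- pairwise_ga_difference(coh, k = 14)
#' d15 <- pairwise_ga_difference(coh, k = 15)
#' stopifnot(all(d14 - d15 == 1))
#' @export
pairwise_ga_difference <- function(records, k) {
  if (!all(records$conception_mode %in% c("fresh_et", "frozen_et")))
    stop("pairwise GA differences are defined for ART records only",
         call. = FALSE)
  needed <- c("culture_days", "transfer_date", "birth_date",
              "ga_us_birth_days")
  ok <- stats::complete.cases(records[needed])
  if (!all(ok))
    stop("ART records with missing dating fields: ",
         paste(utils::head(records$id[!ok], 5), collapse = ", "),
         call. = FALSE)
  t2b <- as.integer(as.Date(records$birth_date) -
                      as.Date(records$transfer_date))
  records$ga_us_birth_days -
    ga_art_at_birth(k, records$culture_days, t2b)
}
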