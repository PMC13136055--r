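#' Simulate a synthetic birth-registry cohort
#'
#' Generates one-row-per-singleton-birth pregnancy records with the
#' statistical structure assumed by the downstream dating and time-to-event
#' analyses, so that every pipeline stage is testable without access to real
#' registry data.
#'
#' For each record the generator draws, in order:
#' \enumerate{
#'   \item a follicular phase `F` (days from LMP day 0 to oocyte
#'     fertilization / ovulation) from a shifted lognormal with median
#'     `follicular_median_days`, rounded to whole days;
#'   \item for ART records, an embryo-culture duration from the group's
#'     mixture over days \{2, 3, 5\}; fresh-ET transfer happens
#'     `culture_days` after fertilization, frozen-ET transfer happens in a
#'     later cycle, `culture_days` after the (virtual) transfer-cycle
#'     ovulation, with the cryostorage interval separating fertilization
#'     from transfer;
#'   \item a latent spontaneous-onset GA from a left-skewed skew-normal with
#'     the group median;
#'   \item a candidate intervention GA (concentrated between roughly 260
#'     days and term), realized with a per-group probability tuned so the
#'     expected nonspontaneous fraction matches `censor_target_fraction`;
#'     the candidate is drawn independently of the latent onset unless
#'     `informative_censoring` is on, in which case it is placed shortly
#'     before the latent onset;
#'   \item the observed birth GA as the minimum of latent onset and realized
#'     intervention, and the registry-recorded ultrasound GA at birth as the
#'     true GA plus rounded Gaussian error, truncated at 154 days
#'     (22 weeks).
#' }
#'
#' Nonspontaneous births are assigned an onset type (induced 73\%, elective
#' Cesarean 25\%, pre-labor emergency Cesarean 2\%) and flagged as
#' pre-eclamptic with probability `preeclampsia_fraction`. Columns prefixed
#' `latent_` are generator ground truth that a real registry would not
#' contain; [analysis_input()] strips them.
#'
#' @param params A [registry_params()] object.
#' @return A `data.frame` with one row per birth and columns `id`,
#'   `conception_mode`, `lmp_date`, `fertilization_date`, `culture_days`,
#'   `transfer_date`, `birth_date`, `ga_us_birth_days`, `onset_type`,
#'   `preeclampsia`, `plurality`, `perinatal_death`, `malformation`,
#'   `maternal_age_years`, `parity`, `fetal_sex`, `latent_onset_ga_days`,
#'   `latent_follicular_days`, `latent_intervention_ga_days`.
#' @examples
#' coh <- simulate_cohort(registry_params(n_fresh = 5, seed = 1))
#' coh$transfer_date - coh$fertilization_date  # culture days
#' @export
simulate_cohort <- function(params) {
  validate_registry_params(params)
  old_seed <- .GlobalEnv$.Random.seed
  on.exit({
    if (is.null(old_seed)) {
      rm(".Random.seed", envir = .GlobalEnv)
    } else {
      assign(".Random.seed", old_seed, envir = .GlobalEnv)
    }
  })
  set.seed(params$seed, kind = "Mersenne-Twister")

  groups <- list(
    spontaneous = params$n_spont,
    fresh_et = params$n_fresh,
    frozen_et = params$n_frozen
  )
  parts <- lapply(names(groups), function(g) {
    .simulate_group(g, groups[[g]], params)
  })
  out <- do.call(rbind, parts)
  if (is.null(out)) stop("no records requested", call. = FALSE)
  rownames(out) <- NULL
  out$id <- sprintf("P%06d", seq_len(nrow(out)))
  out[c("id", setdiff(names(out), "id"))]
}

.simulate_group <- function(group, n, params) {
  if (n == 0L) return(NULL)
  is_art <- group != "spontaneous"

  # calendar anchor: spread LMP dates over a 6-year registry window
  lmp <- as.Date("2015-01-01") + sample.int(2190L, n, replace = TRUE) - 1L

  # follicular phase, whole days
  shift <- params$follicular_median_days - params$follicular_spread_days
  follic <- round(shift + rlnorm(n, meanlog = log(params$follicular_spread_days),
                                 sdlog = params$follicular_skew))
  follic <- pmax(follic, 7)

  # latent spontaneous-onset GA (continuous days)
  xi <- .sn_location_for_median(params$onset_median_days[[group]],
                                params$onset_spread_days, params$onset_skew)
  onset <- xi + params$onset_spread_days * .rsn(n, params$onset_skew)
  onset <- pmax(onset, 160)

  # intervention process: candidate time + tuned Bernoulli realization
  target <- params$censor_target_fraction[[group]]
  if (params$informative_censoring) {
    cand <- onset - 1 - rexp(n, rate = 1 / 4)
  } else {
    cand <- rnorm(n, mean = 279, sd = 9)
  }
  cand <- pmax(cand, 230)
  eligible <- cand < onset
  s <- mean(eligible)
  p_real <- if (target <= 0 || s <= 0) 0 else min(1, target / s)
  intervened <- eligible & (runif(n) < p_real)

  birth_ga <- ifelse(intervened, cand, onset)
  birth_off <- as.integer(round(birth_ga))
  ga_us <- as.integer(pmax(154L, round(birth_off +
                                         rnorm(n, 0, params$us_error_sd_days))))

  onset_type <- rep("spontaneous", n)
  n_ns <- sum(intervened)
  if (n_ns > 0L) {
    onset_type[intervened] <- sample(
      c("induced", "elective_cs", "emergency_cs_prelabor"),
      n_ns, replace = TRUE, prob = c(0.73, 0.25, 0.02))
  }
  preec <- rep(FALSE, n)
  if (n_ns > 0L) {
    preec[intervened] <- runif(n_ns) < params$preeclampsia_fraction
  }

  if (is_art) {
    mix <- if (group == "fresh_et") params$culture_day_mix_fresh else
      params$culture_day_mix_frozen
    culture <- sample(as.integer(names(mix)), n, replace = TRUE,
                      prob = mix / sum(mix))
    if (group == "fresh_et") {
      fert <- lmp + follic
      transfer <- fert + culture
    } else {
      # frozen ET: lmp is the virtual LMP of the transfer cycle; the embryo
      # was fertilized and cryopreserved in an earlier cycle
      transfer <- lmp + follic + culture
      storage <- sample(30:700, n, replace = TRUE)
      fert <- transfer - culture - storage
    }
  } else {
    culture <- rep(NA_integer_, n)
    fert <- as.Date(rep(NA, n))
    transfer <- as.Date(rep(NA, n))
  }

  data.frame(
    conception_mode = group,
    lmp_date = lmp,
    fertilization_date = fert,
    culture_days = culture,
    transfer_date = transfer,
    birth_date = lmp + birth_off,
    ga_us_birth_days = ga_us,
    onset_type = onset_type,
    preeclampsia = preec,
    plurality = 1L,
    perinatal_death = FALSE,
    malformation = FALSE,
    maternal_age_years = round(pmin(45, pmax(18,
      rnorm(n, 30 + 2 * is_art, 4.5))), 1),
    parity = rbinom(n, 3L, 0.3),
    fetal_sex = sample(c("male", "female"), n, replace = TRUE,
                       prob = c(0.514, 0.486)),
    latent_onset_ga_days = onset,
    latent_follicular_days = follic,
    latent_intervention_ga_days = cand,
    stringsAsFactors = FALSE
  )
}

#' Strip generator ground truth from a cohort
#'
#' Returns the columns a real registry extract would contain, dropping the
#' `latent_*` ground-truth columns (and, for ART records, nothing else). Use
#' this to feed simulated cohorts through the analysis exactly as observed
#' data would be.
#'
#' @param records A cohort `data.frame` from [simulate_cohort()] or
#'   [read_registry()].
#' @return The same `data.frame` without `latent_*` columns.
#' @export
analysis_input <- function(records) {
  records[, !grepl("^latent_", names(records)), drop = FALSE]
}
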