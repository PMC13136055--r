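#' Summarize agreement between two dating scales
#'
#' Describes the distribution of pairwise GA differences (ultrasound minus
#' ART-based, see [pairwise_ga_difference()]): sample median, quartile
#' offsets relative to the median, a frequency table of absolute differences
#' binned as \{<= 1, 2, 3, 4, >= 5\} days, and (optionally) a percentile
#' bootstrap CI for the median.
#'
#' Quartiles use linear interpolation of order statistics
#' (`quantile(type = 7)`). Fractional differences are rounded half away from
#' zero before binning, matching integer-day registry histograms.
#'
#' @param diffs Numeric vector of per-pregnancy GA differences in days
#'   (`n >= 1`).
#' @param conf Logical; compute a bootstrap CI for the median (requires
#'   `n >= 2`).
#' @param B,level,seed Bootstrap settings passed to [bootstrap_median_ci()].
#' @return An object of class `"agreement_summary"`: a list with `n`,
#'   `median_diff`, `q1_offset`, `q3_offset`, `freq_table` (named integer
#'   counts), `freq_percent` (one decimal), `ci_median` (length-2 numeric or
#'   `NULL`) and `ci_method`.
#' @examples
#' summarize_agreement(c(-1, 0, 0, 1, 2), conf = FALSE)
#' @export
summarize_agreement <- function(diffs, conf = TRUE, B = 10000,
                                level = 0.95, seed = 1L) {
  if (length(diffs) < 1L || anyNA(diffs))
    stop("diffs must be non-empty and complete", call. = FALSE)
  q <- unname(quantile(diffs, c(0.25, 0.5, 0.75), type = 7))
  abs_d <- abs(round_half_away(diffs))
  bins <- c(`<=1` = sum(abs_d <= 1), `2` = sum(abs_d == 2),
            `3` = sum(abs_d == 3), `4` = sum(abs_d == 4),
            `>=5` = sum(abs_d >= 5))
  ci <- NULL
  if (conf && length(diffs) >= 2L)
    ci <- bootstrap_median_ci(diffs, B = B, level = level, seed = seed)
  structure(list(
    n = length(diffs),
    median_diff = q[2],
    q1_offset = q[1] - q[2],
    q3_offset = q[3] - q[2],
    freq_table = bins,
    freq_percent = round(100 * bins / length(diffs), 1),
    ci_median = ci,
    ci_method = if (is.null(ci)) NA_character_ else "percentile_bootstrap"
  ), class = "agreement_summary")
}

# round half away from zero (round() rounds half to even)
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' @export
print.agreement_summary <- function(x, ...) {
  cat(sprintf("Pairwise GA differences (n = %d)\n", x$n))
  if (!is.null(x$ci_median)) {
    cat(sprintf("  median %.1f d (%.0f%% CI %.1f to %.1f, %s)\n",
                x$median_diff, 100 * attr(x$ci_median, "level"),
                x$ci_median[1], x$ci_median[2], x$ci_method))
  } else {
    cat(sprintf("  median %.1f d\n", x$median_diff))
  }
  cat(sprintf("  quartiles %+.1f / %+.1f d from the median\n",
              x$q1_offset, x$q3_offset))
  cat("  |difference| (days): ",
      paste(sprintf("%s: %d (%.1f%%)", names(x$freq_table), x$freq_table,
                    x$freq_percent), collapse = ", "), "\n")
  invisible(x)
}

#' Percentile bootstrap CI for a sample median
#'
#' Resamples the data with replacement `B` times, takes the median of each
#' resample and returns the `(1-level)/2` and `1-(1-level)/2` percentiles.
#' Reproducible for a fixed seed; the caller's RNG state is untouched.
#'
#' @param x Numeric vector, `n >= 2`.
#' @param B Number of bootstrap resamples (`>= 1000`).
#' @param level Confidence level.
#' @param seed Integer seed.
#' @return Length-2 numeric `(lo, hi)` with attributes `level` and, when the
#'   input is constant (zero-width interval), `degenerate = TRUE`.
#' @examples
#' bootstrap_median_ci(rnorm(200), B = 1000, seed = 1)
#' @export
bootstrap_median_ci <- function(x, B = 10000, level = 0.95, seed = 1L) {
  if (length(x) < 2L) stop("need n >= 2", call. = FALSE)
  if (B < 1000) stop("need B >= 1000 resamples", call. = FALSE)
  n <- length(x)
  meds <- local_rng(seed, {
    if (.all_equal(x)) {
      rep(x[1], B)
    } else {
      out <- numeric(B)
      # chunked so memory stays bounded for large n
      chunk <- max(1L, min(B, floor(2e7 / n)))
      done <- 0L
      while (done < B) {
        b <- min(chunk, B - done)
        m <- matrix(x[sample.int(n, n * b, replace = TRUE)], nrow = n)
        out[done + seq_len(b)] <- apply(m, 2L, stats::median.default)
        done <- done + b
      }
      out
    }
  })
  ci <- unname(quantile(meds, c((1 - level) / 2, 1 - (1 - level) / 2),
                        type = 7))
  attr(ci, "level") <- level
  if (.all_equal(x)) attr(ci, "degenerate") <- TRUE
  ci
}

.all_equal <- function(x) length(unique(x)) == 1L

# evaluate expr under a temporary, seeded RNG stream
local_rng <- function(seed, expr) {
  old_seed <- .GlobalEnv$.Random.seed
  on.exit({
    if (is.null(old_seed)) rm(".Random.seed", envir = .GlobalEnv)
    else assign(".Random.seed", old_seed, envir = .GlobalEnv)
  })
  set.seed(seed, kind = "Mersenne-Twister")
  expr
}

#' Median ultrasound GA on the day of embryo transfer, by culture day
#'
#' Propagates the registry-recorded ultrasound GA at birth back to the
#' embryo-transfer date with [ga_at_date()] and summarizes it per
#' embryo-culture-day stratum. For fresh ET the transfer date is
#' `culture_days` after fertilization; for frozen ET the (thaw-)transfer
#' happens at the same developmental age, so the value equally measures the
#' GA-equivalent of the embryo on its cryopreservation day. Under a
#' correctly calibrated scale the stratum medians sit near
#' `follicular median + culture_days`, i.e. near the 15-day rather than
#' 14-day reference line.
#'
#' @param records ART records (one `conception_mode`) with complete dates.
#' @param B,level,seed Bootstrap CI settings (see [bootstrap_median_ci()]).
#' @return A `data.frame` with one row per culture day present: `culture_days`,
#'   `n`, `median_ga`, `ci_lo`, `ci_hi`. Strata with fewer than 2 records are
#'   omitted with a warning.
#' @examples
#' coh <- simulate_cohort(registry_params(n_fresh = 300, seed = 2))
#' ga_on_transfer_day_by_culture(coh, B = 1000)
#' @export
ga_on_transfer_day_by_culture <- function(records, B = 10000, level = 0.95,
                                          seed = 1L) {
  if (!all(records$conception_mode %in% c("fresh_et", "frozen_et")))
    stop("ART records only", call. = FALSE)
  ga_transfer <- ga_at_date(records$ga_us_birth_days, records$birth_date,
                            records$transfer_date)
  days <- sort(unique(records$culture_days))
  rows <- lapply(days, function(d) {
    g <- ga_transfer[records$culture_days == d]
    if (length(g) < 2L) {
      warning("culture-day ", d, " stratum has < 2 records; omitted")
      return(NULL)
    }
    ci <- bootstrap_median_ci(g, B = B, level = level, seed = seed + d)
    data.frame(culture_days = d, n = length(g),
               median_ga = unname(stats::median(g)),
               ci_lo = ci[1], ci_hi = ci[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
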