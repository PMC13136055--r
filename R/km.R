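#' Kaplan-Meier product-limit estimator
#'
#' Fits the product-limit estimate of the survival function
#' `S(t) = prod_{t_i <= t} (1 - d_i / n_i)` from right-censored times, with
#' the Greenwood variance of `log S` accumulated as
#' `sum d_i / (n_i (n_i - d_i))`. In the pregnancy-duration setting the
#' "time" is gestational age at birth, spontaneous onsets are events and
#' nonspontaneous births (inductions, pre-labor Cesareans) are censored, so
#' `S(t)` is the proportion of pregnancies still ongoing at GA `t` and
#' `F(t) = 1 - S(t)` the cumulative birth distribution.
#'
#' Ties at the same time follow the standard convention: events are
#' processed before censorings, i.e. a record censored at `t` is still at
#' risk for events at `t`.
#'
#' @param times Nonnegative times (days); one per record.
#' @param event Logical (or 0/1) event indicator per record; `TRUE` =
#'   observed event (spontaneous onset), `FALSE` = right-censored. At least
#'   one event is required.
#' @return An object of class `"ga_km"`: a list with `times` (distinct
#'   ascending observed times), `n_risk`, `n_event`, `n_censor`, `surv`,
#'   `var_logs` (all per time), and `n` (records used).
#' @examples
#' fit <- km_fit(c(5, 8, 12), c(TRUE, FALSE, TRUE))
#' fit$surv          # 2/3, 2/3, 0
#' survival_median(fit, interpolate = FALSE)
#' @export
km_fit <- function(times, event) {
  event <- as.logical(event)
  if (length(times) != length(event) || anyNA(times) || anyNA(event))
    stop("times and event must be complete and of equal length",
         call. = FALSE)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  if (!any(event)) stop("no events: survival curve is unidentified",
                        call. = FALSE)
  n <- length(times)
  tt <- sort(unique(times))
  idx <- match(times, tt)
  d <- tabulate(idx[event], nbins = length(tt))
  c_ <- tabulate(idx[!event], nbins = length(tt))
  # at risk just before t (ties: censorings at t still at risk at t)
  removed <- cumsum(d + c_)
  n_risk <- n - c(0, removed[-length(removed)])
  frac <- ifelse(n_risk > 0, 1 - d / n_risk, 1)
  surv <- cumprod(frac)
  gw <- ifelse(d > 0 & n_risk > d, d / (n_risk * (n_risk - d)),
               ifelse(d > 0 & n_risk == d, NA_real_, 0))
  var_logs <- cumsum(ifelse(is.na(gw), 0, gw))
  # once S hits 0 the log-scale variance is undefined; mark NA from there on
  var_logs[surv <= 0] <- NA_real_
  structure(list(times = tt, n_risk = n_risk, n_event = d, n_censor = c_,
                 surv = surv, var_logs = var_logs, n = n),
            class = "ga_km")
}

#' Cumulative birth distribution from a survival curve
#'
#' @param curve A `"ga_km"` object.
#' @return A `data.frame` with `time`, `F` (`= 1 - S`), `S`, `n_risk`.
#' @examples
#' cumulative_birth_distribution(km_fit(c(5, 8, 12), c(1, 0, 1)))
#' @export
cumulative_birth_distribution <- function(curve) {
  stopifnot(inherits(curve, "ga_km"))
  data.frame(time = curve$times, F = 1 - curve$surv, S = curve$surv,
             n_risk = curve$n_risk)
}

#' Median survival time
#'
#' The step median is the smallest observed time with `S(t) <= 0.5`. With
#' `interpolate = TRUE` (default) the crossing is refined by treating each
#' recorded day `t` as the interval `[t - 0.5, t + 0.5)` (registry GA is
#' recorded in whole days) and interpolating the cumulative distribution
#' linearly within the crossing day -- the classic grouped-data median.
#' This yields fractional-day medians (e.g. 286.1 rather than 286), removes
#' the half-day bias that interpolating between raw step times would give
#' on rounded data, and reduces exactly to the sample median of the event
#' times when there is no censoring.
#'
#' @param curve A `"ga_km"` object.
#' @param interpolate Logical; linearly interpolate between the event steps
#'   bracketing the 0.5 crossing.
#' @return The median in days.
#' @examples
#' survival_median(km_fit(c(5, 8, 12), c(1, 0, 1)), interpolate = FALSE)
#' @export
survival_median <- function(curve, interpolate = TRUE) {
  stopifnot(inherits(curve, "ga_km"))
  if (min(curve$surv) > 0.5)
    stop("survival never reaches 0.5: median undefined under this ",
         "censoring pattern", call. = FALSE)
  .median_from_steps(curve$times[curve$n_event > 0],
                     curve$surv[curve$n_event > 0], interpolate)
}

# median (or other F-quantile) from the event-step skeleton: times where S
# drops, with S(t-) = 1 before the first event. Interpolation spreads the
# births recorded on the crossing day uniformly over [t - 0.5, t + 0.5).
.quantile_from_steps <- function(times, surv, p, interpolate) {
  i <- which(surv <= 1 - p)[1]
  if (is.na(i)) return(NA_real_)
  if (!interpolate) return(times[i])
  s_hi <- if (i == 1L) 1 else surv[i - 1L]
  s_lo <- surv[i]
  if (s_hi <= 1 - p) return(times[i - 1L] + 0.5)  # plateau exactly at 1-p
  times[i] - 0.5 + (s_hi - (1 - p)) / (s_hi - s_lo)
}

.median_from_steps <- function(times, surv, interpolate) {
  .quantile_from_steps(times, surv, 0.5, interpolate)
}

#' @export
print.ga_km <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve: %d records, %d events, %d censored\n",
              x$n, sum(x$n_event), sum(x$n_censor)))
  med <- tryCatch(survival_median(x), error = function(e) NA_real_)
  if (!is.na(med)) cat(sprintf("  median: %.1f days\n", med))
  else cat("  median: undefined (S stays above 0.5)\n")
  invisible(x)
}

#' @export
summary.ga_km <- function(object, times = NULL, ...) {
  idx <- if (is.null(times)) seq_along(object$times) else
    vapply(times, function(t) {
      k <- which(object$times <= t)
      if (length(k)) max(k) else NA_integer_
    }, integer(1))
  out <- data.frame(
    time = if (is.null(times)) object$times else times,
    n_risk = object$n_risk[idx],
    n_event = object$n_event[idx],
    n_censor = object$n_censor[idx],
    surv = ifelse(is.na(idx), 1, object$surv[idx]),
    se_logs = sqrt(object$var_logs[idx])
  )
  out$surv[is.na(idx)] <- 1
  out
}

#' Plot a survival curve as a cumulative birth distribution
#'
#' Draws `F(t) = 1 - S(t)` as a step function, the usual display for
#' birth-distribution comparisons.
#'
#' @param x A `"ga_km"` object.
#' @param xlab,ylab,... Passed to [graphics::plot.default()].
#' @param cumulative Logical; plot `F(t)` (default) or `S(t)`.
#' @return `x`, invisibly.
#' @export
plot.ga_km <- function(x, xlab = "Gestational age (days)",
                       ylab = "Cumulative proportion born",
                       cumulative = TRUE, ...) {
  y <- if (cumulative) 1 - x$surv else x$surv
  graphics::plot(x$times, y, type = "s", xlab = xlab,
                 ylab = if (cumulative) ylab else "S(t)",
                 ylim = c(0, 1), ...)
  invisible(x)
}

#' @export
median.ga_km <- function(x, na.rm = FALSE, ...) survival_median(x)

#' Quantiles of the fitted event-time distribution
#'
#' @param x A `"ga_km"` object.
#' @param probs Probabilities (of having delivered), in (0, 1).
#' @param interpolate See [survival_median()].
#' @param ... Unused.
#' @return Named numeric vector of times at which `F(t)` reaches `probs`;
#'   `NA` where the curve never gets there.
#' @export
quantile.ga_km <- function(x, probs = c(0.25, 0.5, 0.75),
                           interpolate = TRUE, ...) {
  tt <- x$times[x$n_event > 0]
  ss <- x$surv[x$n_event > 0]
  out <- vapply(probs, function(p) .quantile_from_steps(tt, ss, p,
                                                        interpolate),
                numeric(1))
  names(out) <- paste0(format(100 * probs), "%")
  out
}
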