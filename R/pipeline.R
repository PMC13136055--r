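#' Configuration for a full analysis run
#'
#' Bundles everything [run_analysis()] needs: the input source, the
#' follicular-phase constants to compare, the censoring strategies, CI
#' settings and an output directory. A seed is mandatory because bootstrap
#' and Monte Carlo steps are always seeded.
#'
#' @param input A registry CSV path, a cohort `data.frame`, or a
#'   [registry_params()] object (in which case the cohort is simulated and
#'   reduced to observable columns).
#' @param k Distinct positive integers: follicular-phase constants to
#'   compare (default `c(14, 15)`).
#' @param strategies Subset of `c("censor", "exclude", "as_event")`.
#' @param bootstrap_B Bootstrap resamples for agreement-median CIs.
#' @param n_sim Monte Carlo replicates for survival-median CIs.
#' @param level Confidence level.
#' @param seed Integer seed controlling every stochastic step.
#' @param out_dir Optional directory; when given, [run_analysis()] writes
#'   the report tables, per-curve step functions and a JSON run manifest
#'   there.
#' @return An object of class `"analysis_config"`.
#' @export
analysis_config <- function(input, k = c(14L, 15L),
                            strategies = c("censor", "exclude", "as_event"),
                            bootstrap_B = 2000, n_sim = 2000, level = 0.95,
                            seed, out_dir = NULL) {
  if (missing(seed) || length(seed) != 1L || is.na(seed))
    stop("an explicit integer seed is required", call. = FALSE)
  k <- as.integer(k)
  if (anyDuplicated(k) || any(k <= 0))
    stop("k values must be distinct positive integers", call. = FALSE)
  strategies <- match.arg(strategies, several.ok = TRUE)
  structure(list(input = input, k = k, strategies = strategies,
                 bootstrap_B = bootstrap_B, n_sim = n_sim, level = level,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "analysis_config")
}

#' Run the full dating and pregnancy-duration analysis
#'
#' Orchestrates the pipeline: load or simulate records, apply exclusions,
#' compute pairwise dating-scale agreement per conception group and per
#' follicular-phase constant, estimate censoring-aware birth distributions
#' and their medians with Monte Carlo CIs on the ultrasound and ART scales,
#' compare group medians, compare censoring strategies, run the
#' competing-risks check with pre-eclamptic deliveries as a competing
#' cause, and summarize the day-of-transfer GA and transfer-to-birth
#' duration checks. Deterministic for a fixed config.
#'
#' @param config An [analysis_config()] object.
#' @return An object of class `"ga_report"`: a list of flat tables
#'   (`exclusions`, `proportions`, `agreement`, `group_medians`,
#'   `median_differences`, `strategy_medians`, `incidence`,
#'   `transfer_day_ga`, `remaining_duration`, `curves`) plus `config`.
#'   When `config$out_dir` is set the tables are also written as CSV with a
#'   JSON manifest.
#' @examples
#' cfg <- analysis_config(registry_params(n_spont = 400, n_fresh = 200,
#'                                        n_frozen = 200, seed = 9),
#'                        bootstrap_B = 1000, n_sim = 500, seed = 9)
#' rep <- run_analysis(cfg)
#' rep$proportions
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "analysis_config"))
  records <- .load_input(config$input)
  excl <- apply_exclusions(records)
  rec <- excl$records
  if (nrow(rec) == 0L) stop("no records retained", call. = FALSE)
  message(sprintf("run_analysis: %d records in, %d retained",
                  excl$tally$n_input, excl$tally$n_retained))

  event <- classify_onset(rec$onset_type) == "event"
  groups <- intersect(c("spontaneous", "fresh_et", "frozen_et"),
                      unique(rec$conception_mode))
  art_groups <- intersect(groups, c("fresh_et", "frozen_et"))
  seed <- config$seed

  proportions <- nonspontaneous_proportions(rec)

  # --- dating-scale agreement, per ART group and per k -------------------
  agreement <- NULL
  for (g in art_groups) for (kk in config$k) {
    sub <- rec[rec$conception_mode == g, , drop = FALSE]
    s <- summarize_agreement(pairwise_ga_difference(sub, kk),
                             B = config$bootstrap_B, level = config$level,
                             seed = seed + kk)
    agreement <- rbind(agreement, data.frame(
      conception_mode = g, k = kk, n = s$n, median_diff = s$median_diff,
      q1_offset = s$q1_offset, q3_offset = s$q3_offset,
      ci_lo = s$ci_median[1], ci_hi = s$ci_median[2],
      ci_method = s$ci_method,
      n_abs_le1 = s$freq_table[["<=1"]], n_abs_2 = s$freq_table[["2"]],
      n_abs_3 = s$freq_table[["3"]], n_abs_4 = s$freq_table[["4"]],
      n_abs_ge5 = s$freq_table[[">=5"]],
      pct_abs_le1 = s$freq_percent[["<=1"]],
      stringsAsFactors = FALSE))
  }

  # --- censoring-aware birth distributions per group and scale -----------
  curves <- list()
  group_medians <- NULL
  for (g in groups) {
    sub <- rec[rec$conception_mode == g, , drop = FALSE]
    sub_event <- event[rec$conception_mode == g]
    scales <- c("us", if (g %in% art_groups) paste0("art", config$k))
    for (sc in scales) {
      tms <- .scale_times(sub, sc)
      fit <- km_fit(tms, sub_event)
      curves[[paste(g, sc, sep = ".")]] <- fit
      est <- tryCatch(
        mc_median_ci(fit, n_sim = config$n_sim, level = config$level,
                     seed = .curve_seed(seed, fit)),
        error = function(e) NULL)
      group_medians <- rbind(group_medians, data.frame(
        conception_mode = g, scale = sc, n = fit$n,
        n_events = sum(fit$n_event),
        median_days = if (is.null(est)) NA_real_ else est$median,
        ci_lo = if (is.null(est)) NA_real_ else est$ci[1],
        ci_hi = if (is.null(est)) NA_real_ else est$ci[2],
        note = if (is.null(est)) "median undefined under censoring" else "",
        stringsAsFactors = FALSE))
    }
  }

  # --- median differences on the ultrasound scale ------------------------
  pairs <- list(c("frozen_et", "fresh_et"), c("fresh_et", "spontaneous"),
                c("frozen_et", "spontaneous"))
  median_differences <- NULL
  for (p in pairs) {
    if (!all(p %in% groups)) next
    ca <- curves[[paste(p[1], "us", sep = ".")]]
    cb <- curves[[paste(p[2], "us", sep = ".")]]
    est <- tryCatch(
      mc_median_difference_ci(ca, cb, n_sim = config$n_sim,
                              level = config$level, seed = seed),
      error = function(e) NULL)
    if (is.null(est)) next
    median_differences <- rbind(median_differences, data.frame(
      comparison = paste(p[1], "-", p[2]), scale = "us",
      difference_days = est$median, ci_lo = est$ci[1], ci_hi = est$ci[2],
      stringsAsFactors = FALSE))
  }

  # --- censoring-strategy comparison -------------------------------------
  strategy_medians <- NULL
  for (g in groups) for (st in config$strategies) {
    sub <- rec[rec$conception_mode == g, , drop = FALSE]
    med <- tryCatch(
      survival_median(strategy_compare(sub, st)),
      error = function(e) NA_real_)
    strategy_medians <- rbind(strategy_medians, data.frame(
      conception_mode = g, strategy = st, median_days = med,
      stringsAsFactors = FALSE))
  }

  # --- competing risks: pre-eclamptic delivery as competing cause --------
  incidence <- NULL
  for (g in groups) {
    sub <- rec[rec$conception_mode == g, , drop = FALSE]
    cause <- ifelse(sub$onset_type == "spontaneous", "onset",
                    ifelse(isTRUE_vec(sub$preeclampsia), "preeclampsia",
                           "censored"))
    ic <- tryCatch(aalen_johansen(sub$ga_us_birth_days, cause),
                   error = function(e) NULL)
    if (is.null(ic)) next
    last <- length(ic$times)
    incidence <- rbind(incidence, data.frame(
      conception_mode = g, n = ic$n,
      cif_onset = if ("onset" %in% ic$causes) ic$cif[last, "onset"] else 0,
      cif_preeclampsia = if ("preeclampsia" %in% ic$causes)
        ic$cif[last, "preeclampsia"] else 0,
      surv_event_free = ic$surv[last],
      stringsAsFactors = FALSE))
  }

  # --- fertilization-clock checks ----------------------------------------
  transfer_day_ga <- NULL
  remaining_duration <- NULL
  for (g in art_groups) {
    sub <- rec[rec$conception_mode == g, , drop = FALSE]
    td <- ga_on_transfer_day_by_culture(sub, B = config$bootstrap_B,
                                        level = config$level,
                                        seed = seed + 17)
    if (!is.null(td))
      transfer_day_ga <- rbind(transfer_day_ga,
                               cbind(conception_mode = g, td))
  }
  if (length(art_groups)) {
    art <- rec[rec$conception_mode %in% art_groups, , drop = FALSE]
    remaining_duration <- remaining_duration_by_culture(
      art, n_sim = config$n_sim, level = config$level, seed = seed + 23)
  }

  curve_table <- do.call(rbind, lapply(names(curves), function(nm) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    cb <- cumulative_birth_distribution(curves[[nm]])
    data.frame(conception_mode = parts[1], scale = parts[2],
               time = cb$time, S = cb$S, F = cb$F, n_risk = cb$n_risk,
               stringsAsFactors = FALSE)
  }))

  report <- structure(list(
    exclusions = excl$tally, proportions = proportions,
    agreement = agreement, group_medians = group_medians,
    median_differences = median_differences,
    strategy_medians = strategy_medians, incidence = incidence,
    transfer_day_ga = transfer_day_ga,
    remaining_duration = remaining_duration, curves = curve_table,
    config = config), class = "ga_report")
  if (!is.null(config$out_dir)) .write_report(report, config)
  report
}

.load_input <- function(input) {
  if (inherits(input, "registry_params"))
    return(analysis_input(simulate_cohort(input)))
  if (is.character(input)) return(read_registry(input))
  if (is.data.frame(input)) return(input)
  stop("input must be a registry_params object, a data.frame or a CSV path",
       call. = FALSE)
}

.scale_times <- function(sub, scale) {
  if (scale == "us") return(sub$ga_us_birth_days)
  k <- as.integer(sub("^art", "", scale))
  t2b <- as.integer(as.Date(sub$birth_date) - as.Date(sub$transfer_date))
  ga_art_at_birth(k, sub$culture_days, t2b)
}

.write_report <- function(report, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  tables <- c("proportions", "agreement", "group_medians",
              "median_differences", "strategy_medians", "incidence",
              "transfer_day_ga", "remaining_duration", "curves")
  for (tb in tables) {
    if (is.null(report[[tb]])) next
    write.csv(report[[tb]], file.path(config$out_dir, paste0(tb, ".csv")),
              row.names = FALSE, na = "NA", quote = FALSE)
  }
  excl <- report$exclusions
  write.csv(data.frame(rule = names(unclass(excl)),
                       count = unlist(unclass(excl), use.names = FALSE)),
            file.path(config$out_dir, "exclusions.csv"),
            row.names = FALSE, quote = FALSE)
  manifest <- list(
    package = "artga",
    version = as.character(utils::packageVersion("artga")),
    seed = config$seed, k = config$k, strategies = config$strategies,
    bootstrap_B = config$bootstrap_B, n_sim = config$n_sim,
    level = config$level,
    input = if (is.character(config$input)) config$input else
      class(config$input)[1])
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}

#' @export
print.ga_report <- function(x, ...) {
  cat("Pregnancy dating and duration analysis\n\n")
  print(x$exclusions)
  cat("\nNonspontaneous births:\n")
  print(x$proportions, row.names = FALSE)
  if (!is.null(x$agreement)) {
    cat("\nDating-scale agreement (GA_US - GA_ART,k, days):\n")
    print(x$agreement[c("conception_mode", "k", "n", "median_diff",
                        "ci_lo", "ci_hi", "pct_abs_le1")],
          row.names = FALSE)
  }
  cat("\nGroup medians (censoring-aware):\n")
  print(x$group_medians, row.names = FALSE)
  if (!is.null(x$median_differences)) {
    cat("\nMedian differences (ultrasound scale):\n")
    print(x$median_differences, row.names = FALSE)
  }
  if (!is.null(x$strategy_medians)) {
    cat("\nCensoring-strategy medians:\n")
    print(x$strategy_medians, row.names = FALSE)
  }
  invisible(x)
}
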