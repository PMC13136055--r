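#' Apply cohort inclusion and exclusion rules
#'
#' Filters a record collection to singleton live births without registered
#' congenital malformation, with ultrasound GA at birth between 154 days
#' (22 weeks) and 310 days inclusive, and (for ART records) complete dating
#' information. Each record is counted once, at the first rule it trips, in
#' the fixed order: multiple birth, perinatal death, malformation,
#' GA > 310 days, GA < 154 days, ART missing information. This single-counting
#' makes the tally conserve records: `n_input = n_retained + sum(counts)`.
#'
#' @param records A cohort `data.frame` with columns `plurality`,
#'   `perinatal_death`, `malformation`, `ga_us_birth_days`,
#'   `conception_mode`, and for ART rows `fertilization_date`,
#'   `transfer_date`, `culture_days`.
#' @return A list with elements `records` (the retained rows) and `tally`
#'   (class `"exclusion_tally"`: per-rule counts plus `n_input`,
#'   `n_retained`).
#' @examples
#' coh <- simulate_cohort(registry_params(n_spont = 50, seed = 1))
#' coh$plurality[1] <- 2L
#' apply_exclusions(coh)$tally
#' @export
apply_exclusions <- function(records) {
  n_input <- nrow(records)
  rules <- list(
    multiple_birth = records$plurality > 1L,
    perinatal_death = isTRUE_vec(records$perinatal_death),
    malformation = isTRUE_vec(records$malformation),
    ga_over_310 = records$ga_us_birth_days > 310,
    ga_under_154 = records$ga_us_birth_days < 154,
    art_missing_info = .art_missing(records)
  )
  counts <- integer(length(rules))
  names(counts) <- names(rules)
  excluded <- rep(FALSE, n_input)
  for (r in names(rules)) {
    trip <- rules[[r]] & !excluded
    trip[is.na(trip)] <- FALSE
    counts[[r]] <- sum(trip)
    excluded <- excluded | trip
  }
  tally <- structure(
    c(as.list(counts),
      list(n_input = n_input, n_retained = n_input - sum(counts))),
    class = "exclusion_tally")
  list(records = records[!excluded, , drop = FALSE], tally = tally)
}

isTRUE_vec <- function(x) !is.na(x) & x

# missing/ambiguous dating information among ART records: any of the dating
# fields absent. GA itself missing also trips this rule for ART records;
# missing flags on non-ART records never trip it.
.art_missing <- function(records) {
  art <- records$conception_mode %in% c("fresh_et", "frozen_et")
  miss <- is.na(records$fertilization_date) | is.na(records$transfer_date) |
    is.na(records$culture_days) | is.na(records$ga_us_birth_days)
  art & miss
}

#' @export
print.exclusion_tally <- function(x, ...) {
  cat("Cohort exclusions (applied in order, first rule tripped counts):\n")
  rules <- setdiff(names(x), c("n_input", "n_retained"))
  for (r in rules) cat(sprintf("  %-18s %8d\n", r, x[[r]]))
  cat(sprintf("  %-18s %8d\n", "input", x$n_input))
  cat(sprintf("  %-18s %8d\n", "retained", x$n_retained))
  invisible(x)
}

#' Classify onset of birth as event or censored
#'
#' Spontaneous onsets are events in the time-to-event analyses; induced
#' births, elective Cesarean sections and emergency Cesarean sections
#' performed before the onset of labor are nonspontaneous and treated as
#' right-censored.
#'
#' @param onset_type Character vector (or a cohort `data.frame`, in which
#'   case its `onset_type` column is used) with values among `spontaneous`,
#'   `induced`, `elective_cs`, `emergency_cs_prelabor`.
#' @return Character vector of `"event"` / `"censored"`.
#' @examples
#' classify_onset(c("spontaneous", "elective_cs"))
#' @export
classify_onset <- function(onset_type) {
  if (is.data.frame(onset_type)) onset_type <- onset_type$onset_type
  known <- c(spontaneous = "event", induced = "censored",
             elective_cs = "censored", emergency_cs_prelabor = "censored")
  bad <- !(onset_type %in% names(known))
  if (any(bad))
    stop("unknown onset_type: ",
         paste(unique(onset_type[bad]), collapse = ", "), call. = FALSE)
  unname(known[onset_type])
}

#' Per-group proportion of nonspontaneous births
#'
#' @param records A cohort `data.frame` with `conception_mode` and
#'   `onset_type`.
#' @return A `data.frame` with one row per conception group: `n_nonspont`,
#'   `n`, `fraction` (in `[0, 1]`) and `percent` (rounded to one decimal).
#'   Groups present in the data only; an empty input is an error.
#' @examples
#' coh <- simulate_cohort(registry_params(n_spont = 2000, seed = 3))
#' nonspontaneous_proportions(coh)
#' @export
nonspontaneous_proportions <- function(records) {
  if (nrow(records) == 0L) stop("no records", call. = FALSE)
  cls <- classify_onset(records$onset_type)
  groups <- unique(records$conception_mode)
  out <- do.call(rbind, lapply(groups, function(g) {
    sel <- records$conception_mode == g
    n <- sum(sel)
    ns <- sum(cls[sel] == "censored")
    data.frame(conception_mode = g, n_nonspont = ns, n = n,
               fraction = ns / n, percent = round(100 * ns / n, 1),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
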