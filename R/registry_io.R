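# Registry CSV interface. One header line, ISO-8601 dates, literal "NA" for
# missing values, columns exactly as the record schema (generator
# ground-truth columns are never written).

.registry_columns <- c(
  "id", "conception_mode", "lmp_date", "fertilization_date", "culture_days",
  "transfer_date", "birth_date", "ga_us_birth_days", "onset_type",
  "preeclampsia", "plurality", "perinatal_death", "malformation",
  "maternal_age_years", "parity", "fetal_sex")

.date_columns <- c("lmp_date", "fertilization_date", "transfer_date",
                   "birth_date")

#' Write pregnancy records to a registry CSV
#'
#' Writes the observable record columns (dropping `latent_*` ground truth)
#' as comma-separated text with ISO-8601 dates and `NA` for missing values.
#'
#' @param records A cohort `data.frame`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_registry <- function(records, path) {
  records <- analysis_input(records)
  missing_cols <- setdiff(.registry_columns, names(records))
  if (length(missing_cols))
    stop("records lack registry columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- records[.registry_columns]
  for (d in .date_columns) out[[d]] <- format(out[[d]], "%Y-%m-%d")
  write.csv(out, path, row.names = FALSE, na = "NA", quote = FALSE)
  invisible(path)
}

#' Read a registry CSV
#'
#' @param path Path to a CSV written in the registry schema (see
#'   [write_registry()]).
#' @param validate Logical; run [validate_registry()] and stop on problems.
#' @return A cohort `data.frame` with typed columns (`Date` dates, integer
#'   counts, logical flags).
#' @export
read_registry <- function(path, validate = TRUE) {
  rec <- read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  missing_cols <- setdiff(.registry_columns, names(rec))
  if (length(missing_cols))
    stop("registry file lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (d in .date_columns) rec[[d]] <- as.Date(rec[[d]], format = "%Y-%m-%d")
  rec$culture_days <- as.integer(rec$culture_days)
  rec$ga_us_birth_days <- as.integer(rec$ga_us_birth_days)
  rec$plurality <- as.integer(rec$plurality)
  rec$parity <- as.integer(rec$parity)
  for (l in c("preeclampsia", "perinatal_death", "malformation"))
    rec[[l]] <- as.logical(rec[[l]])
  if (validate) {
    problems <- validate_registry(rec)
    if (nrow(problems)) {
      shown <- utils::head(problems, 10)
      stop(nrow(problems), " schema problem(s) in ", path, "\n",
           paste(sprintf("  row %d, %s: %s", shown$row, shown$column,
                         shown$problem), collapse = "\n"),
           call. = FALSE)
    }
  }
  rec
}

#' Validate pregnancy records against the registry schema
#'
#' Checks every row for schema violations and returns one diagnostic row per
#' problem found (empty when the records are clean): unknown category
#' labels, unparseable or inconsistent dates (ART records need
#' `fertilization_date <= transfer_date <= birth_date`, fresh-ET records
#' need `transfer - fertilization = culture_days`, births must postdate all
#' other dates), negative GA, and nonpositive plurality.
#'
#' @param records A cohort `data.frame`.
#' @return A `data.frame` with columns `row`, `column`, `problem`.
#' @export
validate_registry <- function(records) {
  probs <- list()
  note <- function(rows, column, problem) {
    if (length(rows))
      probs[[length(probs) + 1L]] <<-
        data.frame(row = rows, column = column, problem = problem,
                   stringsAsFactors = FALSE)
  }
  n <- nrow(records)
  note(which(!records$conception_mode %in%
               c("spontaneous", "fresh_et", "frozen_et")),
       "conception_mode", "unknown conception mode")
  note(which(!records$onset_type %in%
               c("spontaneous", "induced", "elective_cs",
                 "emergency_cs_prelabor")),
       "onset_type", "unknown onset type")
  note(which(is.na(records$birth_date)), "birth_date", "missing birth date")
  note(which(!is.na(records$ga_us_birth_days) &
               records$ga_us_birth_days < 0),
       "ga_us_birth_days", "negative gestational age")
  note(which(!is.na(records$plurality) & records$plurality < 1L),
       "plurality", "plurality below 1")
  art <- records$conception_mode %in% c("fresh_et", "frozen_et")
  note(which(art & !is.na(records$culture_days) &
               !records$culture_days >= 0),
       "culture_days", "negative culture days")
  ok_ft <- !is.na(records$fertilization_date) & !is.na(records$transfer_date)
  note(which(art & ok_ft &
               records$fertilization_date > records$transfer_date),
       "fertilization_date", "fertilization after transfer")
  note(which(art & !is.na(records$transfer_date) &
               !is.na(records$birth_date) &
               records$transfer_date >= records$birth_date),
       "transfer_date", "transfer not before birth")
  fresh <- records$conception_mode == "fresh_et"
  note(which(fresh & ok_ft & !is.na(records$culture_days) &
               as.integer(records$transfer_date -
                            records$fertilization_date) !=
               records$culture_days),
       "culture_days", "fresh ET: transfer - fertilization != culture_days")
  out <- if (length(probs)) do.call(rbind, probs) else
    data.frame(row = integer(), column = character(),
               problem = character(), stringsAsFactors = FALSE)
  out[order(out$row), , drop = FALSE]
}
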