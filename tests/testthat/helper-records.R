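# Fixture builders: consistent pregnancy records constructed in code.

# ART records from GA components; dates are laid out so that
# birth - transfer = transfer_to_birth and transfer - fertilization =
# culture_days (fresh) as the schema requires.
make_art_records <- function(ga_us_birth, culture_days, transfer_to_birth,
                             conception_mode = "fresh_et") {
  n <- max(length(ga_us_birth), length(culture_days),
           length(transfer_to_birth))
  ga_us_birth <- rep_len(ga_us_birth, n)
  culture_days <- rep_len(as.integer(culture_days), n)
  transfer_to_birth <- rep_len(as.integer(transfer_to_birth), n)
  fert <- as.Date("2020-01-15") + seq_len(n)
  transfer <- fert + culture_days
  data.frame(
    id = sprintf("T%04d", seq_len(n)),
    conception_mode = rep_len(conception_mode, n),
    lmp_date = fert - 15L,
    fertilization_date = fert,
    culture_days = culture_days,
    transfer_date = transfer,
    birth_date = transfer + transfer_to_birth,
    ga_us_birth_days = as.integer(ga_us_birth),
    onset_type = "spontaneous",
    preeclampsia = FALSE,
    plurality = 1L,
    perinatal_death = FALSE,
    malformation = FALSE,
    maternal_age_years = 30,
    parity = 0L,
    fetal_sex = "female",
    stringsAsFactors = FALSE
  )
}

# minimal clean singleton record(s) for exclusion tests
make_plain_records <- function(n, conception_mode = "spontaneous",
                               ga_us_birth = 280L) {
  lmp <- as.Date("2019-06-01") + seq_len(n)
  is_art <- conception_mode != "spontaneous"
  data.frame(
    id = sprintf("C%05d", seq_len(n)),
    conception_mode = rep_len(conception_mode, n),
    lmp_date = lmp,
    fertilization_date = if (is_art) lmp + 15L else as.Date(rep(NA, n)),
    culture_days = rep_len(if (is_art) 3L else NA_integer_, n),
    transfer_date = if (is_art) lmp + 18L else as.Date(rep(NA, n)),
    birth_date = lmp + rep_len(as.integer(ga_us_birth), n),
    ga_us_birth_days = rep_len(as.integer(ga_us_birth), n),
    onset_type = rep_len("spontaneous", n),
    preeclampsia = rep_len(FALSE, n),
    plurality = rep_len(1L, n),
    perinatal_death = rep_len(FALSE, n),
    malformation = rep_len(FALSE, n),
    maternal_age_years = rep_len(30, n),
    parity = rep_len(0L, n),
    fetal_sex = rep_len("male", n),
    stringsAsFactors = FALSE
  )
}

# random right-censored survival instances for oracle cross-checks,
# with heavy ties to exercise the tie conventions
fuzz_survival_instance <- function(n, seed) {
  set.seed(seed)
  list(times = sample(1:25, n, replace = TRUE),
       event = c(TRUE, runif(n - 1) < 0.7))  # at least one event
}
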