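#' Read a dispensing claims table
#'
#' Parses a claims extract in which each row is one pharmacy fill:
#' `patient_id`, `fill_date` (ISO 8601), `ingredient`, `indication`
#' (`diabetes_oral`, `blood_pressure`, `cholesterol`, `insulin`, `other`),
#' and `days_supply` (a positive integer number of days).
#'
#' Claims extracts are dirty, so validation is collect-and-report rather
#' than fail-fast: rows violating an invariant (unparseable date,
#' non-positive `days_supply`, unknown indication, missing id) are dropped
#' and recorded, row-numbered, in the `problems` attribute (see
#' [validation_problems()]). Same-day duplicate fills of the same
#' ingredient are retained here; the CMG engine merges them by summing
#' supply. Drug-to-indication mapping is taken as given in the
#' `indication` column: resolving drug codes to therapeutic classes is the
#' caller's responsibility.
#'
#' @param path Path to a CSV file with a header row.
#' @param strict If `TRUE`, any invalid row aborts instead of being
#'   collected into the problems report.
#' @return A tibble of valid fills with typed columns (`fill_date` as
#'   `Date`, `days_supply` as integer). Attribute `problems` holds a
#'   tibble of rejected rows (`row`, `column`, `message`).
#' @seealso [read_eligibility()], [read_selfreports()], [filter_cohort()]
#' @export
read_dispensings <- function(path, strict = FALSE) {
  raw <- read_raw_csv(path, c("patient_id", "fill_date", "ingredient",
                              "indication", "days_supply"))
  probs <- list()
  note <- function(row, column, message) {
    probs[[length(probs) + 1L]] <<- tibble::tibble(
      row = row, column = column, message = message)
  }

  fill_date <- parse_iso_date(raw$fill_date)
  days_supply <- suppressWarnings(as.integer(raw$days_supply))

  for (i in seq_len(nrow(raw))) {
    if (is.na(raw$patient_id[i]) || !nzchar(raw$patient_id[i]))
      note(i, "patient_id", "missing patient id")
    if (is.na(fill_date[i]))
      note(i, "fill_date", sprintf("unparseable date '%s'", raw$fill_date[i]))
    if (is.na(days_supply[i]) || days_supply[i] < 1L)
      note(i, "days_supply",
           sprintf("days_supply must be a positive integer, got '%s'",
                   raw$days_supply[i]))
    if (is.na(raw$indication[i]) || !raw$indication[i] %in% INDICATION_LEVELS)
      note(i, "indication",
           sprintf("unknown indication '%s'", raw$indication[i]))
  }

  problems <- bind_problems(probs)
  ok <- !seq_len(nrow(raw)) %in% problems$row
  out <- tibble::tibble(
    patient_id = raw$patient_id[ok],
    fill_date = fill_date[ok],
    ingredient = raw$ingredient[ok],
    indication = raw$indication[ok],
    days_supply = days_supply[ok]
  )
  finish_read(out, problems, strict, what = "dispensing")
}

#' Read a patient eligibility table
#'
#' One row per patient: `patient_id`, `continuous_benefits` (whether the
#' patient held prescription benefits throughout the 12-month lookback),
#' and `dual_coverage` (alternative pharmacy coverage, e.g. dual
#' Medicaid/Medicare eligibility, which prevents complete claims capture).
#'
#' @inheritParams read_dispensings
#' @return A tibble with one row per patient; logical flag columns.
#'   Duplicate patient ids are a validation problem (first row kept).
#' @export
read_eligibility <- function(path, strict = FALSE) {
  raw <- read_raw_csv(path, c("patient_id", "continuous_benefits",
                              "dual_coverage"))
  probs <- list()
  cb <- parse_flag(raw$continuous_benefits)
  dc <- parse_flag(raw$dual_coverage)
  for (i in seq_len(nrow(raw))) {
    if (is.na(raw$patient_id[i]) || !nzchar(raw$patient_id[i]))
      probs[[length(probs) + 1L]] <- tibble::tibble(
        row = i, column = "patient_id", message = "missing patient id")
    if (is.na(cb[i]))
      probs[[length(probs) + 1L]] <- tibble::tibble(
        row = i, column = "continuous_benefits",
        message = sprintf("not a logical flag: '%s'",
                          raw$continuous_benefits[i]))
    if (is.na(dc[i]))
      probs[[length(probs) + 1L]] <- tibble::tibble(
        row = i, column = "dual_coverage",
        message = sprintf("not a logical flag: '%s'", raw$dual_coverage[i]))
    if (i > 1L && raw$patient_id[i] %in% raw$patient_id[seq_len(i - 1L)])
      probs[[length(probs) + 1L]] <- tibble::tibble(
        row = i, column = "patient_id",
        message = sprintf("duplicate patient id '%s'", raw$patient_id[i]))
  }
  problems <- bind_problems(probs)
  ok <- !seq_len(nrow(raw)) %in% problems$row
  out <- tibble::tibble(
    patient_id = raw$patient_id[ok],
    continuous_benefits = cb[ok],
    dual_coverage = dc[ok]
  )
  finish_read(out, problems, strict, what = "eligibility")
}

#' Read a self-report response table
#'
#' Each row is one 7-day recall answer to "in the last 7 days, how many
#' days did you miss taking your ... pill": `patient_id`, `source`
#' (`atsm` for automated telephone queries or `interview`), `indication`
#' (insulin responses are not analyzable and are rejected),
#' `response_date` (ISO 8601), `missed_days` (integer 0-7; the keypad and
#' interview instruments only admit that range).
#'
#' @inheritParams read_dispensings
#' @return A tibble of valid responses; rejected rows recorded as in
#'   [read_dispensings()].
#' @export
read_selfreports <- function(path, strict = FALSE) {
  raw <- read_raw_csv(path, c("patient_id", "source", "indication",
                              "response_date", "missed_days"))
  probs <- list()
  note <- function(row, column, message) {
    probs[[length(probs) + 1L]] <<- tibble::tibble(
      row = row, column = column, message = message)
  }
  response_date <- parse_iso_date(raw$response_date)
  missed_days <- suppressWarnings(as.integer(raw$missed_days))
  for (i in seq_len(nrow(raw))) {
    if (is.na(raw$patient_id[i]) || !nzchar(raw$patient_id[i]))
      note(i, "patient_id", "missing patient id")
    if (is.na(raw$source[i]) || !raw$source[i] %in% SOURCE_LEVELS)
      note(i, "source", sprintf("unknown source '%s'", raw$source[i]))
    if (is.na(raw$indication[i]) ||
        !raw$indication[i] %in% ANALYZABLE_INDICATIONS)
      note(i, "indication",
           sprintf("indication '%s' is not an analyzable self-report class",
                   raw$indication[i]))
    if (is.na(response_date[i]))
      note(i, "response_date",
           sprintf("unparseable date '%s'", raw$response_date[i]))
    if (is.na(missed_days[i]) || missed_days[i] < 0L || missed_days[i] > 7L)
      note(i, "missed_days",
           sprintf("missed_days must be an integer in [0, 7], got '%s'",
                   raw$missed_days[i]))
  }
  problems <- bind_problems(probs)
  ok <- !seq_len(nrow(raw)) %in% problems$row
  out <- tibble::tibble(
    patient_id = raw$patient_id[ok],
    source = raw$source[ok],
    indication = raw$indication[ok],
    response_date = response_date[ok],
    missed_days = missed_days[ok]
  )
  finish_read(out, problems, strict, what = "self-report")
}

#' Retrieve per-row validation problems from a read table
#'
#' @param x A tibble returned by one of the `read_*()` functions.
#' @return A tibble with columns `row`, `column`, `message` (zero rows if
#'   the file was clean).
#' @export
validation_problems <- function(x) {
  attr(x, "problems") %||%
    tibble::tibble(row = integer(), column = character(),
                   message = character())
}

#' Restrict claims to analyzable patients and indications
#'
#' Applies the cohort-level calculability gates: insulin fills are removed
#' (pharmacy data carries no fixed days supply for insulin), and all fills
#' of patients with dual pharmacy coverage (incomplete claims capture) or
#' without continuous benefits over the lookback are removed. Gates are
#' applied in a fixed precedence -- `dual_coverage`, then
#' `no_continuous_benefits`, then `insulin` -- so the removal tally is
#' reproducible when several reasons apply to one fill.
#'
#' @param records Dispensing tibble as from [read_dispensings()].
#' @param eligibility Eligibility tibble as from [read_eligibility()];
#'   must cover every patient appearing in `records`.
#' @return The retained fills, unaltered, with attribute `removal_tally`
#'   (named integer vector of removed-fill counts by reason; see
#'   [removal_tally()]).
#' @export
filter_cohort <- function(records, eligibility) {
  missing <- setdiff(unique(records$patient_id), eligibility$patient_id)
  if (length(missing) > 0L) {
    abort(sprintf(
      "patients in claims but absent from eligibility: %s",
      paste(missing, collapse = ", ")))
  }
  elig <- eligibility[match(records$patient_id, eligibility$patient_id), ]
  reason <- rep(NA_character_, nrow(records))
  reason[is.na(reason) & elig$dual_coverage] <- "dual_coverage"
  reason[is.na(reason) & !elig$continuous_benefits] <- "no_continuous_benefits"
  reason[is.na(reason) & records$indication == "insulin"] <- "insulin"

  tally <- c(
    dual_coverage = sum(reason == "dual_coverage", na.rm = TRUE),
    no_continuous_benefits = sum(reason == "no_continuous_benefits",
                                 na.rm = TRUE),
    insulin = sum(reason == "insulin", na.rm = TRUE)
  )
  out <- records[is.na(reason), , drop = FALSE]
  attr(out, "problems") <- attr(records, "problems")
  attr(out, "removal_tally") <- tally
  out
}

#' Removed-fill tally from [filter_cohort()]
#'
#' @param x A tibble returned by [filter_cohort()].
#' @return Named integer vector with counts for `dual_coverage`,
#'   `no_continuous_benefits`, and `insulin`.
#' @export
removal_tally <- function(x) {
  attr(x, "removal_tally") %||%
    c(dual_coverage = 0L, no_continuous_benefits = 0L, insulin = 0L)
}

# --- internal helpers -------------------------------------------------------

read_raw_csv <- function(path, expected_cols) {
  if (!file.exists(path)) {
    abort(sprintf("file not found: %s", path))
  }
  raw <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()), progress = FALSE)
  missing <- setdiff(expected_cols, names(raw))
  if (length(missing) > 0L) {
    abort(sprintf("%s is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  if (nrow(raw) == 0L) {
    warn(sprintf("%s contains a header but no rows", path))
  }
  raw
}

# strict ISO 8601 (YYYY-MM-DD); as.Date() alone would accept e.g. "2010-1-1"
# with other separators mangled to NA silently in some locales
parse_iso_date <- function(x) {
  out <- rep(as.Date(NA), length(x))
  well_formed <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  out[well_formed] <- as.Date(x[well_formed], format = "%Y-%m-%d")
  out
}

parse_flag <- function(x) {
  up <- toupper(trimws(as.character(x)))
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "T", "1", "YES")] <- TRUE
  out[up %in% c("FALSE", "F", "0", "NO")] <- FALSE
  out
}

bind_problems <- function(probs) {
  if (length(probs) == 0L) {
    return(tibble::tibble(row = integer(), column = character(),
                          message = character()))
  }
  dplyr::bind_rows(probs)
}

finish_read <- function(out, problems, strict, what) {
  if (nrow(problems) > 0L) {
    if (strict) {
      abort(sprintf(
        "%d invalid %s row(s); first: row %d (%s) %s",
        length(unique(problems$row)), what, problems$row[1],
        problems$column[1], problems$message[1]))
    }
    warn(sprintf("%d invalid %s row(s) dropped; see validation_problems()",
                 length(unique(problems$row)), what))
  }
  attr(out, "problems") <- problems
  out
}
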