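#' Select the analyzable self-report response
#'
#' For one patient, indication, and source, keeps the first (earliest
#' response date) or last completed response. The primary analysis uses
#' the first completed automated-query response, since later responses
#' may be shaped by intervening coaching; `mode = "last"` supports the
#' sensitivity analysis. Two responses on the same date are tie-broken
#' deterministically by keeping the lower `missed_days` (conservative
#' toward adherence) with a warning.
#'
#' @param responses Tibble of responses sharing `patient_id`,
#'   `indication`, and `source`.
#' @param mode `"first"` or `"last"`.
#' @return A one-row tibble, or a zero-row tibble if `responses` is empty.
#' @export
select_response <- function(responses, mode = c("first", "last")) {
  mode <- match.arg(mode)
  if (nrow(responses) == 0L) {
    return(responses)
  }
  target <- if (mode == "first") min(responses$response_date) else
    max(responses$response_date)
  hits <- responses[responses$response_date == target, , drop = FALSE]
  if (nrow(hits) > 1L) {
    warn(sprintf(
      "patient %s/%s/%s: %d responses on %s; keeping lowest missed_days",
      hits$patient_id[1], hits$indication[1], hits$source[1], nrow(hits),
      format(target)))
    hits <- hits[order(hits$missed_days), , drop = FALSE]
  }
  hits[1L, , drop = FALSE]
}

#' Select one response per patient, indication, and source
#'
#' Applies [select_response()] group-wise across a response table.
#'
#' @param responses Self-report tibble as from [read_selfreports()].
#' @inheritParams select_response
#' @return Tibble with at most one row per patient x indication x source.
#' @export
select_responses <- function(responses, mode = c("first", "last")) {
  mode <- match.arg(mode)
  if (nrow(responses) == 0L) {
    return(responses)
  }
  responses |>
    dplyr::group_by(.data$patient_id, .data$indication, .data$source) |>
    dplyr::group_modify(~ select_response(.x, mode = mode)) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(
      c("patient_id", "source", "indication", "response_date",
        "missed_days")))
}

#' Categorize 7-day missed-pill counts
#'
#' Maps reported missed days onto the three analysis categories: `zero`
#' (0 days), `one` (1 day), and `two_to_seven` (2-7 days). The three
#' categories partition the admissible 0-7 range.
#'
#' @param missed_days Integer vector in `[0, 7]`.
#' @return Factor with levels `zero`, `one`, `two_to_seven`.
#' @export
categorize_missed_days <- function(missed_days) {
  if (any(is.na(missed_days)) || any(missed_days < 0) || any(missed_days > 7) ||
      any(missed_days != as.integer(missed_days))) {
    abort("missed_days must be integers in [0, 7]")
  }
  labels <- ifelse(missed_days == 0, "zero",
                   ifelse(missed_days == 1, "one", "two_to_seven"))
  factor(labels, levels = MISSED_CATEGORY_LEVELS)
}

#' Pair automated-query and interview responses for concordance
#'
#' Emits one pair per patient and indication when both sources have a
#' selected response and the two response dates fall within
#' `window_days` of each other (absolute difference, either direction).
#' Unpaired selections are tallied by reason in the `unpaired` attribute:
#' `missing_source` (only one source responded) or `outside_window`.
#'
#' @param atsm,interview Selection tibbles from [select_responses()],
#'   one row per patient x indication, already restricted to their source.
#' @param window_days Maximum days between the two responses, default 30.
#' @return Tibble of pairs: `patient_id`, `indication`, `atsm_missed`,
#'   `interview_missed`, `atsm_date`, `interview_date`; attribute
#'   `unpaired` is a named integer tally.
#' @export
pair_for_concordance <- function(atsm, interview, window_days = 30L) {
  joined <- dplyr::full_join(
    dplyr::select(atsm, "patient_id", "indication",
                  atsm_missed = "missed_days", atsm_date = "response_date"),
    dplyr::select(interview, "patient_id", "indication",
                  interview_missed = "missed_days",
                  interview_date = "response_date"),
    by = c("patient_id", "indication"))
  both <- !is.na(joined$atsm_missed) & !is.na(joined$interview_missed)
  delta <- abs(as.integer(joined$atsm_date - joined$interview_date))
  in_window <- both & delta <= window_days
  out <- joined[in_window, , drop = FALSE]
  attr(out, "unpaired") <- c(
    missing_source = sum(!both),
    outside_window = sum(both & !in_window))
  out
}
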