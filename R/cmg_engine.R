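#' Select fills inside a 12-month lookback window
#'
#' Restricts one patient-and-indication fill series to the lookback window
#' `[index_date - window_days, index_date]` (both endpoints inclusive),
#' sorts by date, and merges same-day fills of the same ingredient by
#' summing their days supply. Fills before the window are ignored entirely
#' even if their supply would extend into it: the window has no run-in
#' provision (a documented limitation).
#'
#' @param fills Tibble of fills for one patient and indication with
#'   columns `fill_date`, `ingredient`, `days_supply` (and optionally
#'   `patient_id`, `indication`, carried through).
#' @param index_date The adherence-assessment date anchoring the lookback.
#' @param window_days Length of the lookback, default 365 (12 months).
#' @return The windowed, date-ordered, same-day-merged fills.
#' @export
select_window_fills <- function(fills, index_date, window_days = 365L) {
  index_date <- as.Date(index_date)
  lo <- index_date - window_days
  keep <- fills$fill_date >= lo & fills$fill_date <= index_date
  out <- fills[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    return(out)
  }
  out <- out |>
    dplyr::group_by(dplyr::across(dplyr::any_of(
      c("patient_id", "indication", "ingredient", "fill_date")))) |>
    dplyr::summarise(days_supply = sum(.data$days_supply),
                     .groups = "drop") |>
    dplyr::arrange(.data$ingredient, .data$fill_date)
  out
}

#' Time-forward gap accounting over one ingredient's refill intervals
#'
#' Walks the refill intervals of one ingredient in date order. In the
#' interval opened by fill *k*, the usable supply is the supply dispensed
#' at *k* plus any surplus carried over from earlier intervals; days of
#' the interval beyond that supply are gap days, and supply beyond the
#' interval length carries forward. Carrying surplus only forward is what
#' makes the algorithm "time-forward": a later fill, however large, never
#' erases a gap already incurred (stockpiling cannot retroactively mask
#' non-adherence). Observation runs from the first to the last fill, so
#' supply remaining at the final fill is discarded.
#'
#' @param fills Tibble with `fill_date` (strictly increasing after
#'   same-day merging) and `days_supply`, all one ingredient.
#' @return A list with `gap_days`, `observed_days` (both integer), and
#'   `intervals`, a trace tibble with one row per refill interval
#'   (`start_date`, `end_date`, `length_days`, `supply_available`,
#'   `gap_days`, `carryover_out`) for audit.
#' @export
time_forward_gaps <- function(fills) {
  if (nrow(fills) < 2L) {
    abort("time_forward_gaps() needs at least 2 fills (one refill interval)",
          class = "cmgap_fewer_than_two_fills")
  }
  dates <- as.Date(fills$fill_date)
  supply <- as.integer(fills$days_supply)
  if (any(diff(as.integer(dates)) <= 0L)) {
    abort("fill dates must be strictly increasing; merge same-day fills first")
  }
  n_int <- length(dates) - 1L
  len <- as.integer(diff(dates))
  avail <- integer(n_int)
  gap <- integer(n_int)
  carry_out <- integer(n_int)
  carry <- 0L
  for (k in seq_len(n_int)) {
    avail[k] <- carry + supply[k]
    gap[k] <- max(0L, len[k] - avail[k])
    carry_out[k] <- max(0L, avail[k] - len[k])
    carry <- carry_out[k]
  }
  list(
    gap_days = sum(gap),
    observed_days = sum(len),
    intervals = tibble::tibble(
      start_date = dates[seq_len(n_int)],
      end_date = dates[seq_len(n_int) + 1L],
      length_days = len,
      supply_available = avail,
      gap_days = gap,
      carryover_out = carry_out
    )
  )
}

#' Day-by-day inventory simulation of supply gaps
#'
#' Reference implementation of the same quantity as
#' [time_forward_gaps()], by brute force: simulate a pill inventory one
#' day at a time from the first to the last fill date, adding each fill's
#' supply on its date, consuming one day of supply per day when any is on
#' hand, and counting a gap day otherwise. Used as an independent oracle
#' in the test suite; the interval-arithmetic engine must agree with it on
#' every input.
#'
#' @inheritParams time_forward_gaps
#' @return A list with `gap_days` and `observed_days`.
#' @export
daily_inventory_oracle <- function(fills) {
  if (nrow(fills) < 2L) {
    abort("daily_inventory_oracle() needs at least 2 fills",
          class = "cmgap_fewer_than_two_fills")
  }
  dates <- as.integer(as.Date(fills$fill_date))
  supply <- as.integer(fills$days_supply)
  first <- dates[1]
  last <- dates[length(dates)]
  inventory <- 0L
  gap <- 0L
  for (day in first:(last - 1L)) {
    inventory <- inventory + sum(supply[dates == day])
    if (inventory > 0L) {
      inventory <- inventory - 1L
    } else {
      gap <- gap + 1L
    }
  }
  list(gap_days = gap, observed_days = last - first)
}

#' Classify a continuous medication gap at the optimal-adherence threshold
#'
#' Adherence is optimal when medication was available at least 80% of
#' observed time, i.e. CMG <= 20%; the boundary value itself is optimal.
#'
#' @param cmg Numeric vector of gap fractions in `[0, 1]`.
#' @param threshold Optimal-adherence cut point, default 0.20.
#' @return Character vector, `"optimal"` or `"suboptimal"`.
#' @export
classify_adherence <- function(cmg, threshold = 0.20) {
  if (any(is.na(cmg)) || any(cmg < 0) || any(cmg > 1)) {
    abort("cmg must lie in [0, 1]")
  }
  # small epsilon keeps the boundary decision exact for ratios of integers
  ifelse(cmg <= threshold + 1e-9, "optimal", "suboptimal")
}

#' Continuous medication gap for one patient and indication
#'
#' Applies the calculability gates in fixed precedence (insulin excluded,
#' then dual coverage, then missing continuous benefits, then fewer than
#' two fills), windows and merges the fills, runs [time_forward_gaps()]
#' per ingredient for every ingredient with at least two windowed fills,
#' aggregates to an indication-level CMG, and classifies adherence at the
#' threshold. Different ingredients within an indication are independent
#' supply series: supply of one drug never covers days of another.
#'
#' @param fills Fills for one patient and one indication (may be empty).
#' @param index_date Assessment date anchoring the 12-month lookback.
#' @param window_days Lookback length in days, default 365.
#' @param patient_id,indication Identify the result row when `fills` is
#'   empty; defaulted from `fills` otherwise.
#' @param dual_coverage,continuous_benefits The patient's eligibility
#'   flags over the lookback.
#' @param threshold Optimal-adherence cut point on the gap fraction.
#' @param aggregation How to combine multiple ingredients within the
#'   indication: `"pooled_days"` (default) divides total gap days by total
#'   observed days across qualifying ingredients, weighting each by its
#'   observed time and keeping the result a true day proportion;
#'   `"mean_per_ingredient"` averages per-ingredient gap fractions
#'   unweighted.
#' @return A one-row tibble: `patient_id`, `indication`, `index_date`,
#'   `observed_days`, `gap_days`, `cmg`, `calculable`,
#'   `non_calculable_reason`, `adherence_class`, plus an `intervals`
#'   attribute holding the per-interval audit trace.
#' @export
compute_indication_cmg <- function(fills, index_date,
                                   window_days = 365L,
                                   patient_id = NULL, indication = NULL,
                                   dual_coverage = FALSE,
                                   continuous_benefits = TRUE,
                                   threshold = 0.20,
                                   aggregation = c("pooled_days",
                                                   "mean_per_ingredient")) {
  aggregation <- match.arg(aggregation)
  patient_id <- patient_id %||%
    (if (nrow(fills) > 0L) fills$patient_id[1] else NA_character_)
  indication <- indication %||%
    (if (nrow(fills) > 0L) fills$indication[1] else NA_character_)

  not_calc <- function(reason) {
    res <- tibble::tibble(
      patient_id = patient_id, indication = indication,
      index_date = as.Date(index_date),
      observed_days = NA_integer_, gap_days = NA_integer_,
      cmg = NA_real_, calculable = FALSE,
      non_calculable_reason = reason,
      adherence_class = "not_applicable")
    attr(res, "intervals") <- empty_interval_trace()
    res
  }

  if (identical(indication, "insulin")) {
    return(not_calc("insulin_excluded"))
  }
  if (isTRUE(dual_coverage)) {
    return(not_calc("dual_coverage"))
  }
  if (!isTRUE(continuous_benefits)) {
    return(not_calc("no_continuous_benefits"))
  }

  windowed <- select_window_fills(fills, index_date, window_days)
  per_ing <- list()
  if (nrow(windowed) > 0L) {
    for (ing in unique(windowed$ingredient)) {
      sub <- windowed[windowed$ingredient == ing, , drop = FALSE]
      if (nrow(sub) >= 2L) {
        res <- time_forward_gaps(sub)
        res$intervals$ingredient <- ing
        per_ing[[ing]] <- res
      }
    }
  }
  if (length(per_ing) == 0L) {
    return(not_calc("fewer_than_two_fills"))
  }

  gap_days <- sum(vapply(per_ing, `[[`, integer(1), "gap_days"))
  observed_days <- sum(vapply(per_ing, `[[`, integer(1), "observed_days"))
  cmg <- if (aggregation == "pooled_days") {
    gap_days / observed_days
  } else {
    mean(vapply(per_ing, function(r) r$gap_days / r$observed_days,
                numeric(1)))
  }
  adherence <- if (aggregation == "pooled_days") {
    # exact rational comparison: gap/observed <= threshold
    if (gap_days <= threshold * observed_days + 1e-9) "optimal" else "suboptimal"
  } else {
    classify_adherence(cmg, threshold)
  }

  res <- tibble::tibble(
    patient_id = patient_id, indication = indication,
    index_date = as.Date(index_date),
    observed_days = observed_days, gap_days = gap_days,
    cmg = cmg, calculable = TRUE,
    non_calculable_reason = "none",
    adherence_class = adherence)
  trace <- dplyr::bind_rows(lapply(per_ing, `[[`, "intervals"))
  trace$patient_id <- patient_id
  trace$indication <- indication
  attr(res, "intervals") <- trace
  res
}

#' Continuous medication gap for a cohort
#'
#' Vectorizes [compute_indication_cmg()] over an anchor table of
#' patient-indication assessment dates, using cohort-filtered claims and
#' the eligibility table. One result row is produced per anchor row,
#' including respondents with no claims at all (non-calculable,
#' `fewer_than_two_fills`).
#'
#' @param claims Cohort claims tibble (typically after [filter_cohort()];
#'   insulin fills, if still present, are ignored per anchor indication).
#' @param anchors Tibble with `patient_id`, `indication`, `index_date` --
#'   one row per CMG to compute.
#' @param eligibility Eligibility tibble covering all anchor patients.
#' @inheritParams compute_indication_cmg
#' @return Tibble of CMG results, one row per anchor, with attribute
#'   `intervals` binding all audit traces.
#' @export
compute_cohort_cmg <- function(claims, anchors, eligibility,
                               window_days = 365L, threshold = 0.20,
                               aggregation = "pooled_days") {
  rows <- vector("list", nrow(anchors))
  traces <- vector("list", nrow(anchors))
  for (i in seq_len(nrow(anchors))) {
    pid <- anchors$patient_id[i]
    ind <- anchors$indication[i]
    el <- eligibility[eligibility$patient_id == pid, , drop = FALSE]
    if (nrow(el) == 0L) {
      abort(sprintf("patient '%s' missing from eligibility", pid))
    }
    fills <- claims[claims$patient_id == pid & claims$indication == ind, ,
                    drop = FALSE]
    res <- compute_indication_cmg(
      fills, index_date = anchors$index_date[i],
      window_days = window_days, patient_id = pid, indication = ind,
      dual_coverage = el$dual_coverage[1],
      continuous_benefits = el$continuous_benefits[1],
      threshold = threshold, aggregation = aggregation)
    traces[[i]] <- attr(res, "intervals")
    rows[[i]] <- res
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "intervals") <- dplyr::bind_rows(traces)
  out
}

empty_interval_trace <- function() {
  tibble::tibble(
    start_date = as.Date(character()), end_date = as.Date(character()),
    length_days = integer(), supply_available = integer(),
    gap_days = integer(), carryover_out = integer(),
    ingredient = character(), patient_id = character(),
    indication = character())
}
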