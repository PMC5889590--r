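#' Parameters for a synthetic claims cohort
#'
#' Describes the behavioral model the generator simulates. Each patient
#' and indication gets a latent daily pill-taking propensity
#' `p ~ Beta(adherence_alpha, adherence_beta)`. Refills are driven by
#' supply exhaustion plus a non-adherence delay: consecutive fills are
#' `days_supply + delay` days apart with `delay ~ Geometric` with mean
#' `days_supply * (1 - p) / p`, so the expected uncovered fraction of a
#' refill interval is `1 - p` and the taking propensity is recoverable
#' from claims alone. Seven-day recall responses are
#' `Binomial(7, 1 - p)` true missed days, thinned per missed day by
#' `disclosure_prob` (1 = fully honest; lower values reproduce the
#' under-disclosure bias of self-report). Designated fractions of
#' patients are made non-calculable on purpose: exactly one fill, or
#' dual pharmacy coverage.
#'
#' @param n_patients Number of patients (default 500).
#' @param adherence_alpha,adherence_beta Beta shape parameters of the
#'   taking propensity (default 8 and 2: mean propensity 0.8, i.e. an
#'   expected gap fraction of 0.2 straddling the optimal-adherence cut).
#'   `adherence_beta = 0` is the degenerate perfect-adherence limit
#'   (propensity identically 1, every refill on time, all gaps zero).
#' @param days_supply Days supply per fill (default 30, the standard
#'   one-month fill).
#' @param window_days CMG lookback length (default 365).
#' @param disclosure_prob Probability each truly missed day is disclosed
#'   in a 7-day recall (default 1).
#' @param frac_single_fill Fraction of patients given exactly one fill
#'   per indication (non-calculable: `fewer_than_two_fills`); default 0.05.
#' @param frac_dual_coverage Fraction flagged with dual coverage
#'   (non-calculable); default 0.05.
#' @param indications Indication classes to simulate.
#' @param interview_offset_days Maximum days after the automated-query
#'   response at which the interview response occurs (default 7).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A `cmgap_cohort_params` list.
#' @export
cohort_params <- function(n_patients = 500L,
                          adherence_alpha = 8, adherence_beta = 2,
                          days_supply = 30L, window_days = 365L,
                          disclosure_prob = 1,
                          frac_single_fill = 0.05,
                          frac_dual_coverage = 0.05,
                          indications = ANALYZABLE_INDICATIONS,
                          interview_offset_days = 7L,
                          seed = 1L) {
  stopifnot(n_patients >= 1L, adherence_alpha > 0, adherence_beta >= 0,
            days_supply >= 1L, window_days >= 1L,
            disclosure_prob >= 0, disclosure_prob <= 1,
            frac_single_fill >= 0, frac_single_fill <= 1,
            frac_dual_coverage >= 0, frac_dual_coverage <= 1,
            all(indications %in% ANALYZABLE_INDICATIONS),
            interview_offset_days >= 0L)
  # the generator keeps every fill within window_days minus a reserve so
  # that both assessment anchors' lookbacks cover the full fill history
  if (window_days - 35L < days_supply) {
    abort("window_days too short to complete a refill interval at this days_supply")
  }
  structure(
    list(n_patients = as.integer(n_patients),
         adherence_alpha = adherence_alpha,
         adherence_beta = adherence_beta,
         days_supply = as.integer(days_supply),
         window_days = as.integer(window_days),
         disclosure_prob = disclosure_prob,
         frac_single_fill = frac_single_fill,
         frac_dual_coverage = frac_dual_coverage,
         indications = indications,
         interview_offset_days = as.integer(interview_offset_days),
         seed = as.integer(seed)),
    class = "cmgap_cohort_params")
}

# one representative ingredient label per simulated class
SYNTHETIC_INGREDIENTS <- c(diabetes_oral = "metformin",
                           blood_pressure = "lisinopril",
                           cholesterol = "simvastatin")

#' Generate a synthetic claims cohort with known ground truth
#'
#' Simulates the dispensing, eligibility, and self-report tables the
#' analysis pipeline consumes, together with a truth table recording each
#' patient-indication taking propensity `p_true` and the realized
#' uncovered-day fraction `true_gap_fraction` between first and last
#' fill. Because every generated fill lies inside both assessment
#' anchors' lookback windows and supply is constant per fill, the
#' pipeline's CMG equals `true_gap_fraction` exactly for calculable
#' patients: both are the same realized gaps, measured two ways.
#'
#' @param params A [cohort_params()] object.
#' @return A list of tibbles: `claims`, `eligibility`, `selfreports`,
#'   `truth`, plus the `params` echoed back.
#' @seealso [write_cohort()] to emit the CSV dialects read by
#'   [read_dispensings()] and friends.
#' @export
generate_cohort <- function(params) {
  stopifnot(inherits(params, "cmgap_cohort_params"))
  set.seed(params$seed)
  n <- params$n_patients
  ds <- params$days_supply
  horizon <- params$window_days - 35L
  ids <- sprintf("P%04d", seq_len(n))
  epoch <- as.Date("2010-01-01")

  n_single <- floor(params$frac_single_fill * n)
  n_dual <- floor(params$frac_dual_coverage * n)
  special <- sample(ids, n_single + n_dual)
  single_ids <- head(special, n_single)
  dual_ids <- tail(special, n_dual)

  claims <- list()
  reports <- list()
  truth <- list()
  for (pid in ids) {
    start0 <- epoch + sample.int(60L, 1L)
    for (ind in params$indications) {
      # shape2 = 0 is the degenerate perfect-adherence limit (p identically 1)
      p <- if (params$adherence_beta == 0) 1 else
        rbeta(1, params$adherence_alpha, params$adherence_beta)
      delay_mean <- ds * (1 - p) / p
      dates <- start0
      delays <- integer(0)
      if (!pid %in% single_ids) {
        repeat {
          delay <- rgeom(1, prob = 1 / (1 + delay_mean))
          nxt <- dates[length(dates)] + ds + delay
          if (as.integer(nxt - dates[1]) > horizon) break
          dates <- c(dates, nxt)
          delays <- c(delays, delay)
        }
      }
      claims[[length(claims) + 1L]] <- tibble::tibble(
        patient_id = pid, fill_date = dates,
        ingredient = SYNTHETIC_INGREDIENTS[[ind]], indication = ind,
        days_supply = ds)
      observed <- as.integer(dates[length(dates)] - dates[1])
      truth[[length(truth) + 1L]] <- tibble::tibble(
        patient_id = pid, indication = ind, p_true = p,
        n_fills = length(dates),
        true_gap_fraction = if (length(dates) >= 2L)
          sum(delays) / observed else NA_real_)

      index_date <- dates[length(dates)]
      atsm_date <- index_date
      interview_date <- index_date +
        (if (params$interview_offset_days > 0L)
          sample.int(params$interview_offset_days, 1L) else 0L)
      for (src in SOURCE_LEVELS) {
        missed_true <- rbinom(1, 7, 1 - p)
        disclosed <- rbinom(1, missed_true, params$disclosure_prob)
        reports[[length(reports) + 1L]] <- tibble::tibble(
          patient_id = pid, source = src, indication = ind,
          response_date = if (src == "atsm") atsm_date else interview_date,
          missed_days = disclosed)
      }
    }
  }

  list(
    claims = dplyr::bind_rows(claims),
    eligibility = tibble::tibble(
      patient_id = ids,
      continuous_benefits = TRUE,
      dual_coverage = ids %in% dual_ids),
    selfreports = dplyr::bind_rows(reports),
    truth = dplyr::bind_rows(truth),
    params = params)
}

#' Write a synthetic cohort to CSV files
#'
#' Emits `claims.csv`, `eligibility.csv`, `selfreports.csv`, and
#' `truth.csv` in exactly the dialects the readers consume, so a
#' generated cohort round-trips through the file interface.
#'
#' @param cohort A list from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    claims = file.path(dir, "claims.csv"),
    eligibility = file.path(dir, "eligibility.csv"),
    selfreports = file.path(dir, "selfreports.csv"),
    truth = file.path(dir, "truth.csv"))
  readr::write_csv(cohort$claims, paths[["claims"]], progress = FALSE)
  readr::write_csv(cohort$eligibility, paths[["eligibility"]], progress = FALSE)
  readr::write_csv(cohort$selfreports, paths[["selfreports"]], progress = FALSE)
  readr::write_csv(cohort$truth, paths[["truth"]], progress = FALSE)
  invisible(paths)
}

#' Compare pipeline CMG against the generator's ground truth
#'
#' Joins CMG results to the synthetic truth table and summarizes, per
#' indication, the bias and root-mean-square error of CMG against (a) the
#' realized uncovered-day fraction (`true_gap_fraction`; identical by
#' construction, so RMSE 0 certifies the gap accounting end to end) and
#' (b) the structural non-adherence level `1 - p_true` (approached only
#' in expectation, with bias shrinking as refill count grows).
#'
#' @param truth Truth tibble from [generate_cohort()].
#' @param cmg_results Calculable CMG rows from [compute_cohort_cmg()].
#' @return Tibble per indication: `n`, `bias_vs_truth`, `rmse_vs_truth`,
#'   `bias_vs_propensity`, `rmse_vs_propensity`.
#' @export
recovery_report <- function(truth, cmg_results) {
  joined <- dplyr::inner_join(
    truth, cmg_results[cmg_results$calculable, , drop = FALSE],
    by = c("patient_id", "indication"))
  joined <- joined[!is.na(joined$true_gap_fraction), , drop = FALSE]
  if (nrow(joined) == 0L) {
    abort("no calculable CMG rows join to the truth table")
  }
  joined |>
    dplyr::group_by(.data$indication) |>
    dplyr::summarise(
      n = dplyr::n(),
      bias_vs_truth = mean(.data$cmg - .data$true_gap_fraction),
      rmse_vs_truth = sqrt(mean((.data$cmg - .data$true_gap_fraction)^2)),
      bias_vs_propensity = mean(.data$cmg - (1 - .data$p_true)),
      rmse_vs_propensity = sqrt(mean((.data$cmg - (1 - .data$p_true))^2)),
      .groups = "drop")
}
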