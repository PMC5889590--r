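#' Configure an end-to-end adherence analysis run
#'
#' Bundles every tunable of the pipeline. Inputs are either the three
#' file paths (`claims`, `eligibility`, `selfreports` -- CSVs in the
#' dialects of [read_dispensings()] and friends), already-read tibbles,
#' or a [cohort_params()] object under `synthetic`, in which case the
#' cohort is generated in-run and the truth table carried through.
#'
#' @param claims,eligibility,selfreports Paths or tibbles (ignored when
#'   `synthetic` is given).
#' @param synthetic Optional [cohort_params()].
#' @param window_days CMG lookback length in days (default 365).
#' @param cmg_threshold Optimal-adherence cut on the gap fraction
#'   (default 0.20); must lie in `[0, 1)`.
#' @param selection_mode Which completed response to analyze per patient,
#'   indication, and source: `"first"` (primary) or `"last"`
#'   (sensitivity).
#' @param pairing_window_days Maximum days between automated-query and
#'   interview responses for concordance pairing (default 30).
#' @param aggregation_mode Multi-ingredient aggregation within an
#'   indication (see [compute_indication_cmg()]).
#' @param output_dir Optional directory for the report bundle; when
#'   `NULL` nothing is written and results are only returned.
#' @param strict Passed to the readers.
#' @return A `cmgap_pipeline_config` list.
#' @export
pipeline_config <- function(claims = NULL, eligibility = NULL,
                            selfreports = NULL, synthetic = NULL,
                            window_days = 365L, cmg_threshold = 0.20,
                            selection_mode = c("first", "last"),
                            pairing_window_days = 30L,
                            aggregation_mode = c("pooled_days",
                                                 "mean_per_ingredient"),
                            output_dir = NULL, strict = FALSE) {
  selection_mode <- match.arg(selection_mode)
  aggregation_mode <- match.arg(aggregation_mode)
  stopifnot(window_days >= 1L, cmg_threshold >= 0, cmg_threshold < 1,
            pairing_window_days >= 0L)
  if (is.null(synthetic) &&
      (is.null(claims) || is.null(eligibility) || is.null(selfreports))) {
    abort("provide claims, eligibility and selfreports, or synthetic params")
  }
  structure(
    list(claims = claims, eligibility = eligibility,
         selfreports = selfreports, synthetic = synthetic,
         window_days = as.integer(window_days),
         cmg_threshold = cmg_threshold,
         selection_mode = selection_mode,
         pairing_window_days = as.integer(pairing_window_days),
         aggregation_mode = aggregation_mode,
         output_dir = output_dir, strict = strict),
    class = "cmgap_pipeline_config")
}

#' Run the adherence measurement and validity pipeline
#'
#' Executes the full analysis: input (or synthetic generation) ->
#' cohort filtering -> response selection -> CMG per patient, indication,
#' and source (the 12-month lookback is anchored at each source's
#' selected response date, so automated-query and interview analyses use
#' their own index dates) -> adherence summary -> validity contingency
#' tables with exact tests -> cross-mode concordance -> run manifest.
#' All randomness lives in the synthetic generator; given the same
#' config (and generator seed) the report bundle is reproduced
#' identically.
#'
#' @param config A [pipeline_config()].
#' @return A `cmgap_report` list: `cmg_results`, `selections`,
#'   `adherence_summary`, `validity_tables` (list of
#'   `cmgap_validity_table`), `validity_summary` (flat tibble), `pairs`,
#'   `concordance`, `recovery` (synthetic runs only), and `manifest`.
#'   Written to `output_dir` as CSVs plus `manifest.json` and
#'   `report.txt` when configured.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cmgap_pipeline_config"))
  truth <- NULL
  if (!is.null(config$synthetic)) {
    cohort <- generate_cohort(config$synthetic)
    claims_raw <- cohort$claims
    eligibility <- cohort$eligibility
    selfreports <- cohort$selfreports
    truth <- cohort$truth
  } else {
    claims_raw <- read_table_arg(config$claims, read_dispensings,
                                 config$strict)
    eligibility <- read_table_arg(config$eligibility, read_eligibility,
                                  config$strict)
    selfreports <- read_table_arg(config$selfreports, read_selfreports,
                                  config$strict)
  }

  claims <- filter_cohort(claims_raw, eligibility)
  selections <- select_responses(selfreports, mode = config$selection_mode)

  anchors <- selections |>
    dplyr::transmute(.data$patient_id, .data$indication, .data$source,
                     index_date = .data$response_date)
  cmg_results <- list()
  for (src in SOURCE_LEVELS) {
    anc <- anchors[anchors$source == src,
                   c("patient_id", "indication", "index_date")]
    if (nrow(anc) == 0L) next
    res <- compute_cohort_cmg(
      claims, anc, eligibility,
      window_days = config$window_days, threshold = config$cmg_threshold,
      aggregation = config$aggregation_mode)
    trace <- attr(res, "intervals")
    res$source <- src
    if (nrow(trace) > 0L) trace$source <- src
    attr(res, "intervals") <- trace
    cmg_results[[src]] <- res
  }
  traces <- dplyr::bind_rows(lapply(cmg_results, attr, "intervals"))
  cmg_results <- dplyr::bind_rows(cmg_results)

  calc <- cmg_results[cmg_results$calculable, , drop = FALSE]
  adherence_summary <- calc |>
    dplyr::group_by(.data$source, .data$indication) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_cmg = mean(.data$cmg),
      sd_cmg = stats::sd(.data$cmg),
      pct_optimal = round(100 * mean(.data$adherence_class == "optimal"), 1),
      .groups = "drop")

  indications <- sort(unique(selections$indication))
  validity_tables <- list()
  for (src in unique(selections$source)) {
    for (ind in indications) {
      vt <- add_exact_test(
        build_contingency(cmg_results, selections, ind, src))
      validity_tables[[paste(src, ind, sep = ".")]] <- vt
    }
  }
  validity_summary <- dplyr::bind_rows(lapply(validity_tables, flatten_vt))

  pairs <- pair_for_concordance(
    selections[selections$source == "atsm", , drop = FALSE],
    selections[selections$source == "interview", , drop = FALSE],
    window_days = config$pairing_window_days)
  concordance <- dplyr::bind_rows(
    lapply(indications, function(ind) concordance_summary(pairs, ind)))

  recovery <- NULL
  if (!is.null(truth)) {
    atsm_cmg <- cmg_results[cmg_results$source == "atsm", , drop = FALSE]
    recovery <- recovery_report(truth, atsm_cmg)
  }

  manifest <- build_manifest(config, claims_raw, claims, eligibility,
                             selfreports, selections, cmg_results, pairs)

  report <- structure(
    list(cmg_results = cmg_results, interval_trace = traces,
         selections = selections, adherence_summary = adherence_summary,
         validity_tables = validity_tables,
         validity_summary = validity_summary,
         pairs = pairs, concordance = concordance,
         recovery = recovery, truth = truth, manifest = manifest),
    class = "cmgap_report")
  if (!is.null(config$output_dir)) {
    write_report_bundle(report, config$output_dir)
  }
  report
}

read_table_arg <- function(x, reader, strict) {
  if (is.character(x) && length(x) == 1L) reader(x, strict = strict) else x
}

flatten_vt <- function(vt) {
  tibble::tibble(
    source = vt$source, indication = vt$indication,
    category = rownames(vt$counts),
    optimal = vt$counts[, "optimal"],
    suboptimal = vt$counts[, "suboptimal"],
    non_calculable = as.integer(vt$n_non_calculable),
    p_value = vt$p_value)
}

build_manifest <- function(config, claims_raw, claims, eligibility,
                           selfreports, selections, cmg_results, pairs) {
  all_patients <- sort(unique(c(claims_raw$patient_id,
                                eligibility$patient_id,
                                selfreports$patient_id)))
  el <- eligibility[match(all_patients, eligibility$patient_id), ]
  status <- ifelse(
    is.na(el$patient_id), "missing_eligibility",
    ifelse(el$dual_coverage, "excluded_dual_coverage",
           ifelse(!el$continuous_benefits, "excluded_no_continuous_benefits",
                  "analyzed")))
  accounting <- tibble::tibble(patient_id = all_patients, status = status)
  list(
    config = list(
      window_days = config$window_days,
      cmg_threshold = config$cmg_threshold,
      selection_mode = config$selection_mode,
      pairing_window_days = config$pairing_window_days,
      aggregation_mode = config$aggregation_mode,
      synthetic_seed = if (!is.null(config$synthetic))
        config$synthetic$seed else NA_integer_),
    input_rows = c(claims = nrow(claims_raw),
                   eligibility = nrow(eligibility),
                   selfreports = nrow(selfreports)),
    removal_tally = as.list(removal_tally(claims)),
    n_selected_responses = nrow(selections),
    n_cmg_rows = nrow(cmg_results),
    n_calculable = sum(cmg_results$calculable),
    non_calculable_reasons = as.list(table(
      cmg_results$non_calculable_reason[!cmg_results$calculable])),
    n_pairs = nrow(pairs),
    unpaired = as.list(attr(pairs, "unpaired")),
    patient_accounting = accounting)
}

write_report_bundle <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(x, name) readr::write_csv(x, file.path(dir, name),
                                           progress = FALSE)
  wr(report$cmg_results, "cmg_results.csv")
  wr(report$interval_trace, "interval_trace.csv")
  wr(report$selections, "selections.csv")
  wr(report$adherence_summary, "adherence_summary.csv")
  wr(report$validity_summary, "validity_tables.csv")
  wr(report$pairs, "pairs.csv")
  wr(report$concordance, "concordance.csv")
  if (!is.null(report$recovery)) wr(report$recovery, "recovery.csv")
  jsonlite::write_json(report$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(format_report_text(report), file.path(dir, "report.txt"))
  invisible(dir)
}

format_report_text <- function(report) {
  out <- c("Adherence measurement and self-report validity report", "")
  out <- c(out, "== Mean CMG and optimal adherence by source x indication ==")
  s <- report$adherence_summary
  for (i in seq_len(nrow(s))) {
    out <- c(out, sprintf(
      "  %-9s %-14s n=%-4d mean CMG %.3f (SD %.3f)  optimal %.1f%%",
      s$source[i], s$indication[i], s$n[i], s$mean_cmg[i], s$sd_cmg[i],
      s$pct_optimal[i]))
  }
  out <- c(out, "", "== Missed-day category vs CMG adherence (exact test) ==")
  v <- report$validity_summary
  for (key in unique(paste(v$source, v$indication))) {
    sub <- v[paste(v$source, v$indication) == key, ]
    out <- c(out, sprintf("  %s  (p = %s)", key,
                          format(sub$p_value[1], digits = 3)))
    for (i in seq_len(nrow(sub))) {
      out <- c(out, sprintf(
        "    %-12s optimal %3d  suboptimal %3d  non-calculable %3d",
        sub$category[i], sub$optimal[i], sub$suboptimal[i],
        sub$non_calculable[i]))
    }
  }
  out <- c(out, "", "== Cross-mode concordance of missed-day reports ==")
  cc <- report$concordance
  for (i in seq_len(nrow(cc))) {
    out <- c(out, sprintf(
      "  %-14s n=%-4d concordant %.1f%%  higher interview %.1f%%  higher ATSM %.1f%%",
      cc$indication[i], cc$n_pairs[i], cc$pct_concordant[i],
      cc$pct_higher_interview[i], cc$pct_higher_atsm[i]))
  }
  out
}

#' @export
print.cmgap_report <- function(x, ...) {
  cat(format_report_text(x), sep = "\n")
  invisible(x)
}
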