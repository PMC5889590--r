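#' Exact test of homogeneity for an r x c contingency table
#'
#' Two-sided Fisher-Freeman-Halton exact test. Conditional on the
#' observed row and column margins, table probabilities follow the
#' multivariate hypergeometric distribution
#' \deqn{P(T) = \frac{\prod_i r_i!\; \prod_j c_j!}{n!\; \prod_{ij} n_{ij}!}}
#' and the two-sided p-value is the total probability of all tables with
#' those margins whose probability does not exceed the observed table's
#' (probability ordering, with a 1e-12 relative tolerance on the
#' comparison so floating-point ties are included). Tables are enumerated
#' exactly, row by row, over all compositions compatible with the
#' remaining margins. Rows and columns summing to zero are dropped first;
#' a table reduced to a single row or column carries no evidence against
#' homogeneity and returns p = 1.
#'
#' @param counts Matrix (or object coercible to one) of non-negative
#'   integer counts; for the adherence analysis, rows are missed-day
#'   categories and columns optimal/suboptimal adherence.
#' @return The two-sided exact p-value in `[0, 1]`.
#' @examples
#' fisher_exact_rxc(matrix(c(3, 1, 1, 3), 2, 2, byrow = TRUE)) # 34/70
#' @export
fisher_exact_rxc <- function(counts) {
  m <- as.matrix(counts)
  if (any(is.na(m)) || any(m < 0) || any(m != round(m))) {
    abort("counts must be non-negative integers")
  }
  if (sum(m) == 0) {
    abort("table has no observations")
  }
  m <- m[rowSums(m) > 0, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2L || ncol(m) < 2L) {
    return(1)
  }
  rs <- rowSums(m)
  cs <- colSums(m)
  n <- sum(m)
  log_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  logp_obs <- log_const - sum(lgamma(m + 1))
  cutoff <- logp_obs + log1p(1e-12)

  total <- 0
  # depth-first over rows; each level distributes one row sum across the
  # columns within the remaining column margins
  recurse <- function(row, col_rem, log_acc) {
    if (row == length(rs)) {
      # last row forced by the remaining column margins
      logp <- log_const + log_acc - sum(lgamma(col_rem + 1))
      if (logp <= cutoff) total <<- total + exp(logp)
      return(invisible())
    }
    for (comp in row_compositions(rs[row], col_rem)) {
      recurse(row + 1L, col_rem - comp, log_acc - sum(lgamma(comp + 1)))
    }
    invisible()
  }
  recurse(1L, cs, 0)
  min(1, total)
}

# all ways to split `total` across cells bounded above by `caps`
row_compositions <- function(total, caps) {
  out <- list()
  cells <- length(caps)
  comp <- integer(cells)
  gen <- function(j, remaining) {
    if (j == cells) {
      if (remaining <= caps[j]) {
        comp[j] <<- remaining
        out[[length(out) + 1L]] <<- comp
      }
      return(invisible())
    }
    # lower bound: later cells can absorb at most sum(caps[(j+1):cells])
    slack <- sum(caps[(j + 1L):cells])
    lo <- max(0L, remaining - slack)
    hi <- min(caps[j], remaining)
    if (lo > hi) return(invisible())
    for (v in lo:hi) {
      comp[j] <<- v
      gen(j + 1L, remaining - v)
    }
    invisible()
  }
  gen(1L, total)
  out
}

#' Build a missed-day by adherence contingency table
#'
#' Cross-tabulates self-report categories (`zero`, `one`, `two_to_seven`
#' missed days) against claims-based adherence class (optimal vs
#' suboptimal CMG) for one indication and source. Respondents without a
#' calculable CMG -- including respondents with no CMG record at all --
#' are excluded from the counts and tallied per category instead, since
#' the exact test compares only optimal against suboptimal adherence.
#'
#' @param cmg_results CMG result tibble from [compute_cohort_cmg()]
#'   (any sources/indications; filtered here).
#' @param selections Categorizable selections from [select_responses()].
#' @param indication,source The stratum to tabulate.
#' @return An object of class `cmgap_validity_table`: a list with
#'   `indication`, `source`, `counts` (3 x 2 integer matrix),
#'   `n_non_calculable` (per-category tally), and `p_value` (`NA` until
#'   [add_exact_test()] is applied).
#' @export
build_contingency <- function(cmg_results, selections, indication, source) {
  sel <- selections[selections$indication == indication &
                      selections$source == source, , drop = FALSE]
  counts <- matrix(0L, nrow = 3L, ncol = 2L,
                   dimnames = list(MISSED_CATEGORY_LEVELS,
                                   c("optimal", "suboptimal")))
  non_calc <- setNames(integer(3L), MISSED_CATEGORY_LEVELS)
  cmg_ind <- cmg_results[cmg_results$indication == indication, , drop = FALSE]
  if ("source" %in% names(cmg_ind)) {
    cmg_ind <- cmg_ind[cmg_ind$source == source, , drop = FALSE]
  }
  for (i in seq_len(nrow(sel))) {
    cat <- as.character(categorize_missed_days(sel$missed_days[i]))
    hit <- cmg_ind[cmg_ind$patient_id == sel$patient_id[i], , drop = FALSE]
    if (nrow(hit) >= 1L && isTRUE(hit$calculable[1])) {
      counts[cat, hit$adherence_class[1]] <-
        counts[cat, hit$adherence_class[1]] + 1L
    } else {
      non_calc[cat] <- non_calc[cat] + 1L
    }
  }
  structure(
    list(indication = indication, source = source, counts = counts,
         n_non_calculable = non_calc, p_value = NA_real_),
    class = "cmgap_validity_table")
}

#' Attach the exact-test p-value to a validity table
#'
#' @param table A `cmgap_validity_table` from [build_contingency()].
#' @return The table with `p_value` filled in ([fisher_exact_rxc()] on
#'   the counts), or left `NA` when the counts are all zero.
#' @export
add_exact_test <- function(table) {
  stopifnot(inherits(table, "cmgap_validity_table"))
  if (sum(table$counts) > 0L) {
    table$p_value <- fisher_exact_rxc(table$counts)
  }
  table
}

#' @export
print.cmgap_validity_table <- function(x, ...) {
  cat(sprintf("Convergent validity: %s (%s)\n", x$indication, x$source))
  print(x$counts)
  cat("non-calculable CMG by category:",
      paste(sprintf("%s=%d", names(x$n_non_calculable), x$n_non_calculable),
            collapse = ", "), "\n")
  cat(sprintf("exact test (optimal vs suboptimal): p = %s\n",
              ifelse(is.na(x$p_value), "NA", format(x$p_value, digits = 4))))
  invisible(x)
}

#' Summarize cross-mode concordance of missed-day reports
#'
#' Classifies each automated-query/interview pair by comparing raw
#' missed-day counts: concordant (equal), higher disclosure on interview,
#' or higher disclosure on the automated query. The three classes
#' partition the pairs; percentages are reported to one decimal and sum
#' to 100 up to rounding.
#'
#' @param pairs Pair tibble from [pair_for_concordance()].
#' @param indication Optional: restrict to one indication.
#' @return One-row tibble: `indication`, `n_pairs`, `pct_concordant`,
#'   `pct_higher_interview`, `pct_higher_atsm` (percentages `NA` when
#'   there are no pairs).
#' @export
concordance_summary <- function(pairs, indication = NULL) {
  if (!is.null(indication)) {
    pairs <- pairs[pairs$indication == indication, , drop = FALSE]
  }
  label <- indication %||%
    (if (nrow(pairs) > 0L) paste(unique(pairs$indication), collapse = "+")
     else NA_character_)
  n <- nrow(pairs)
  if (n == 0L) {
    return(tibble::tibble(
      indication = label, n_pairs = 0L, pct_concordant = NA_real_,
      pct_higher_interview = NA_real_, pct_higher_atsm = NA_real_))
  }
  conc <- sum(pairs$atsm_missed == pairs$interview_missed)
  hi_int <- sum(pairs$interview_missed > pairs$atsm_missed)
  hi_atsm <- sum(pairs$atsm_missed > pairs$interview_missed)
  tibble::tibble(
    indication = label, n_pairs = n,
    pct_concordant = round(100 * conc / n, 1),
    pct_higher_interview = round(100 * hi_int / n, 1),
    pct_higher_atsm = round(100 * hi_atsm / n, 1))
}
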