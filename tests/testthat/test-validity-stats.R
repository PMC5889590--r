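test_that("exact test handles the canonical worked tables", {
  expect_equal(fisher_exact_rxc(matrix(5, 3, 2)), 1)
  expect_equal(fisher_exact_rxc(matrix(c(3, 1, 1, 3), 2, byrow = TRUE)),
               34 / 70, tolerance = 1e-12)
  # degenerate shapes carry no evidence
  expect_equal(fisher_exact_rxc(matrix(c(4, 9), 1, 2)), 1)
  expect_equal(fisher_exact_rxc(matrix(c(4, 9), 2, 1)), 1)
  # zero rows/columns are dropped before testing
  with_zero <- matrix(c(3, 1, 0, 0, 1, 3), 3, 2, byrow = TRUE)
  expect_equal(fisher_exact_rxc(with_zero), 34 / 70, tolerance = 1e-12)
  expect_error(fisher_exact_rxc(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("2x2 p-values equal the classical conditional hypergeometric test", {
  set.seed(404)
  for (i in 1:40) {
    m <- random_table(r = 2, n_max = 40)
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) next
    expect_equal(fisher_exact_rxc(m), stats::fisher.test(m)$p.value,
                 tolerance = 1e-9)
  }
})

test_that("3x2 p-values match brute-force fixed-margin enumeration", {
  set.seed(505)
  for (i in 1:25) {
    m <- random_table(r = 3, n_max = 20)
    expect_equal(fisher_exact_rxc(m), brute_force_fisher(m),
                 tolerance = 1e-10)
  }
})

test_that("p-values are invariant to row permutation and column swap", {
  set.seed(606)
  for (i in 1:15) {
    m <- random_table(r = 3, n_max = 25)
    p <- fisher_exact_rxc(m)
    expect_equal(fisher_exact_rxc(m[sample(3), ]), p, tolerance = 1e-10)
    expect_equal(fisher_exact_rxc(m[, 2:1]), p, tolerance = 1e-10)
  }
})

make_cmg_row <- function(patient, class = "optimal", calculable = TRUE,
                         indication = "diabetes_oral") {
  tibble::tibble(
    patient_id = patient, indication = indication,
    index_date = DAY0, observed_days = 100L,
    gap_days = if (class == "optimal") 10L else 40L,
    cmg = if (class == "optimal") 0.1 else 0.4,
    calculable = calculable,
    non_calculable_reason = if (calculable) "none" else
      "fewer_than_two_fills",
    adherence_class = if (calculable) class else "not_applicable")
}

test_that("contingency counts and non-calculable tallies follow the hand tally", {
  sel <- dplyr::bind_rows(
    make_response("A", missed = 0), make_response("B", missed = 0),
    make_response("C", missed = 1), make_response("D", missed = 4),
    make_response("E", missed = 1))
  cmg <- dplyr::bind_rows(
    make_cmg_row("A", "optimal"), make_cmg_row("B", "suboptimal"),
    make_cmg_row("C", "optimal"), make_cmg_row("D", "suboptimal"),
    make_cmg_row("E", calculable = FALSE))
  vt <- build_contingency(cmg, sel, "diabetes_oral", "atsm")
  expect_equal(unname(vt$counts),
               matrix(c(1L, 1L, 1L, 0L, 0L, 1L), 3, 2, byrow = TRUE))
  expect_equal(vt$n_non_calculable,
               c(zero = 0L, one = 1L, two_to_seven = 0L))

  # a respondent with no CMG record at all counts as non-calculable
  orphan <- build_contingency(cmg[cmg$patient_id != "E", ], sel,
                              "diabetes_oral", "atsm")
  expect_equal(orphan$n_non_calculable[["one"]], 1L)

  both_opt <- build_contingency(
    dplyr::bind_rows(make_cmg_row("A"), make_cmg_row("B")),
    dplyr::bind_rows(make_response("A", missed = 0),
                     make_response("B", missed = 0)),
    "diabetes_oral", "atsm")
  expect_equal(unname(both_opt$counts[1, ]), c(2L, 0L))
  expect_equal(sum(both_opt$counts[-1, ]), 0L)

  empty <- build_contingency(cmg[0, ], sel[0, ], "diabetes_oral", "atsm")
  expect_true(all(empty$counts == 0L))
  expect_true(is.na(add_exact_test(empty)$p_value))
})

test_that("concordance summaries classify pairs and always sum to 100", {
  mk_pairs <- function(a, b) tibble::tibble(
    patient_id = sprintf("P%d", seq_along(a)), indication = "cholesterol",
    atsm_missed = a, interview_missed = b,
    atsm_date = DAY0, interview_date = DAY0 + 3)
  perfect <- concordance_summary(mk_pairs(c(0, 3), c(0, 3)))
  expect_equal(perfect$pct_concordant, 100)
  expect_equal(perfect$n_pairs, 2L)

  mixed <- concordance_summary(mk_pairs(c(0, 2, 1), c(0, 1, 3)))
  expect_equal(mixed$pct_concordant, 33.3)
  expect_equal(mixed$pct_higher_atsm, 33.3)
  expect_equal(mixed$pct_higher_interview, 33.3)

  set.seed(707)
  for (i in 1:20) {
    n <- sample(1:50, 1)
    s <- concordance_summary(mk_pairs(sample(0:7, n, TRUE),
                                      sample(0:7, n, TRUE)))
    expect_equal(s$pct_concordant + s$pct_higher_interview +
                   s$pct_higher_atsm, 100, tolerance = 0.11)
  }

  none <- concordance_summary(mk_pairs(integer(), integer()))
  expect_equal(none$n_pairs, 0L)
  expect_true(is.na(none$pct_concordant))
})
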