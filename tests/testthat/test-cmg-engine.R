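test_that("lookback windowing keeps in-window fills and merges same-day fills", {
  fills <- make_fills(c(-400, -100, -10), 30)
  got <- select_window_fills(fills, index_date = DAY0, window_days = 365)
  expect_equal(nrow(got), 2L)
  expect_equal(got$fill_date, DAY0 + c(-100, -10))

  two <- make_fills(c(50, 50), c(30, 30))
  merged <- select_window_fills(two, index_date = DAY0 + 60)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$days_supply, 60L)

  empty <- make_fills(integer(), integer())
  expect_equal(nrow(select_window_fills(empty, DAY0)), 0L)
})

test_that("time-forward gap accounting matches worked refill scenarios", {
  cases <- list(
    # perfect refill timing
    list(days = c(0, 30), supply = c(30, 30), gap = 0L, obs = 30L),
    # two 10-day late refills
    list(days = c(0, 40, 80), supply = c(30, 30, 30), gap = 20L, obs = 80L),
    # stockpile carried forward across intervals
    list(days = c(0, 30, 100), supply = c(60, 30, 10), gap = 10L, obs = 100L),
    # a later large fill must NOT negate an earlier gap
    list(days = c(0, 40, 60), supply = c(10, 60, 40), gap = 30L, obs = 60L))
  for (cs in cases) {
    got <- time_forward_gaps(make_fills(cs$days, cs$supply))
    expect_equal(got$gap_days, cs$gap)
    expect_equal(got$observed_days, cs$obs)
  }
})

test_that("the interval trace obeys the refill-interval invariants", {
  got <- time_forward_gaps(make_fills(c(0, 30, 100, 103), c(60, 30, 10, 5)))
  tr <- got$intervals
  expect_equal(tr$gap_days, pmax(0L, tr$length_days - tr$supply_available))
  expect_equal(tr$carryover_out,
               pmax(0L, tr$supply_available - tr$length_days))
  expect_true(all(tr$gap_days >= 0 & tr$gap_days <= tr$length_days))
  # carryover chains: next interval's supply = carryover_in + its fill
  # (the final fill closes the observation and opens no interval)
  expect_equal(tr$supply_available[-1] - tr$carryover_out[-nrow(tr)],
               c(30L, 10L))
  expect_equal(sum(tr$length_days), got$observed_days)
  expect_equal(sum(tr$gap_days), got$gap_days)
})

test_that("fewer than two fills is a non-calculable signal, not a number", {
  one <- make_fills(0, 30)
  expect_error(time_forward_gaps(one), class = "cmgap_fewer_than_two_fills")
  expect_error(daily_inventory_oracle(one),
               class = "cmgap_fewer_than_two_fills")
})

test_that("interval arithmetic agrees with the daily inventory oracle", {
  set.seed(101)
  for (i in 1:60) {
    fills <- random_fill_sequence()
    a <- time_forward_gaps(fills)
    b <- daily_inventory_oracle(fills)
    expect_identical(c(a$gap_days, a$observed_days),
                     c(b$gap_days, b$observed_days))
  }
})

test_that("gap accounting is translation-invariant and supply-monotone", {
  set.seed(202)
  for (i in 1:30) {
    fills <- random_fill_sequence()
    base <- time_forward_gaps(fills)
    shifted <- fills
    shifted$fill_date <- shifted$fill_date + sample(-500:500, 1)
    expect_equal(time_forward_gaps(shifted)[c("gap_days", "observed_days")],
                 base[c("gap_days", "observed_days")])
    bumped <- fills
    k <- sample(nrow(fills), 1)
    bumped$days_supply[k] <- bumped$days_supply[k] + sample(1:60, 1)
    expect_lte(time_forward_gaps(bumped)$gap_days, base$gap_days)
  }
})

test_that("adherence classification is exact at the 20% boundary", {
  expect_equal(classify_adherence(0.20), "optimal")
  expect_equal(classify_adherence(21 / 100), "suboptimal")
  expect_equal(classify_adherence(0), "optimal")
  expect_equal(classify_adherence(1), "suboptimal")
  expect_error(classify_adherence(1.2), "\\[0, 1\\]")
  expect_error(classify_adherence(-0.1), "\\[0, 1\\]")
})

test_that("indication-level CMG pools ingredients by observed days", {
  single <- make_fills(c(0, 100), c(90, 10))
  got <- compute_indication_cmg(single, index_date = DAY0 + 100)
  expect_equal(got$cmg, 0.10)
  expect_equal(got$adherence_class, "optimal")
  expect_true(got$calculable)

  # gap 10/100 on drug A and 30/60 on drug B -> pooled 40/160 = 0.25
  two <- dplyr::bind_rows(
    make_fills(c(0, 100), c(90, 10), ingredient = "metformin"),
    make_fills(c(0, 60), c(30, 30), ingredient = "glipizide"))
  pooled <- compute_indication_cmg(two, index_date = DAY0 + 100)
  expect_equal(pooled$gap_days, 40L)
  expect_equal(pooled$observed_days, 160L)
  expect_equal(pooled$cmg, 0.25)
  expect_equal(pooled$adherence_class, "suboptimal")

  unweighted <- compute_indication_cmg(two, index_date = DAY0 + 100,
                                       aggregation = "mean_per_ingredient")
  expect_equal(unweighted$cmg, mean(c(0.10, 0.50)))
})

test_that("calculability gates follow the fixed precedence", {
  fills <- make_fills(c(0, 30), 30)
  one_fill <- compute_indication_cmg(make_fills(0, 30), index_date = DAY0 + 40)
  expect_false(one_fill$calculable)
  expect_equal(one_fill$non_calculable_reason, "fewer_than_two_fills")
  expect_equal(one_fill$adherence_class, "not_applicable")

  dual <- compute_indication_cmg(fills, DAY0 + 40, dual_coverage = TRUE,
                                 continuous_benefits = FALSE)
  expect_equal(dual$non_calculable_reason, "dual_coverage")

  nocb <- compute_indication_cmg(fills, DAY0 + 40,
                                 continuous_benefits = FALSE)
  expect_equal(nocb$non_calculable_reason, "no_continuous_benefits")

  ins <- compute_indication_cmg(
    make_fills(c(0, 30), 30, indication = "insulin",
               ingredient = "insulin glargine"),
    DAY0 + 40)
  expect_equal(ins$non_calculable_reason, "insulin_excluded")

  # two single-fill ingredients: no qualifying ingredient at all
  scattered <- dplyr::bind_rows(
    make_fills(0, 30, ingredient = "metformin"),
    make_fills(10, 30, ingredient = "glipizide"))
  got <- compute_indication_cmg(scattered, DAY0 + 40)
  expect_equal(got$non_calculable_reason, "fewer_than_two_fills")
})
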