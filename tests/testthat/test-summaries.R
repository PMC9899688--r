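one_patient <- function(weeks, sbp, dbp = NA_real_, uacr = 100) {
  trial_data(dplyr::bind_rows(
    visits("P1", 1L, weeks, uacr = uacr, sbp = sbp, dbp = dbp, egfr = 70),
    visits("Q1", 0L, weeks, uacr = uacr, sbp = sbp, dbp = dbp, egfr = 70)
  ))
}

test_that("change from baseline is plain differencing, MAP derived per visit", {
  d <- one_patient(c(0L, 8L), sbp = c(140, 134))
  expect_equal(change_from_baseline(d, "sbp", 8L)$change[1], -6)

  d2 <- one_patient(c(0L, 8L), sbp = c(140, NA))
  expect_true(is.na(change_from_baseline(d2, "sbp", 8L)$change[1]))

  # MAP = DBP + (SBP - DBP)/3: 120/90 -> 100 against a baseline MAP of 110
  d3 <- one_patient(c(0L, 8L), sbp = c(140, 120), dbp = c(95, 90))
  expect_equal(change_from_baseline(d3, "map", 8L)$change[1], 100 - 110)

  no_base <- trial_data(visits("P1", 1L, c(0L, 4L), uacr = 100,
                               sbp = c(NA, 130), egfr = 70))
  expect_error(change_from_baseline(no_base, "sbp", 4L),
               class = "longmediate_precondition_error")
})

test_that("cumulative mean averages observed post-baseline changes", {
  d <- one_patient(c(0L, 4L, 8L, 12L), sbp = c(140, 138, 136, 134))
  out <- cumulative_mean_change(d, "sbp", 12L)
  expect_equal(out$value, c(-4, -4))
  expect_equal(unique(out$convention), "cumulative_mean")

  one <- one_patient(c(0L, 4L), sbp = c(140, 137))
  expect_equal(cumulative_mean_change(one, "sbp", 12L)$value[1], -3)

  holey <- one_patient(c(0L, 4L, 8L, 12L), sbp = c(140, 138, NA, 131))
  expect_equal(cumulative_mean_change(holey, "sbp", 12L)$value[1],
               mean(c(-2, -9)))

  # trapezoid switch: piecewise-linear average anchored at (0, 0)
  tw <- cumulative_mean_change(d, "sbp", 12L, time_weighted = TRUE)
  manual <- (4 * (0 - 2) / 2 + 4 * (-2 - 4) / 2 + 4 * (-4 - 6) / 2) / 12
  expect_equal(tw$value[1], manual)
})

test_that("achieved change takes the latest value strictly before the endpoint", {
  d <- one_patient(c(0L, 4L, 8L, 12L), sbp = c(140, 138, 136, 134))
  out <- achieved_change(d, "sbp", 12L)
  expect_equal(out$value[1], -4)
  expect_equal(out$week_used[1], 8L)
  expect_false(out$fallback[1])

  # endpoint-only measurement: falls back, flagged
  lone <- one_patient(c(0L, 12L), sbp = c(140, 133))
  fb <- achieved_change(lone, "sbp", 12L)
  expect_equal(fb$value[1], -7)
  expect_true(fb$fallback[1])

  # missing the week-8 value steps back to week 6
  skip6 <- one_patient(c(0L, 4L, 6L, 8L, 12L),
                       sbp = c(140, 138, 137, NA, 134))
  s6 <- achieved_change(skip6, "sbp", 12L)
  expect_equal(s6$week_used[1], 6L)
  expect_equal(s6$value[1], -3)

  # documented switch: read the endpoint-week visit itself
  at <- achieved_change(d, "sbp", 12L, at_endpoint = TRUE)
  expect_equal(at$value[1], -6)
})

test_that("summary invariants: constant trajectory, order and translation", {
  const <- one_patient(c(0L, 4L, 8L, 12L), sbp = c(140, 135, 135, 135))
  expect_equal(cumulative_mean_change(const, "sbp", 12L)$value,
               achieved_change(const, "sbp", 12L)$value)

  d <- quick_cohort(n = 30, seed = 19, missing_rate = 0.1)
  shuffled <- as_tibble(d)[sample.int(nrow(d)), ]
  expect_equal(cumulative_mean_change(d, "sbp", 52L),
               cumulative_mean_change(trial_data(shuffled), "sbp", 52L))

  shifted <- as_tibble(d) |> dplyr::mutate(sbp = sbp + 25)
  for (fn in list(cumulative_mean_change, achieved_change)) {
    expect_equal(fn(d, "sbp", 52L)$value,
                 fn(trial_data(shifted), "sbp", 52L)$value,
                 tolerance = 1e-12)
  }
})

test_that("mediator_summaries binds per-mediator rows under one convention", {
  d <- small_trial()
  out <- mediator_summaries(d, c("sbp", "egfr"), "achieved", 12L)
  expect_equal(nrow(out), 8L)
  expect_setequal(unique(out$mediator), c("sbp", "egfr"))
  expect_equal(unique(out$convention), "achieved")
})
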