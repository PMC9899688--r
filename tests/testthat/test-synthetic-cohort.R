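test_that("generator respects counts, schedule and seed reproducibility", {
  cfg <- cohort_config(n_patients = 10, missing_rate = 0, seed = 7)
  d <- generate_cohort(cfg)
  expect_equal(dplyr::n_distinct(d$patient_id), 10L)
  weeks <- sort(union(cfg$mediator_schedule, cfg$uacr_schedule))
  expect_equal(nrow(d), 10L * length(weeks))
  expect_identical(as.data.frame(d), as.data.frame(generate_cohort(cfg)))

  d2 <- generate_cohort(cohort_config(n_patients = 10, seed = 8))
  expect_false(identical(as.data.frame(d), as.data.frame(d2)))
})

test_that("null treatment path: SBP trajectories identical across arms", {
  cfg <- cohort_config(
    n_patients = 60, seed = 9, missing_rate = 0,
    alpha = c(sbp = 0, dbp = 0, egfr = 0),
    sigma_m = c(sbp = 0, dbp = 0, egfr = 0),
    covariate_slopes = list(sbp = NULL, dbp = NULL, egfr = NULL,
                            outcome = c(log_uacr0 = -0.05))
  )
  d <- generate_cohort(cfg)
  flat <- as_tibble(d) |>
    dplyr::filter(!is.na(sbp)) |>
    dplyr::group_by(patient_id) |>
    dplyr::summarise(spread = max(sbp) - min(sbp))
  expect_true(all(flat$spread == 0))
})

test_that("trajectory contract: change at and beyond the plateau equals the target", {
  cfg <- cohort_config(n_patients = 40, seed = 13, missing_rate = 0,
                       sigma_m = c(sbp = 0, dbp = 0, egfr = 0))
  d <- generate_cohort(cfg)
  base <- as_tibble(d) |> dplyr::filter(week == 0L) |>
    dplyr::select(patient_id, arm, sbp0 = sbp)
  late <- as_tibble(d) |>
    dplyr::filter(week >= 30, !is.na(sbp)) |>
    dplyr::left_join(base, by = c("patient_id", "arm")) |>
    dplyr::mutate(change = sbp - sbp0,
                  target = cfg$alpha[["sbp"]] * arm +
                    cfg$covariate_slopes$sbp[["sbp0"]] * (sbp0 - 141))
  expect_equal(late$change, late$target, tolerance = 1e-10)
})

test_that("arm-mean achieved SBP change difference recovers alpha at n = 5000", {
  cfg <- cohort_config(n_patients = 5000, seed = 17, missing_rate = 0)
  d <- generate_cohort(cfg)
  ach <- achieved_change(d, "sbp", 52L) |>
    dplyr::left_join(dplyr::distinct(as_tibble(d), patient_id, arm),
                     by = "patient_id")
  per_arm <- ach |> dplyr::group_by(arm) |>
    dplyr::summarise(m = mean(value), v = var(value), n = dplyr::n())
  diff <- per_arm$m[per_arm$arm == 1] - per_arm$m[per_arm$arm == 0]
  se <- sqrt(sum(per_arm$v / per_arm$n))
  expect_lt(abs(diff - cfg$alpha[["sbp"]]), 3 * se)
})

test_that("true_effects matches hand arithmetic and additivity invariants", {
  cfg <- cohort_config(summary = "achieved", delta = -0.8,
                       gamma = c(sbp = 0.02), tau = c(sbp = 0),
                       alpha = c(sbp = -5, dbp = 0, egfr = 0),
                       covariate_slopes = list(outcome = NULL))
  tr <- true_effects(cfg)
  expect_equal(tr$nie_log, -0.1, tolerance = 1e-12)
  expect_equal(tr$nde_log, -0.8, tolerance = 1e-12)
  expect_equal(tr$te_ratio, exp(-0.9), tolerance = 1e-12)
  expect_equal(tr$pm_pct, 100 * 0.1 / 0.9, tolerance = 1e-10)
  expect_equal(tr$te_log, tr$nde_log + tr$nie_log)
  expect_equal(tr$nde_ratio * tr$nie_ratio, tr$te_ratio, tolerance = 1e-12)
})

test_that("true_effects limits: full mediation, no mediation, zero total effect", {
  full <- true_effects(cohort_config(delta = 0))
  expect_equal(full$pm_pct, 100)
  none <- true_effects(cohort_config(alpha = c(sbp = 0, dbp = 0, egfr = 0)))
  expect_equal(none$nie_log, 0)
  expect_equal(none$pm_pct, 0)
  zero <- cohort_config(summary = "achieved", gamma = c(sbp = 0.02),
                        tau = c(sbp = 0), alpha = c(sbp = -5, dbp = 0, egfr = 0),
                        delta = 0.1)
  expect_warning(tr <- true_effects(zero), "undefined")
  expect_true(is.na(tr$pm_pct))
  expect_equal(tr$te_log, 0, tolerance = 1e-15)
})

test_that("config validation rejects impossible settings", {
  expect_error(cohort_config(missing_rate = 1),
               class = "longmediate_config_error")
  expect_error(cohort_config(allocation = 1.2),
               class = "longmediate_config_error")
  expect_error(cohort_config(sigma_y = -1),
               class = "longmediate_config_error")
  expect_error(cohort_config(nonsense = 3),
               class = "longmediate_config_error")
  expect_error(cohort_config(gamma = c(map = 0.01)),
               class = "longmediate_config_error")
})
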