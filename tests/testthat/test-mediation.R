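test_that("log-ratio outcome matches direct arithmetic", {
  d <- trial_data(dplyr::bind_rows(
    visits("P1", 1L, c(0L, 52L), uacr = c(100, 100), sbp = 140, egfr = 70),
    visits("P2", 1L, c(0L, 52L), uacr = c(100, 38.5), sbp = 140, egfr = 70),
    visits("P3", 0L, c(0L, 52L), uacr = c(200, 100), sbp = 140, egfr = 70)
  ))
  y <- outcome_log_ratio(d, 52L)
  expect_equal(y$y, c(0, log(0.385), log(0.5)), tolerance = 1e-12)
})

test_that("least-squares engine honours its rank and size contracts", {
  set.seed(1)
  X <- cbind(`(Intercept)` = 1, x1 = rnorm(100), x2 = rnorm(100),
             x3 = rnorm(100))
  beta <- c(2, -1, 0.5, 3)
  y_exact <- drop(X %*% beta)
  fit <- fit_least_squares(y_exact, X)
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-10)
  expect_equal(fit$residual_sd, 0, tolerance = 1e-10)

  y <- y_exact + rnorm(100)
  oracle <- drop(solve(t(X) %*% X, t(X) %*% y))
  expect_equal(fit_least_squares(y, X)$coefficients, oracle,
               tolerance = 1e-8)

  Xdup <- cbind(X, x1_copy = X[, "x1"])
  expect_error(fit_least_squares(y, Xdup), "x1_copy",
               class = "longmediate_estimation_error")
  expect_error(fit_least_squares(y[1:3], X[1:3, ]), "Insufficient",
               class = "longmediate_estimation_error")
})

test_that("null mediator path gives a zero indirect effect to fit precision", {
  cfg <- cohort_config(n_patients = 300, seed = 23, missing_rate = 0,
                       alpha = c(sbp = 0, dbp = 0, egfr = 0),
                       gamma = c(sbp = 0, egfr = 0), sigma_y = 0)
  fit <- estimate_mediation(generate_cohort(cfg), mediation_spec())
  expect_lt(abs(fit$estimates$nie_log), 1e-8)
  expect_equal(fit$estimates$nie_ratio, 1, tolerance = 1e-8)
  expect_lt(abs(fit$estimates$pm_pct), 1e-5)
})

test_that("with no direct path the proportion mediated approaches 100%", {
  cfg <- cohort_config(n_patients = 5000, seed = 29, missing_rate = 0,
                       delta = 0)
  fit <- estimate_mediation(generate_cohort(cfg), mediation_spec())
  expect_lt(abs(fit$estimates$pm_pct - 100), 7)
})

test_that("single-mediator estimates agree with an lm()-based oracle", {
  d <- quick_cohort(n = 300, seed = 37, tau = c(sbp = 0.01, egfr = 0.02))
  spec <- mediation_spec(mediators = "sbp")
  fit <- estimate_mediation(d, spec)
  fr <- analysis_frame(d, spec)

  om <- lm(y ~ arm * m_sbp + log_uacr0 + sbp0, data = fr)
  mm <- lm(m_sbp ~ arm + log_uacr0 + sbp0, data = fr)
  th <- coef(om); be <- coef(mm)
  m0 <- be[["(Intercept)"]] +
    be[["log_uacr0"]] * mean(fr$log_uacr0) + be[["sbp0"]] * mean(fr$sbp0)
  nde <- th[["arm"]] + th[["arm:m_sbp"]] * m0
  nie <- (th[["m_sbp"]] + th[["arm:m_sbp"]]) * be[["arm"]]
  expect_equal(fit$estimates$nde_log, nde, tolerance = 1e-10)
  expect_equal(fit$estimates$nie_log, nie, tolerance = 1e-10)
  expect_equal(fit$estimates$te_log, nde + nie, tolerance = 1e-10)
})

test_that("no-interaction fit reduces to the product of coefficients and the difference method", {
  d <- quick_cohort(n = 250, seed = 41)
  spec <- mediation_spec(interaction = FALSE)
  fit <- estimate_mediation(d, spec)
  th <- fit$outcome_fit$coefficients
  prod_nie <- sum(vapply(
    fit$spec$mediators,
    function(k) th[[paste0("m_", k)]] *
      fit$mediator_fits[[paste0("m_", k)]]$coefficients[["arm"]],
    numeric(1)))
  expect_equal(fit$estimates$nie_log, prod_nie, tolerance = 1e-12)
  # difference method: marginal ITT coefficient minus adjusted direct effect
  expect_equal(fit$te_marginal_log - fit$estimates$nde_log,
               fit$estimates$nie_log, tolerance = 1e-8)
})

test_that("estimates are invariant to covariate location and outcome scaling", {
  d <- quick_cohort(n = 200, seed = 43, tau = c(sbp = 0.01, egfr = 0))
  spec <- mediation_spec()
  fit <- estimate_mediation(d, spec)

  shifted <- as_tibble(d) |>
    dplyr::mutate(sbp = sbp + 30, egfr = egfr + 10, uacr = uacr * 3)
  fit2 <- estimate_mediation(trial_data(shifted), spec)
  expect_equal(fit$estimates, fit2$estimates, tolerance = 1e-9)
})

test_that("swapping arm labels negates the total effect", {
  d <- quick_cohort(n = 200, seed = 47)
  spec <- mediation_spec(interaction = FALSE)
  fit <- estimate_mediation(d, spec)
  swapped <- as_tibble(d) |> dplyr::mutate(arm = 1L - arm)
  fit2 <- estimate_mediation(trial_data(swapped), spec)
  expect_equal(fit2$te_marginal_log, -fit$te_marginal_log, tolerance = 1e-10)
  expect_equal(fit2$estimates$te_log, -fit$estimates$te_log,
               tolerance = 1e-8)
})

test_that("proportion mediated follows the log-scale convention", {
  expect_equal(round(pm_from_ratios(0.911, 0.385), 1), 9.8)
  expect_equal(pm_from_ratios(1, 0.5), 0)
  expect_equal(pm_from_ratios(0.7, 0.7), 100)
  expect_warning(pm <- proportion_mediated(0.1, 0), "undefined")
  expect_true(is.na(pm))
  expect_equal(ratio_reduction_pct(0.422), 57.8)
})

test_that("mediation_spec validates mediators and always carries their baselines", {
  expect_error(mediation_spec(mediators = character(0)),
               class = "longmediate_config_error")
  expect_error(mediation_spec(mediators = "weight"),
               class = "longmediate_lookup_error")
  expect_error(mediation_spec(covariates = "height0"),
               class = "longmediate_config_error")
  sp <- mediation_spec(mediators = "egfr", covariates = "log_uacr0")
  expect_true("egfr0" %in% sp$covariates)
})
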