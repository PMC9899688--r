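# Small in-code fixtures shared across test files.

# one patient's visit rows
visits <- function(id, arm, weeks, uacr = NA_real_, sbp = NA_real_,
                   dbp = NA_real_, egfr = NA_real_, ...) {
  tibble::tibble(patient_id = id, arm = arm, week = weeks,
                 uacr = uacr, sbp = sbp, dbp = dbp, egfr = egfr, ...)
}

# four-patient two-arm dataset with complete baselines, weeks 0/4/8/12
small_trial <- function() {
  trial_data(dplyr::bind_rows(
    visits("A1", 1L, c(0L, 4L, 8L, 12L),
           uacr = c(100, 90, 80, 60), sbp = c(140, 138, 134, 132),
           dbp = c(90, 89, 88, 87), egfr = c(70, 69, 68, 67),
           sex = "male"),
    visits("A2", 1L, c(0L, 4L, 8L, 12L),
           uacr = c(200, 180, 150, 120), sbp = c(150, 146, 142, 140),
           dbp = c(95, 93, 92, 91), egfr = c(60, 59, 58, 57),
           sex = "female"),
    visits("B1", 0L, c(0L, 4L, 8L, 12L),
           uacr = c(120, 118, 115, 110), sbp = c(138, 138, 137, 137),
           dbp = c(88, 88, 87, 87), egfr = c(72, 72, 71, 71),
           sex = "male"),
    visits("B2", 0L, c(0L, 4L, 8L, 12L),
           uacr = c(90, 92, 91, 88), sbp = c(142, 141, 141, 140),
           dbp = c(92, 92, 91, 91), egfr = c(65, 65, 64, 64),
           sex = "female")
  ))
}

# a quick generated cohort with overridable config
quick_cohort <- function(n = 100, seed = 11, ...) {
  generate_cohort(cohort_config(n_patients = n, seed = seed, ...))
}

# a mediation_fit built directly from ratio-scale effects, for table tests
fake_fit <- function(nde_ratio, nie_ratio, mediators = "egfr",
                     convention = "cumulative_mean") {
  te_ratio <- nde_ratio * nie_ratio
  est <- tibble::tibble(
    te_log = log(te_ratio), nde_log = log(nde_ratio),
    nie_log = log(nie_ratio), te_ratio = te_ratio,
    nde_ratio = nde_ratio, nie_ratio = nie_ratio,
    pm_pct = 100 * log(nie_ratio) / log(te_ratio))
  structure(list(estimates = est,
                 spec = mediation_spec(mediators = mediators,
                                       convention = convention),
                 n_used = 449L),
            class = "mediation_fit")
}

expect_tibble_equal <- function(a, b, tol = 1e-12) {
  attr(a, "meta") <- attr(b, "meta") <- NULL
  a <- as.data.frame(a)[order(a$patient_id, a$week), ]
  b <- as.data.frame(b)[names(a)]
  b <- b[order(b$patient_id, b$week), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b, tolerance = tol)
}
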