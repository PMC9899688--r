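# Synthetic two-arm trial cohorts with a known linear structural mediation
# model. Each patient gets baseline values, a per-mediator target change
# (treatment effect + covariate effects + noise) reached along a
# piecewise-linear ramp that plateaus at a mediator-specific week, and a
# log-scale outcome change at the endpoint driven by a direct treatment
# path plus the mediator summaries. Because the structural coefficients are
# known, the implied natural direct/indirect/total effects are available in
# closed form and every estimator in the package can be checked against
# them.

#' Configuration for the synthetic trial-cohort generator
#'
#' Returns the default generator configuration, optionally overridden via
#' `...`. Defaults emulate a 449-patient, 52-week, two-arm trial in which
#' the active arm lowers SBP (plateauing near week 30) and eGFR (plateauing
#' near week 24), both mediator paths and a direct path reduce log UACR, and
#' visits follow the 2-weekly-then-4-weekly mediator schedule with UACR
#' every 4 weeks. The default structural coefficients are a calibration
#' choice: they place the total-effect geometric ratio near 0.39 with modest
#' mediated fractions, a regime typical of albuminuria trials.
#'
#' Key fields (units in parentheses):
#' \describe{
#'   \item{n_patients, allocation, seed}{cohort size, active-arm
#'     probability, RNG seed.}
#'   \item{mediator_schedule, uacr_schedule}{visit weeks for mediators and
#'     for UACR; week 0 is baseline.}
#'   \item{baseline_log_uacr, baseline_sbp, baseline_dbp, baseline_egfr}{
#'     `c(mean=, sd=)` of the baseline distributions (log mg/g; mmHg; mmHg;
#'     mL/min/1.73 m^2).}
#'   \item{alpha}{named treatment effects on each mediator's target change
#'     (mediator units; negative = decrease).}
#'   \item{plateau_week}{named weeks at which each trajectory (including
#'     `uacr`) levels off; change(t) = target * min(1, t/plateau).}
#'   \item{gamma, tau}{mediator-summary main effects and
#'     treatment-by-mediator interactions on the log outcome (per mediator
#'     unit); `names(gamma)` defines which mediators enter the outcome.}
#'   \item{delta}{direct treatment effect on the log outcome.}
#'   \item{covariate_slopes}{list of named slopes of centered baseline
#'     covariates (`log_uacr0`, `sbp0`, `dbp0`, `egfr0`) on each mediator
#'     target and on the outcome.}
#'   \item{sigma_m, sigma_y}{mediator-target and outcome noise SDs.}
#'   \item{missing_rate}{independent per-visit drop probability (baseline
#'     never dropped).}
#'   \item{summary, endpoint_week}{the mediator-summary convention and
#'     endpoint week the structural outcome model uses.}
#' }
#'
#' @param ... Named overrides of any default field.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_patients = 449L,
    allocation = 0.5,
    seed = 1L,
    mediator_schedule = c(0L, 2L, 4L, 6L, 8L, seq(12L, 52L, 4L)),
    uacr_schedule = seq(0L, 52L, 4L),
    endpoint_week = 52L,
    summary = "cumulative_mean",
    baseline_log_uacr = c(mean = log(120), sd = 0.6),
    baseline_sbp = c(mean = 141, sd = 12),
    baseline_dbp = c(mean = 82, sd = 9),
    baseline_egfr = c(mean = 68, sd = 14),
    alpha = c(sbp = -5, dbp = -3, egfr = -4),
    plateau_week = c(sbp = 30, dbp = 30, egfr = 24, uacr = 24),
    gamma = c(sbp = 0.028, egfr = 0.080),
    tau = c(sbp = 0, egfr = 0),
    delta = -0.630,
    covariate_slopes = list(
      sbp = c(sbp0 = -0.10),
      dbp = c(dbp0 = -0.10),
      egfr = c(egfr0 = -0.05),
      outcome = c(log_uacr0 = -0.05)
    ),
    sigma_m = c(sbp = 8, dbp = 6, egfr = 6),
    sigma_y = 0.7,
    missing_rate = 0.02,
    attribute_probs = c(sex_male = 0.75, bmi_high = 0.45, hba1c_high = 0.5,
                        dpp4_use = 0.35, sglt2_use = 0.25)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0) {
    abort(paste0("Unknown cohort_config field(s): ",
                 paste(unknown, collapse = ", ")),
          class = "longmediate_config_error")
  }
  cfg <- modifyList(cfg, over)
  validate_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_config <- function(cfg) {
  stopifnot(cfg$n_patients >= 1)
  if (cfg$allocation < 0 || cfg$allocation > 1) {
    abort("allocation must be in [0, 1].", class = "longmediate_config_error")
  }
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1) {
    abort("missing_rate must be in [0, 1).",
          class = "longmediate_config_error")
  }
  sds <- c(cfg$baseline_log_uacr["sd"], cfg$baseline_sbp["sd"],
           cfg$baseline_dbp["sd"], cfg$baseline_egfr["sd"],
           cfg$sigma_m, cfg$sigma_y)
  if (any(sds < 0)) {
    abort("All SDs must be >= 0.", class = "longmediate_config_error")
  }
  if (!cfg$summary %in% c("cumulative_mean", "achieved")) {
    abort("summary must be 'cumulative_mean' or 'achieved'.",
          class = "longmediate_config_error")
  }
  if (!all(names(cfg$gamma) %in% names(cfg$alpha))) {
    abort("Every mediator in gamma needs an alpha entry.",
          class = "longmediate_config_error")
  }
  invisible(cfg)
}

# centered-covariate matrix used by both the generator and true_effects
generator_covariates <- function(cfg, log_uacr0, sbp0, dbp0, egfr0) {
  cbind(log_uacr0 = log_uacr0 - cfg$baseline_log_uacr[["mean"]],
        sbp0 = sbp0 - cfg$baseline_sbp[["mean"]],
        dbp0 = dbp0 - cfg$baseline_dbp[["mean"]],
        egfr0 = egfr0 - cfg$baseline_egfr[["mean"]])
}

cov_contrib <- function(slopes, covmat) {
  if (is.null(slopes) || length(slopes) == 0) return(rep(0, nrow(covmat)))
  drop(covmat[, names(slopes), drop = FALSE] %*% slopes)
}

ramp_frac <- function(week, plateau) pmin(1, week / plateau)

# expected summary fraction of the target change under the full schedule
summary_fraction <- function(cfg, mediator) {
  s <- cfg$mediator_schedule
  s <- s[s > 0 & s <= cfg$endpoint_week]
  pl <- cfg$plateau_week[[mediator]]
  if (cfg$summary == "cumulative_mean") {
    mean(ramp_frac(s, pl))
  } else {
    before <- s[s < cfg$endpoint_week]
    wk <- if (length(before) > 0) max(before) else cfg$endpoint_week
    ramp_frac(wk, pl)
  }
}

#' Generate a synthetic trial cohort
#'
#' Draws a [trial_data] cohort from the linear structural model described in
#' [cohort_config()]. For patient i with arm A_i and centered baseline
#' covariates C_i, each mediator k has target change
#' T_ik = alpha_k A_i + b_k' C_i + e_ik, e_ik ~ N(0, sigma_m_k), and its
#' visit-week value is baseline + T_ik * min(1, week/plateau_k). Post-baseline
#' visits are dropped independently with probability `missing_rate`. The
#' log-outcome change at the endpoint is
#' delta A_i + sum_k (gamma_k + tau_k A_i) M_ik + c' C_i + eps_i with
#' eps_i ~ N(0, sigma_y), where M_ik is the configured mediator summary
#' computed on the patient's realized (non-missing) visit schedule — so the
#' structural mediator is exactly the quantity the estimator reconstructs.
#' Interim UACR values follow the same endpoint log-change scaled along the
#' UACR ramp. A fixed seed makes the dataset reproducible bit for bit.
#'
#' @param cfg A [cohort_config()].
#' @return A [trial_data] tibble; `meta` records the seed.
#' @export
generate_cohort <- function(cfg) {
  validate_config(cfg)
  n <- as.integer(cfg$n_patients)
  set.seed(cfg$seed)

  # patient-level draws, fixed order
  arm <- rbinom(n, 1L, cfg$allocation)
  log_uacr0 <- rnorm(n, cfg$baseline_log_uacr[["mean"]],
                     cfg$baseline_log_uacr[["sd"]])
  sbp0 <- rnorm(n, cfg$baseline_sbp[["mean"]], cfg$baseline_sbp[["sd"]])
  dbp0 <- rnorm(n, cfg$baseline_dbp[["mean"]], cfg$baseline_dbp[["sd"]])
  egfr0 <- rnorm(n, cfg$baseline_egfr[["mean"]], cfg$baseline_egfr[["sd"]])
  ap <- cfg$attribute_probs
  sex <- ifelse(rbinom(n, 1L, ap[["sex_male"]]) == 1L, "male", "female")
  bmi_class <- ifelse(rbinom(n, 1L, ap[["bmi_high"]]) == 1L, ">=25", "<25")
  hba1c_class <- ifelse(rbinom(n, 1L, ap[["hba1c_high"]]) == 1L,
                        ">=7.4", "<7.4")
  dpp4_use <- ifelse(rbinom(n, 1L, ap[["dpp4_use"]]) == 1L, "yes", "no")
  sglt2_use <- ifelse(rbinom(n, 1L, ap[["sglt2_use"]]) == 1L, "yes", "no")
  uacr_class <- ifelse(exp(log_uacr0) < 100, "<100", ">=100")
  egfr_class <- ifelse(egfr0 < 60, "<60", ">=60")

  covmat <- generator_covariates(cfg, log_uacr0, sbp0, dbp0, egfr0)
  med_names <- names(cfg$alpha)
  targets <- sapply(med_names, function(k) {
    cfg$alpha[[k]] * arm + cov_contrib(cfg$covariate_slopes[[k]], covmat) +
      rnorm(n, 0, cfg$sigma_m[[k]])
  })

  # visit presence: union grid of both schedules, baseline never dropped
  weeks <- sort(union(cfg$mediator_schedule, cfg$uacr_schedule))
  post <- weeks[weeks > 0]
  present <- matrix(rbinom(n * length(post), 1L, 1 - cfg$missing_rate) == 1L,
                    nrow = n, dimnames = list(NULL, post))
  # keep every patient summarizable: force the last mediator visit present
  med_post <- as.character(intersect(post, cfg$mediator_schedule))
  none <- rowSums(present[, med_post, drop = FALSE]) == 0
  if (any(none)) present[none, med_post[length(med_post)]] <- TRUE

  # structural mediator summaries on the realized schedule
  out_meds <- names(cfg$gamma)
  med_weeks <- cfg$mediator_schedule
  med_weeks <- med_weeks[med_weeks > 0 & med_weeks <= cfg$endpoint_week]
  pres_med <- present[, as.character(med_weeks), drop = FALSE]
  M <- sapply(out_meds, function(k) {
    fr <- ramp_frac(med_weeks, cfg$plateau_week[[k]])
    if (cfg$summary == "cumulative_mean") {
      fbar <- as.vector(pres_med %*% fr) / rowSums(pres_med)
    } else {
      before <- med_weeks < cfg$endpoint_week
      idx_last <- apply(pres_med, 1, function(p) {
        cand <- which(p & before)
        if (length(cand) > 0) max(cand) else max(which(p))
      })
      fbar <- fr[idx_last]
    }
    targets[, k] * fbar
  })

  delta_log <- cfg$delta * arm +
    as.vector(M %*% cfg$gamma[out_meds]) +
    as.vector((M * arm) %*% cfg$tau[out_meds]) +
    cov_contrib(cfg$covariate_slopes$outcome, covmat) +
    rnorm(n, 0, cfg$sigma_y)

  # assemble long visit rows
  base_vals <- cbind(sbp = sbp0, dbp = dbp0, egfr = egfr0)
  grid <- tidyr::expand_grid(idx = seq_len(n), week = weeks)
  keep <- grid$week == 0L |
    present[cbind(grid$idx, match(as.character(grid$week),
                                  colnames(present)))]
  grid <- grid[keep, ]
  i <- grid$idx
  w <- grid$week
  med_row <- w %in% cfg$mediator_schedule
  rows <- tibble(
    patient_id = sprintf("P%04d", i),
    arm = arm[i],
    week = as.integer(w),
    uacr = ifelse(w %in% cfg$uacr_schedule,
                  exp(log_uacr0[i] +
                        delta_log[i] *
                          ramp_frac(w, cfg$plateau_week[["uacr"]])),
                  NA_real_),
    sbp = ifelse(med_row, sbp0[i] +
                   targets[i, "sbp"] * ramp_frac(w, cfg$plateau_week[["sbp"]]),
                 NA_real_),
    dbp = ifelse(med_row, dbp0[i] +
                   targets[i, "dbp"] * ramp_frac(w, cfg$plateau_week[["dbp"]]),
                 NA_real_),
    egfr = ifelse(med_row, egfr0[i] +
                    targets[i, "egfr"] *
                      ramp_frac(w, cfg$plateau_week[["egfr"]]),
                  NA_real_),
    sex = sex[i], bmi_class = bmi_class[i], hba1c_class = hba1c_class[i],
    uacr_class = uacr_class[i], egfr_class = egfr_class[i],
    dpp4_use = dpp4_use[i], sglt2_use = sglt2_use[i]
  )
  trial_data(rows, meta = list(generator_seed = cfg$seed,
                               summary = cfg$summary,
                               endpoint_week = cfg$endpoint_week))
}

#' Closed-form true effects implied by a generator configuration
#'
#' Evaluates the natural direct, natural indirect and total effects that the
#' structural model of [generate_cohort()] implies for the contrast active
#' (a = 1) versus control (a* = 0) at the population covariate mean (which
#' is zero, since the generator centers covariates):
#' nde_log = delta + sum_k tau_k (b_k' cbar); nie_log = sum_k
#' (gamma_k + tau_k) alpha_k f_k, where f_k is the expected fraction of the
#' target change captured by the configured summary under the full visit
#' schedule (1 for the achieved summary once the last pre-endpoint visit is
#' past the plateau); te_log is their sum. Ratio-scale fields are the
#' exponentials and pm_pct = 100 nie_log / te_log (missing, with a warning,
#' when te_log = 0).
#'
#' @param cfg A [cohort_config()].
#' @return One-row tibble: `nde_log`, `nie_log`, `te_log`, `nde_ratio`,
#'   `nie_ratio`, `te_ratio`, `pm_pct`.
#' @export
true_effects <- function(cfg) {
  validate_config(cfg)
  out_meds <- names(cfg$gamma)
  # centered covariates: population mean is exactly zero
  cbar_term <- 0
  nde <- cfg$delta + sum(cfg$tau[out_meds] * cbar_term)
  nie <- sum(vapply(out_meds, function(k) {
    (cfg$gamma[[k]] + cfg$tau[[k]]) * cfg$alpha[[k]] * summary_fraction(cfg, k)
  }, numeric(1)))
  te <- nde + nie
  pm <- if (te == 0) {
    warn("Total effect is zero: proportion mediated undefined.")
    NA_real_
  } else 100 * nie / te
  tibble(nde_log = nde, nie_log = nie, te_log = te,
         nde_ratio = exp(nde), nie_ratio = exp(nie), te_ratio = exp(te),
         pm_pct = pm)
}
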