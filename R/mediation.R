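# Regression-based natural effect decomposition. One outcome model with
# treatment, mediator summaries, treatment-by-mediator interactions and
# baseline covariates; one linear model per mediator summary on treatment
# and the same covariates; closed-form natural direct / indirect / total
# effects for the contrast a vs a*, evaluated at the covariate sample mean
# (with linear models this equals the average of patient-level conditional
# effects, so conditional and marginal reports coincide).

#' Describe one mediation analysis
#'
#' A declarative specification of a mediation run: which mediator summaries
#' enter the outcome model, at which endpoint week, with which baseline
#' covariates, and for which treatment contrast.
#'
#' @param mediators Character vector of mediator names (subset of `"sbp"`,
#'   `"dbp"`, `"map"`, `"egfr"`), 1 to 4 of them; with several mediators the
#'   indirect effect is the joint effect through all of them (no
#'   per-mediator split, so mediator-to-mediator causation need not be
#'   specified).
#' @param convention Mediator-summary convention, `"cumulative_mean"` or
#'   `"achieved"`.
#' @param endpoint_week Analysis endpoint (default 52, end of treatment).
#' @param covariates Baseline covariates of the outcome and mediator models.
#'   `NULL` (default) means log baseline UACR plus the baseline value of
#'   every analyzed mediator. Recognized names: `"log_uacr0"`, `"sbp0"`,
#'   `"dbp0"`, `"map0"`, `"egfr0"`. Mediator baselines are always included.
#' @param contrast Numeric `c(a, a_star)`; default `c(1, 0)`, active versus
#'   control.
#' @param interaction Include treatment-by-mediator interaction terms in the
#'   outcome model (default `TRUE`). With `FALSE` the indirect effect
#'   reduces to the classic product of coefficients.
#' @param at_endpoint,time_weighted Summary switches, see
#'   [achieved_change()] and [cumulative_mean_change()].
#' @return A `mediation_spec` object.
#' @export
mediation_spec <- function(mediators = c("sbp", "egfr"),
                           convention = c("cumulative_mean", "achieved"),
                           endpoint_week = 52L,
                           covariates = NULL,
                           contrast = c(1, 0),
                           interaction = TRUE,
                           at_endpoint = FALSE,
                           time_weighted = FALSE) {
  convention <- match.arg(convention)
  mediators <- unique(mediators)
  purrr::walk(mediators, check_mediator)
  if (length(mediators) < 1 || length(mediators) > 4) {
    abort("Between 1 and 4 mediators are supported.",
          class = "longmediate_config_error")
  }
  allowed_cov <- c("log_uacr0", paste0(MEDIATORS, "0"))
  med_base <- paste0(mediators, "0")
  covariates <- unique(c(covariates %||% "log_uacr0", med_base))
  bad <- setdiff(covariates, allowed_cov)
  if (length(bad) > 0) {
    abort(paste0("Unrecognized covariate(s): ", paste(bad, collapse = ", "),
                 ". Allowed: ", paste(allowed_cov, collapse = ", ")),
          class = "longmediate_config_error")
  }
  stopifnot(length(contrast) == 2, contrast[1] != contrast[2])
  structure(list(mediators = mediators, convention = convention,
                 endpoint_week = as.integer(endpoint_week),
                 covariates = covariates, contrast = as.numeric(contrast),
                 interaction = isTRUE(interaction),
                 at_endpoint = isTRUE(at_endpoint),
                 time_weighted = isTRUE(time_weighted)),
            class = "mediation_spec")
}

#' @export
print.mediation_spec <- function(x, ...) {
  cat(sprintf(
    "<mediation_spec> mediators: %s | summary: %s | endpoint: week %d\n",
    paste(x$mediators, collapse = "+"), x$convention, x$endpoint_week))
  cat(sprintf("  covariates: %s | contrast: a=%g vs a*=%g | interaction: %s\n",
              paste(x$covariates, collapse = ", "), x$contrast[1],
              x$contrast[2], x$interaction))
  invisible(x)
}

#' Log-ratio outcome at the endpoint week
#'
#' The analysis outcome: natural log of UACR at the endpoint divided by
#' UACR at baseline (so arm contrasts back-transform to geometric mean
#' ratios to baseline versus control).
#'
#' @param data A [trial_data] tibble.
#' @param endpoint_week Integer endpoint week.
#' @return Tibble with columns `patient_id`, `y` (missing when either UACR
#'   value is missing; such patients are excluded by [analysis_set()]).
#' @export
outcome_log_ratio <- function(data, endpoint_week) {
  d <- as_tibble(data)
  base <- d %>% filter(.data$week == 0L) %>%
    select(all_of(c("patient_id", "uacr"))) %>% rename(u0 = "uacr")
  endv <- d %>% filter(.data$week == as.integer(endpoint_week)) %>%
    select(all_of(c("patient_id", "uacr"))) %>% rename(u1 = "uacr")
  tibble(patient_id = unique(d$patient_id)) %>%
    left_join(base, by = "patient_id") %>%
    left_join(endv, by = "patient_id") %>%
    mutate(y = log(.data$u1 / .data$u0)) %>%
    select(all_of(c("patient_id", "y")))
}

baseline_covariate <- function(data, name) {
  d <- as_tibble(data) %>% filter(.data$week == 0L)
  if (name == "log_uacr0") return(tibble(patient_id = d$patient_id,
                                         value = log(d$uacr)))
  med <- sub("0$", "", name)
  tibble(patient_id = d$patient_id, value = mediator_column(d, med))
}

#' One-row-per-patient frame for a mediation analysis
#'
#' Applies the complete-case [analysis_set()] rule for the spec's endpoint,
#' computes the log-ratio outcome, the mediator summaries and the baseline
#' covariates, and drops patients with any missing entry. Whole-patient
#' bootstrap resampling operates on rows of this frame (summaries are
#' per-patient, so resampling the frame is identical to resampling the
#' dataset).
#'
#' @param data A [trial_data] tibble.
#' @param spec A [mediation_spec()].
#' @return Tibble with `patient_id`, `arm`, `y`, one `m_<mediator>` column
#'   per mediator, and one column per covariate.
#' @export
analysis_frame <- function(data, spec) {
  stopifnot(inherits(spec, "mediation_spec"))
  ds <- analysis_set(data, spec$endpoint_week)
  frame <- outcome_log_ratio(ds, spec$endpoint_week)
  arms <- as_tibble(ds) %>% distinct(.data$patient_id, .data$arm)
  frame <- frame %>% left_join(arms, by = "patient_id")
  extra <- if (spec$convention == "cumulative_mean") {
    list(time_weighted = spec$time_weighted)
  } else {
    list(at_endpoint = spec$at_endpoint)
  }
  summ <- rlang::exec(mediator_summaries, ds, spec$mediators,
                      spec$convention, spec$endpoint_week, !!!extra) %>%
    mutate(col = paste0("m_", .data$mediator)) %>%
    select(all_of(c("patient_id", "col", "value"))) %>%
    tidyr::pivot_wider(names_from = "col", values_from = "value")
  frame <- frame %>% left_join(summ, by = "patient_id")
  for (cv in spec$covariates) {
    frame[[cv]] <- baseline_covariate(ds, cv)$value[
      match(frame$patient_id, baseline_covariate(ds, cv)$patient_id)]
  }
  frame <- frame %>% select(all_of(c("patient_id", "arm", "y",
                                     paste0("m_", spec$mediators),
                                     spec$covariates)))
  frame[stats::complete.cases(frame), ]
}

#' Ordinary least squares with an explicit rank contract
#'
#' Thin wrapper over base R's pivoted QR least squares that turns rank
#' deficiency and under-determination into informative errors (naming the
#' collinear columns) instead of silently aliasing coefficients.
#'
#' @param y Numeric response vector.
#' @param X Numeric design matrix with column names (include the intercept
#'   column yourself).
#' @return List with `coefficients` (named), `residual_sd` (divisor n - p),
#'   `rank`, `n`.
#' @export
fit_least_squares <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- length(y)
  if (n <= ncol(X)) {
    abort(sprintf("Insufficient data: %d rows for %d coefficients.",
                  n, ncol(X)),
          class = "longmediate_estimation_error")
  }
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) {
    aliased <- colnames(X)[fit$qr$pivot[(fit$rank + 1):ncol(X)]]
    abort(paste0("Rank-deficient design: collinear column(s) ",
                 paste(aliased, collapse = ", ")),
          class = "longmediate_estimation_error")
  }
  rss <- sum(fit$residuals^2)
  list(coefficients = fit$coefficients,
       residual_sd = sqrt(rss / (n - ncol(X))),
       rank = fit$rank, n = n)
}

# Closed-form decomposition on a prepared frame. Kept free of data-frame
# overhead because the bootstrap calls it tens of thousands of times.
fit_mediation_frame <- function(arm, y, M, C, contrast, interaction = TRUE) {
  a <- contrast[1]; astar <- contrast[2]
  K <- ncol(M)
  mnames <- colnames(M)
  if (!all(c(0, 1) %in% arm)) {
    abort("Both treatment arms are required for estimation.",
          class = "longmediate_estimation_error")
  }
  Xparts <- cbind(`(Intercept)` = 1, arm = arm, M)
  if (interaction) {
    AM <- M * arm
    colnames(AM) <- paste0("arm:", mnames)
    Xparts <- cbind(Xparts, AM)
  }
  if (ncol(C) > 0) Xparts <- cbind(Xparts, C)
  outcome_fit <- fit_least_squares(y, Xparts)
  theta <- outcome_fit$coefficients

  Xm <- cbind(`(Intercept)` = 1, arm = arm)
  if (ncol(C) > 0) Xm <- cbind(Xm, C)
  mediator_fits <- lapply(mnames, function(k) fit_least_squares(M[, k], Xm))
  names(mediator_fits) <- mnames

  cbar <- if (ncol(C) > 0) colMeans(C) else numeric(0)
  theta_AM <- if (interaction) theta[paste0("arm:", mnames)] else
    setNames(rep(0, K), mnames)
  m_astar <- vapply(mnames, function(k) {
    b <- mediator_fits[[k]]$coefficients
    b[["(Intercept)"]] + b[["arm"]] * astar +
      (if (length(cbar) > 0) sum(b[names(cbar)] * cbar) else 0)
  }, numeric(1))
  beta_A <- vapply(mnames, function(k) {
    mediator_fits[[k]]$coefficients[["arm"]]
  }, numeric(1))

  nde <- (theta[["arm"]] + sum(theta_AM * m_astar)) * (a - astar)
  nie <- sum((theta[mnames] + theta_AM * a) * beta_A) * (a - astar)
  te <- nde + nie

  # marginal ITT regression of the outcome on treatment and covariates only
  te_marginal <- fit_least_squares(y, Xm)$coefficients[["arm"]] * (a - astar)

  list(nde_log = unname(nde), nie_log = unname(nie), te_log = unname(te),
       pm_pct = proportion_mediated(unname(nie), unname(te), quiet = TRUE),
       te_marginal_log = te_marginal,
       outcome_fit = outcome_fit, mediator_fits = mediator_fits,
       n_used = length(y))
}

frame_matrices <- function(frame, spec) {
  mcols <- paste0("m_", spec$mediators)
  list(arm = frame$arm, y = frame$y,
       M = as.matrix(frame[, mcols, drop = FALSE]),
       C = as.matrix(frame[, spec$covariates, drop = FALSE]))
}

#' Estimate natural direct, indirect and total effects
#'
#' Fits the outcome model
#' Y = theta_0 + theta_A A + sum_k (theta_Mk M_k + theta_AMk A M_k) +
#' theta_C' C and per-mediator models M_k = beta_0k + beta_Ak A + beta_Ck' C
#' on the complete-case analysis frame, then evaluates the closed-form
#' natural effects for the contrast a vs a* at the covariate sample mean
#' cbar:
#' \deqn{NDE = [\theta_A + \sum_k \theta_{AMk} \bar m_k(a^*)] (a - a^*)}
#' \deqn{NIE = [\sum_k (\theta_{Mk} + \theta_{AMk} a) \beta_{Ak}] (a - a^*)}
#' with \eqn{\bar m_k(a^*) = \beta_{0k} + \beta_{Ak} a^* + \beta_{Ck}'
#' \bar c}; the total effect is their sum, ratio-scale effects are the
#' exponentials (geometric mean ratios to baseline versus control), and the
#' proportion mediated is 100 nie_log / te_log. With several mediators the
#' NIE is the joint indirect effect through all of them. The marginal ITT
#' regression coefficient of treatment (outcome on treatment and covariates
#' only) is carried along as a consistency check, not as the headline total
#' effect.
#'
#' @param data A [trial_data] tibble.
#' @param spec A [mediation_spec()].
#' @return A `mediation_fit` object; see [tidy.mediation_fit()] and
#'   [glance.mediation_fit()].
#' @export
estimate_mediation <- function(data, spec) {
  frame <- analysis_frame(data, spec)
  mats <- frame_matrices(frame, spec)
  res <- fit_mediation_frame(mats$arm, mats$y, mats$M, mats$C,
                             spec$contrast, spec$interaction)
  estimates <- tibble(
    te_log = res$te_log, nde_log = res$nde_log, nie_log = res$nie_log,
    te_ratio = exp(res$te_log), nde_ratio = exp(res$nde_log),
    nie_ratio = exp(res$nie_log), pm_pct = res$pm_pct
  )
  structure(list(estimates = estimates, spec = spec, frame = frame,
                 n_used = res$n_used,
                 te_marginal_log = res$te_marginal_log,
                 outcome_fit = res$outcome_fit,
                 mediator_fits = res$mediator_fits),
            class = "mediation_fit")
}

#' @export
print.mediation_fit <- function(x, digits = 3, ...) {
  e <- x$estimates
  cat(sprintf(
    "<mediation_fit> %s (%s, week %d), n = %d\n",
    paste(x$spec$mediators, collapse = "+"), x$spec$convention,
    x$spec$endpoint_week, x$n_used))
  cat(sprintf("  TE  ratio %.*f (log %+.4f)\n", digits, e$te_ratio, e$te_log))
  cat(sprintf("  NDE ratio %.*f (log %+.4f)\n", digits, e$nde_ratio,
              e$nde_log))
  cat(sprintf("  NIE ratio %.*f (log %+.4f)\n", digits, e$nie_ratio,
              e$nie_log))
  cat(sprintf("  proportion mediated %.1f%%\n", e$pm_pct))
  invisible(x)
}

#' Proportion of the total effect transmitted through the mediators
#'
#' Computed on the additive (log) scale: 100 * nie_log / te_log, which is
#' identical to 100 * ln(NIE ratio) / ln(TE ratio). Undefined (missing, with
#' a warning) when the total effect is zero.
#'
#' @param nie_log Natural indirect effect on the log scale.
#' @param te_log Total effect on the log scale.
#' @param quiet Suppress the zero-total-effect warning.
#' @return Percentage (vectorized).
#' @export
proportion_mediated <- function(nie_log, te_log, quiet = FALSE) {
  out <- ifelse(te_log == 0, NA_real_, 100 * nie_log / te_log)
  if (any(te_log == 0) && !quiet) {
    warn("Total effect is zero: proportion mediated undefined.")
  }
  out
}

#' Proportion mediated from ratio-scale (back-transformed) effects
#'
#' @param nie_ratio,te_ratio Geometric-mean-ratio effects (e.g. as printed
#'   in a results table).
#' @return Percentage, `100 * log(nie_ratio) / log(te_ratio)`.
#' @export
pm_from_ratios <- function(nie_ratio, te_ratio) {
  proportion_mediated(log(nie_ratio), log(te_ratio))
}

#' Percent reduction implied by a geometric mean ratio
#'
#' A ratio-to-baseline effect of r versus control corresponds to a
#' 100 (1 - r) percent reduction; e.g. a direct-effect ratio of 0.422 is a
#' 57.8 percent reduction independent of the mediators.
#'
#' @param ratio Geometric mean ratio(s).
#' @return Percentage reduction (vectorized).
#' @export
ratio_reduction_pct <- function(ratio) 100 * (1 - ratio)

#' Total effect from the marginal ITT regression, with consistency report
#'
#' Regresses the log-ratio outcome on treatment and the covariates only (no
#' mediators) — the intention-to-treat contrast — and reports it alongside
#' the decomposition total effect. The two agree exactly (to numerical
#' precision) when the outcome model carries no treatment-by-mediator
#' interaction, or carries interactions but no covariates; with both,
#' agreement is approximate at the order of the arms' covariate imbalance.
#'
#' @inheritParams estimate_mediation
#' @return One-row tibble: `te_log_marginal`, `te_log_decomposition`,
#'   `difference`.
#' @export
total_effect_check <- function(data, spec) {
  fit <- estimate_mediation(data, spec)
  tibble(te_log_marginal = fit$te_marginal_log,
         te_log_decomposition = fit$estimates$te_log,
         difference = fit$te_marginal_log - fit$estimates$te_log)
}
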