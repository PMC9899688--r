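# Broom-style accessors and publication-style table rendering, plus a
# small replayable run-configuration record used by the command-line
# wrapper (inst/cli/mediate.R).

#' Tidy a mediation fit
#'
#' One row per effect (TE, NDE, NIE) with the log-scale estimate, the
#' back-transformed geometric mean ratio, and — when a bootstrap is
#' supplied — ratio-scale percentile interval bounds.
#'
#' @param x A `mediation_fit`.
#' @param boot Optional `mediation_boot` for the same fit.
#' @param ... Unused.
#' @return A tibble with columns `term`, `estimate` (log scale), `ratio`,
#'   and `conf.low`/`conf.high` (ratio scale) when `boot` is given.
#' @export
tidy.mediation_fit <- function(x, boot = NULL, ...) {
  e <- x$estimates
  out <- tibble(term = c("total", "direct", "indirect"),
                estimate = c(e$te_log, e$nde_log, e$nie_log),
                ratio = c(e$te_ratio, e$nde_ratio, e$nie_ratio))
  if (!is.null(boot)) {
    iv <- boot$intervals
    grab <- function(q, f) iv[[f]][iv$quantity == q]
    out$conf.low <- c(grab("te_ratio", "lower"), grab("nde_ratio", "lower"),
                      grab("nie_ratio", "lower"))
    out$conf.high <- c(grab("te_ratio", "upper"), grab("nde_ratio", "upper"),
                       grab("nie_ratio", "upper"))
  }
  out
}

#' One-row summary of a mediation fit
#'
#' @param x A `mediation_fit`.
#' @param ... Unused.
#' @return Tibble with the mediator set, summary convention, endpoint week,
#'   `n_used`, proportion mediated, marginal-ITT total effect and the
#'   outcome-model residual SD and rank.
#' @export
glance.mediation_fit <- function(x, ...) {
  tibble(mediators = paste(x$spec$mediators, collapse = "+"),
         convention = x$spec$convention,
         endpoint_week = x$spec$endpoint_week,
         n_used = x$n_used,
         pm_pct = x$estimates$pm_pct,
         te_marginal_log = x$te_marginal_log,
         sigma = x$outcome_fit$residual_sd,
         design_rank = x$outcome_fit$rank)
}

#' Render fits as a publication-style results table
#'
#' Mirrors the usual mediation-summary layout: per analysis, rows TE / NDE /
#' NIE on the geometric-ratio scale rounded to 3 decimal places with 95%
#' interval bounds (when bootstraps are supplied), and the proportion
#' mediated to 1 decimal place on the TE row. Full-precision values belong
#' in [tidy.mediation_fit()]; this renderer is for display and CSV export.
#'
#' @param fits A `mediation_fit` or list of them.
#' @param boots Optional `mediation_boot` or list matching `fits`.
#' @return Tibble with columns `mediator`, `summary`, `effect`, `estimate`,
#'   `conf.low`, `conf.high`, `pm`, `pm_lo`, `pm_hi`.
#' @export
render_results_table <- function(fits, boots = NULL) {
  if (inherits(fits, "mediation_fit")) fits <- list(fits)
  if (inherits(boots, "mediation_boot")) boots <- list(boots)
  purrr::imap(fits, function(fit, i) {
    bt <- if (!is.null(boots)) boots[[i]] else NULL
    td <- tidy(fit, boot = bt)
    pm_int <- if (!is.null(bt)) {
      iv <- bt$intervals
      c(iv$lower[iv$quantity == "pm_pct"], iv$upper[iv$quantity == "pm_pct"])
    } else c(NA_real_, NA_real_)
    tibble(
      mediator = paste(fit$spec$mediators, collapse = "+"),
      summary = fit$spec$convention,
      effect = c("TE", "NDE", "NIE"),
      estimate = round(td$ratio, 3),
      conf.low = if ("conf.low" %in% names(td)) round(td$conf.low, 3)
                 else NA_real_,
      conf.high = if ("conf.high" %in% names(td)) round(td$conf.high, 3)
                  else NA_real_,
      pm = c(round(fit$estimates$pm_pct, 1), NA_real_, NA_real_),
      pm_lo = c(round(pm_int[1], 1), NA_real_, NA_real_),
      pm_hi = c(round(pm_int[2], 1), NA_real_, NA_real_)
    )
  }) %>% bind_rows()
}

#' Aligned-text rendering of a results table
#'
#' @param tbl Output of [render_results_table()].
#' @return Character vector of formatted lines (also printed invisibly
#'   usable via `cat`).
#' @export
format_results_table <- function(tbl) {
  fmt_ci <- function(lo, hi) {
    ifelse(is.na(lo), "", sprintf(" (%.3f, %.3f)", lo, hi))
  }
  fmt_pm <- function(pm, lo, hi) {
    ifelse(is.na(pm), "",
           ifelse(is.na(lo), sprintf("%.1f%%", pm),
                  sprintf("%.1f (%.1f, %.1f)%%", pm, lo, hi)))
  }
  lines <- sprintf("%-10s %-16s %-4s %6.3f%-18s %s",
                   tbl$mediator, tbl$summary, tbl$effect, tbl$estimate,
                   fmt_ci(tbl$conf.low, tbl$conf.high),
                   fmt_pm(tbl$pm, tbl$pm_lo, tbl$pm_hi))
  header <- sprintf("%-10s %-16s %-4s %-25s %s",
                    "mediator", "summary", "effect", "ratio (95% CI)", "PM")
  c(header, lines)
}

#' Record of one reproducible analysis run
#'
#' A fully serializable description of an `analyze` or `scan` run: input
#' file, analysis settings, bootstrap settings and seed. A run can be
#' replayed from its recorded configuration alone and yields byte-identical
#' results.
#'
#' @param command `"analyze"` or `"scan"`.
#' @param input Path to the input long/wide CSV.
#' @param layout CSV layout, `"long"` or `"wide"`.
#' @param mediators,convention,endpoint_week,covariates Analysis settings,
#'   as in [mediation_spec()].
#' @param bootstrap Bootstrap replicates (0 disables).
#' @param seed Integer seed.
#' @param axis,weeks,attribute Scan settings (axis `"week"` or
#'   `"subgroup"`).
#' @return A `run_config` list.
#' @export
run_config <- function(command = c("analyze", "scan"), input,
                       layout = "long", mediators = c("sbp", "egfr"),
                       convention = "cumulative_mean", endpoint_week = 52L,
                       covariates = NULL, bootstrap = 0L, seed = 1L,
                       axis = "week", weeks = NULL, attribute = NULL) {
  structure(list(command = match.arg(command), input = input,
                 layout = layout, mediators = mediators,
                 convention = convention,
                 endpoint_week = as.integer(endpoint_week),
                 covariates = covariates, bootstrap = as.integer(bootstrap),
                 seed = as.integer(seed), axis = axis, weeks = weeks,
                 attribute = attribute),
            class = "run_config")
}

#' Write / read a run configuration as plain text
#'
#' Serialized with [dput()] so the record is human-readable, text-only and
#' dependency-free.
#'
#' @param cfg A [run_config()].
#' @param path File path.
#' @return `path` (write) or the `run_config` (read).
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  dput(unclass(cfg), file = path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- dget(path)
  do.call(run_config, cfg[!vapply(cfg, is.null, logical(1))])
}

#' Replay an analysis run from its recorded configuration
#'
#' Re-executes the run described by a [run_config()] and returns the
#' results table together with a structured log (dataset sizes, filters,
#' fit diagnostics, bootstrap failure counts). Replaying the same
#' configuration on the same input reproduces the results exactly.
#'
#' @param cfg A [run_config()].
#' @return List with `table` (results tibble) and `log` (character lines).
#' @export
replay_run <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  data <- read_trial_table(cfg$input, layout = cfg$layout)
  spec <- mediation_spec(mediators = cfg$mediators,
                         convention = cfg$convention,
                         endpoint_week = cfg$endpoint_week,
                         covariates = cfg$covariates)
  log <- c(sprintf("input: %s (%s layout), %d patients",
                   cfg$input, cfg$layout,
                   dplyr::n_distinct(data$patient_id)))
  if (cfg$command == "analyze") {
    fit <- estimate_mediation(data, spec)
    log <- c(log,
             sprintf("analysis set (week %d): n_used = %d, design rank = %d",
                     spec$endpoint_week, fit$n_used, fit$outcome_fit$rank))
    bt <- NULL
    if (cfg$bootstrap > 0) {
      bt <- bootstrap_mediation(fit, B = cfg$bootstrap, seed = cfg$seed)
      log <- c(log, sprintf("bootstrap: B = %d, degenerate redraws = %d",
                            bt$n_replicates, bt$n_failed))
    }
    table <- render_results_table(fit, bt)
  } else {
    scan <- if (cfg$axis == "week") {
      longitudinal_scan(data, spec, weeks = cfg$weeks, B = cfg$bootstrap,
                        seed = cfg$seed)
    } else {
      subgroup_scan(data, spec, attribute = cfg$attribute,
                    B = cfg$bootstrap, seed = cfg$seed)
    }
    log <- c(log, sprintf("scan axis: %s, %d cells (%d ok)",
                          attr(scan, "axis"), nrow(scan), sum(scan$ok)))
    table <- as_tibble(scan)
  }
  list(table = table, log = log)
}
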