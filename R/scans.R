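# Repeat the same mediation analysis along two axes: endpoint week
# (longitudinal scan; the complete-case analysis set is rebuilt per week,
# so per-week sample sizes may differ) and subgroup level. Per-cell
# bootstrap seeds are derived as master seed + cell index so cells are
# reproducible independently of scan order.

scan_cell <- function(data, spec, label, B, seed, extra = list()) {
  est <- tryCatch(estimate_mediation(data, spec), error = function(e) e)
  if (inherits(est, "error")) {
    return(tibble(label = label, ok = FALSE, note = conditionMessage(est),
                  n_used = NA_integer_, te_log = NA_real_,
                  nde_log = NA_real_, nie_log = NA_real_,
                  te_ratio = NA_real_, nde_ratio = NA_real_,
                  nie_ratio = NA_real_, pm_pct = NA_real_, !!!extra))
  }
  row <- est$estimates %>%
    mutate(label = label, ok = TRUE, note = NA_character_,
           n_used = est$n_used, !!!extra)
  if (B > 0) {
    bt <- bootstrap_mediation(est, B = B, seed = seed)
    for (q in c("te_ratio", "nde_ratio", "nie_ratio", "pm_pct")) {
      iv <- bt$intervals %>% filter(.data$quantity == q)
      row[[paste0(q, "_lo")]] <- iv$lower
      row[[paste0(q, "_hi")]] <- iv$upper
    }
  }
  row
}

finish_scan <- function(cells, axis, spec) {
  lead <- intersect(c("label", "week", "level", "n_used", "ok", "note"),
                    names(cells))
  out <- cells %>% select(all_of(lead), dplyr::everything())
  structure(out, axis = axis, spec = spec,
            class = c("mediation_scan", class(as_tibble(out))))
}

#' Mediation analysis across endpoint weeks
#'
#' Re-runs the analysis with the endpoint moved to each requested week:
#' per week, the complete-case analysis set is rebuilt (only patients with
#' a UACR value at that week enter), mediator summaries are recomputed up
#' to / just before that week, and the decomposition (optionally with a
#' bootstrap) is estimated. A week whose analysis fails (e.g. an empty arm)
#' is flagged in its row and the scan continues.
#'
#' @param data A [trial_data] tibble.
#' @param spec A [mediation_spec()]; its `endpoint_week` is overridden per
#'   cell.
#' @param weeks Integer vector of endpoint weeks.
#' @param B Bootstrap replicates per week (0 = point estimates only).
#' @param seed Master seed; week i uses `seed + i`.
#' @return A `mediation_scan` tibble (axis `"week"`), one row per week with
#'   effects, `pm_pct`, `n_used` and interval columns when `B > 0`.
#' @export
longitudinal_scan <- function(data, spec, weeks, B = 0L, seed = 1L) {
  data <- as_trial(data)
  weeks <- as.integer(weeks)
  have <- sort(unique(as_tibble(data)$week[!is.na(as_tibble(data)$uacr)]))
  bad <- setdiff(weeks, have)
  if (length(bad) > 0) {
    abort(paste0("Week(s) not in the UACR schedule: ",
                 paste(bad, collapse = ", ")),
          class = "longmediate_config_error")
  }
  cells <- purrr::imap(weeks, function(w, i) {
    spec_w <- spec
    spec_w$endpoint_week <- w
    scan_cell(data, spec_w, label = paste0("week ", w), B = B,
              seed = seed + i, extra = list(week = w))
  }) %>% bind_rows()
  finish_scan(cells, "week", spec)
}

#' Mediation analysis within each level of a subgroup attribute
#'
#' Applies the identical analysis (same spec, same covariates) within every
#' observed level of a patient attribute. Small-cell failures are flagged
#' per level and do not stop the scan; if every level fails the scan
#' errors.
#'
#' @inheritParams longitudinal_scan
#' @param attribute Name of an attribute column with at least two observed
#'   levels (e.g. `"sex"`).
#' @param B Bootstrap replicates per level; level i uses `seed + i`.
#' @return A `mediation_scan` tibble (axis `"subgroup"`), one row per level.
#' @export
subgroup_scan <- function(data, spec, attribute, B = 0L, seed = 1L) {
  data <- as_trial(data)
  if (!attribute %in% attribute_names(data)) {
    abort(paste0("Unknown subgroup attribute '", attribute, "'."),
          class = "longmediate_lookup_error")
  }
  levels <- as_tibble(data) %>%
    distinct(.data$patient_id, .data[[attribute]]) %>%
    pull(.data[[attribute]]) %>% unique() %>% sort()
  if (length(levels) < 2) {
    abort(paste0("Attribute '", attribute, "' has fewer than 2 levels."),
          class = "longmediate_precondition_error")
  }
  cells <- purrr::imap(levels, function(lv, i) {
    scan_cell(subgroup(data, attribute, lv), spec,
              label = paste0(attribute, " = ", lv), B = B, seed = seed + i,
              extra = list(level = as.character(lv)))
  }) %>% bind_rows()
  if (!any(cells$ok)) {
    abort(paste0("Every level of '", attribute, "' failed estimation."),
          class = "longmediate_estimation_error")
  }
  finish_scan(cells, "subgroup", spec)
}

#' Plot a mediation scan
#'
#' For a week-axis scan, the proportion mediated versus endpoint week (with
#' a percentile-interval ribbon when the scan was bootstrapped); for a
#' subgroup scan, per-level point estimates with interval bars.
#'
#' @param object A `mediation_scan`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mediation_scan <- function(object, ...) {
  axis <- attr(object, "axis")
  d <- as_tibble(object) %>% filter(.data$ok)
  has_ci <- "pm_pct_lo" %in% names(d)
  if (axis == "week") {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$week, y = .data$pm_pct))
    if (has_ci) {
      p <- p + ggplot2::geom_ribbon(
        ggplot2::aes(ymin = .data$pm_pct_lo, ymax = .data$pm_pct_hi),
        alpha = 0.2)
    }
    p + ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "Endpoint week",
                    y = "Proportion mediated (%)",
                    title = "Proportion mediated by treatment duration")
  } else {
    p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$label, y = .data$pm_pct))
    if (has_ci) {
      p <- p + ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$pm_pct_lo, ymax = .data$pm_pct_hi),
        width = 0.2)
    }
    p + ggplot2::geom_point() + ggplot2::coord_flip() +
      ggplot2::labs(x = NULL, y = "Proportion mediated (%)",
                    title = "Proportion mediated by subgroup")
  }
}
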