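# Scalar summaries of each patient's longitudinal mediator trajectory.
# Two conventions: the cumulative mean of change from baseline over all
# visits up to the endpoint (cumulative-exposure hypothesis) and the
# achieved change just before the endpoint (acute-effect hypothesis).

MEDIATORS <- c("sbp", "dbp", "map", "egfr")

# per-visit mediator value; MAP is derived from SBP/DBP before differencing
mediator_column <- function(data, mediator) {
  switch(mediator,
    map = data$dbp + (data$sbp - data$dbp) / 3,
    data[[mediator]]
  )
}

check_mediator <- function(mediator) {
  if (!mediator %in% MEDIATORS) {
    abort(paste0("Unknown mediator '", mediator, "'; expected one of ",
                 paste(MEDIATORS, collapse = ", ")),
          class = "longmediate_lookup_error")
  }
  mediator
}

# long tibble of (patient_id, week, change) for one mediator
change_table <- function(data, mediator) {
  check_mediator(mediator)
  d <- as_tibble(data)
  d$value <- mediator_column(d, mediator)
  base <- d %>% filter(.data$week == 0L) %>%
    select(all_of(c("patient_id", "value"))) %>%
    rename(baseline = "value")
  missing_base <- setdiff(unique(d$patient_id),
                          base$patient_id[!is.na(base$baseline)])
  if (length(missing_base) > 0) {
    abort(paste0("Missing baseline ", mediator, " for patient(s): ",
                 paste(head(missing_base, 5), collapse = ", ")),
          class = "longmediate_precondition_error")
  }
  d %>% left_join(base, by = "patient_id") %>%
    mutate(change = .data$value - .data$baseline) %>%
    select(all_of(c("patient_id", "arm", "week", "change")))
}

#' Change from baseline in a mediator at one visit week
#'
#' Subtracts each patient's baseline (week 0) mediator value from the value
#' at `week`. For `mediator = "map"`, mean arterial pressure is computed per
#' visit as DBP + (SBP - DBP)/3 before differencing. A missing visit value
#' yields a missing change; a missing baseline is an error.
#'
#' @param data A [trial_data] tibble.
#' @param mediator One of `"sbp"`, `"dbp"`, `"map"`, `"egfr"`.
#' @param week Integer visit week.
#' @return Tibble with columns `patient_id`, `change` (mediator units).
#' @export
change_from_baseline <- function(data, mediator, week) {
  week <- as.integer(week)
  ct <- change_table(data, mediator)
  ids <- unique(as_tibble(data)$patient_id)
  tibble(patient_id = ids) %>%
    left_join(ct %>% filter(.data$week == .env$week) %>%
                select(all_of(c("patient_id", "change"))),
              by = "patient_id")
}

#' Cumulative-mean change summary of a mediator trajectory
#'
#' Averages the change from baseline over all observed post-baseline visits
#' with week <= `endpoint_week`, skipping missing values (the
#' cumulative-exposure summary). With `time_weighted = TRUE` the unweighted
#' mean is replaced by the time average of the piecewise-linear trajectory
#' through the observed changes (trapezoid rule anchored at zero change at
#' week 0), which down-weights closely spaced early visits.
#'
#' @inheritParams change_from_baseline
#' @param endpoint_week Integer endpoint week; visits after it are ignored.
#' @param time_weighted Use the trapezoid time average instead of the plain
#'   mean of observed changes. Default `FALSE`.
#' @return Tibble with columns `patient_id`, `mediator`, `convention`
#'   (`"cumulative_mean"`), `value`. Patients with no usable post-baseline
#'   measurement get a missing `value` (excluded downstream).
#' @export
cumulative_mean_change <- function(data, mediator, endpoint_week,
                                   time_weighted = FALSE) {
  endpoint_week <- as.integer(endpoint_week)
  ct <- change_table(data, mediator) %>%
    filter(.data$week > 0L, .data$week <= .env$endpoint_week,
           !is.na(.data$change))
  summ <- if (!time_weighted) {
    ct %>% group_by(.data$patient_id) %>%
      summarise(value = mean(.data$change), .groups = "drop")
  } else {
    ct %>% arrange(.data$patient_id, .data$week) %>%
      group_by(.data$patient_id) %>%
      summarise(value = {
        w <- c(0, .data$week); d <- c(0, .data$change)
        sum(diff(w) * (head(d, -1) + tail(d, -1)) / 2) / max(w)
      }, .groups = "drop")
  }
  ids <- unique(as_tibble(data)$patient_id)
  tibble(patient_id = ids, mediator = mediator,
         convention = "cumulative_mean") %>%
    left_join(summ, by = "patient_id")
}

#' Achieved-change summary of a mediator trajectory
#'
#' The change from baseline at the latest visit with a non-missing mediator
#' value strictly before `endpoint_week` (the acute-effect summary,
#' "just before the end of treatment"). When no such visit exists the
#' endpoint-week value itself is used and flagged in the `fallback` column;
#' `at_endpoint = TRUE` switches to always reading the endpoint-week visit.
#'
#' @inheritParams cumulative_mean_change
#' @param at_endpoint Use the endpoint-week measurement itself rather than
#'   the latest one strictly before it. Default `FALSE`.
#' @return Tibble with columns `patient_id`, `mediator`, `convention`
#'   (`"achieved"`), `value`, `week_used`, `fallback`.
#' @export
achieved_change <- function(data, mediator, endpoint_week,
                            at_endpoint = FALSE) {
  endpoint_week <- as.integer(endpoint_week)
  ct <- change_table(data, mediator) %>%
    filter(.data$week > 0L, .data$week <= .env$endpoint_week,
           !is.na(.data$change))
  pick <- function(tbl) {
    before <- tbl %>% filter(.data$week < .env$endpoint_week)
    if (!at_endpoint && nrow(before) > 0) {
      row <- before %>% filter(.data$week == max(.data$week))
      tibble(value = row$change[1], week_used = row$week[1], fallback = FALSE)
    } else {
      at <- tbl %>% filter(.data$week == .env$endpoint_week)
      if (nrow(at) > 0) {
        tibble(value = at$change[1], week_used = at$week[1],
               fallback = !at_endpoint)
      } else {
        tibble(value = NA_real_, week_used = NA_integer_, fallback = NA)
      }
    }
  }
  summ <- ct %>% group_by(.data$patient_id) %>%
    dplyr::group_modify(~ pick(.x)) %>% ungroup()
  ids <- unique(as_tibble(data)$patient_id)
  tibble(patient_id = ids, mediator = mediator, convention = "achieved") %>%
    left_join(summ, by = "patient_id")
}

#' Mediator summaries for a set of mediators under one convention
#'
#' Convenience wrapper computing [cumulative_mean_change()] or
#' [achieved_change()] for each requested mediator and binding the results.
#'
#' @inheritParams cumulative_mean_change
#' @param mediators Character vector of mediator names.
#' @param convention `"cumulative_mean"` or `"achieved"`.
#' @param ... Passed to the underlying summary function (`time_weighted` or
#'   `at_endpoint`).
#' @return Long tibble with one row per patient x mediator.
#' @export
mediator_summaries <- function(data, mediators, convention, endpoint_week,
                               ...) {
  convention <- match.arg(convention, c("cumulative_mean", "achieved"))
  fn <- if (convention == "cumulative_mean") cumulative_mean_change
        else achieved_change
  purrr::map(mediators, function(m) {
    fn(data, m, endpoint_week, ...) %>%
      select(all_of(c("patient_id", "mediator", "convention", "value")))
  }) %>% bind_rows()
}
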