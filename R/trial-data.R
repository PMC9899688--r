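# Patient-level longitudinal trial data: a long tibble with one row per
# patient-visit, carrying treatment arm, clinical measurements and any
# per-patient subgroup attributes, plus a `meta` attribute recording
# provenance and the filters applied so far.

CORE_COLS <- c("patient_id", "arm", "week", "uacr", "sbp", "dbp", "egfr")
MEASURE_COLS <- c("uacr", "sbp", "dbp", "egfr")

#' Construct a validated trial dataset
#'
#' Wraps a long-format data frame (one row per patient-visit) as a
#' `trial_data` tibble after validating its structural invariants. Columns
#' beyond the core set (`patient_id`, `arm`, `week`, `uacr`, `sbp`, `dbp`,
#' `egfr`) are treated as per-patient subgroup attributes (for example `sex`
#' or `bmi_class`) and must be constant within a patient.
#'
#' Validation enforces: unique (patient, week) pairs, integer weeks >= 0,
#' strictly positive UACR where present (its log transform must exist),
#' finite measurement values, and a treatment arm constant within patient and
#' coded 0 (control) / 1 (active).
#'
#' @param data A data frame with the long-format columns described above.
#' @param meta Optional named list of provenance facts (source file,
#'   generator seed, filters). Stored as the `meta` attribute and carried
#'   through the pipeline.
#' @return A `trial_data` tibble (rows sorted by patient then week).
#' @export
trial_data <- function(data, meta = list()) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(CORE_COLS, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Malformed trial table: missing column(s) ",
             paste(missing_cols, collapse = ", ")),
      class = "longmediate_format_error"
    )
  }
  data <- as_tibble(data)
  data$patient_id <- as.character(data$patient_id)
  data$week <- as.integer(data$week)
  data$arm <- as.integer(data$arm)
  for (m in MEASURE_COLS) data[[m]] <- as.numeric(data[[m]])

  if (anyNA(data$week) || any(data$week < 0)) {
    abort("Visit weeks must be non-negative integers.",
          class = "longmediate_validation_error")
  }
  dup <- data %>% dplyr::count(.data$patient_id, .data$week) %>% filter(n > 1)
  if (nrow(dup) > 0) {
    abort(
      paste0("Duplicate (patient, week) visit(s): ",
             paste0(dup$patient_id, "@w", dup$week, collapse = ", ")),
      class = "longmediate_validation_error"
    )
  }
  bad_uacr <- data %>% filter(!is.na(.data$uacr) & .data$uacr <= 0)
  if (nrow(bad_uacr) > 0) {
    abort(
      paste0("Nonpositive UACR (log undefined) for ",
             paste0(bad_uacr$patient_id, " at week ", bad_uacr$week,
                    collapse = "; ")),
      class = "longmediate_validation_error"
    )
  }
  for (m in MEASURE_COLS) {
    if (any(!is.finite(data[[m]]) & !is.na(data[[m]]))) {
      abort(paste0("Non-finite values in column ", m),
            class = "longmediate_validation_error")
    }
  }
  if (anyNA(data$arm) || !all(data$arm %in% c(0L, 1L))) {
    abort("Treatment arm must be coded 0 (control) or 1 (active).",
          class = "longmediate_validation_error")
  }
  arm_chk <- data %>%
    distinct(.data$patient_id, .data$arm) %>%
    dplyr::count(.data$patient_id) %>%
    filter(n > 1)
  if (nrow(arm_chk) > 0) {
    abort(paste0("Treatment arm varies within patient(s): ",
                 paste(arm_chk$patient_id, collapse = ", ")),
          class = "longmediate_validation_error")
  }
  attr_cols <- setdiff(names(data), CORE_COLS)
  for (a in attr_cols) {
    chk <- data %>%
      distinct(.data$patient_id, .data[[a]]) %>%
      dplyr::count(.data$patient_id) %>%
      filter(n > 1)
    if (nrow(chk) > 0) {
      abort(paste0("Attribute '", a, "' varies within patient(s): ",
                   paste(chk$patient_id, collapse = ", ")),
            class = "longmediate_validation_error")
    }
  }
  data <- data %>% arrange(.data$patient_id, .data$week)
  structure(data, meta = meta,
            class = c("trial_data", class(as_tibble(data))))
}

#' @export
print.trial_data <- function(x, ...) {
  cat(sprintf("<trial_data> %d patients, %d visit rows, arms: %s\n",
              dplyr::n_distinct(x$patient_id), nrow(x),
              paste0("n", sort(unique(x$arm)), "=",
                     table(x$arm[!duplicated(x$patient_id)])[
                       as.character(sort(unique(x$arm)))],
                     collapse = ", ")))
  filters <- attr(x, "meta")$filters
  if (length(filters)) cat("filters:", paste(filters, collapse = " | "), "\n")
  NextMethod()
}

trial_meta <- function(data) attr(data, "meta") %||% list()

append_filter <- function(data, label) {
  meta <- trial_meta(data)
  meta$filters <- c(meta$filters, label)
  attr(data, "meta") <- meta
  data
}

#' Names of the subgroup attribute columns in a trial dataset
#' @param data A `trial_data` tibble (or compatible data frame).
#' @return Character vector of attribute column names (possibly empty).
#' @export
attribute_names <- function(data) setdiff(names(data), CORE_COLS)

#' Read a patient-level trial table from CSV
#'
#' Reads UTF-8 CSV with a header. Empty cells and `"."` are treated as
#' missing (never as zeros). The long layout has one row per patient-visit
#' with columns `patient_id, arm, week, uacr, sbp, dbp, egfr` plus optional
#' attribute columns. The wide layout has one row per patient with
#' per-week measurement columns named `<measure>_w<week>` (e.g. `uacr_w0`,
#' `sbp_w12`).
#'
#' Units are documented, not converted: UACR in mg/g creatinine, SBP/DBP in
#' mmHg, eGFR in mL/min/1.73 m^2; weeks since randomization.
#'
#' @param path Path to the CSV file.
#' @param layout `"long"` (default) or `"wide"`.
#' @return A validated [trial_data] tibble; `meta$source` records the path.
#' @export
read_trial_table <- function(path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  raw <- readr::read_csv(path, na = c("", ".", "NA"), show_col_types = FALSE,
                         progress = FALSE)
  if (layout == "wide") {
    wide_meas <- grep("^(uacr|sbp|dbp|egfr)_w[0-9]+$", names(raw), value = TRUE)
    if (length(wide_meas) == 0) {
      abort("Malformed trial table: no <measure>_w<week> columns found.",
            class = "longmediate_format_error")
    }
    raw <- raw %>%
      tidyr::pivot_longer(all_of(wide_meas),
                          names_to = c("measure", "week"),
                          names_pattern = "^(uacr|sbp|dbp|egfr)_w([0-9]+)$",
                          values_to = "value") %>%
      mutate(week = as.integer(.data$week)) %>%
      tidyr::pivot_wider(names_from = "measure", values_from = "value")
    for (m in setdiff(MEASURE_COLS, names(raw))) raw[[m]] <- NA_real_
    # visits where every measurement is absent are padding from the wide grid
    raw <- raw %>% filter(!dplyr::if_all(all_of(MEASURE_COLS), is.na) |
                            .data$week == 0L)
  }
  trial_data(raw, meta = list(source = path, layout = layout))
}

#' Write a trial dataset to CSV
#'
#' Inverse of [read_trial_table()]: round-tripping a dataset through
#' `write_trial_table()` and `read_trial_table()` reproduces it field by
#' field (missing values written as empty cells).
#'
#' @param data A [trial_data] tibble.
#' @param path Output CSV path.
#' @param layout `"long"` (default) or `"wide"`.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(data, path, layout = c("long", "wide")) {
  layout <- match.arg(layout)
  out <- as_tibble(data)
  if (layout == "wide") {
    attrs <- attribute_names(data)
    out <- out %>%
      tidyr::pivot_longer(all_of(MEASURE_COLS), names_to = "measure",
                          values_to = "value") %>%
      mutate(col = paste0(.data$measure, "_w", .data$week)) %>%
      select(-all_of(c("measure", "week"))) %>%
      tidyr::pivot_wider(names_from = "col", values_from = "value")
    lead <- c("patient_id", "arm", attrs)
    out <- out %>% select(all_of(lead), dplyr::everything())
  }
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Restrict to the complete-case analysis set for an endpoint week
#'
#' Keeps patients with non-missing baseline (week 0) UACR, SBP and eGFR and
#' a non-missing UACR at the endpoint week: the per-timepoint complete-case
#' rule used when the analysis endpoint moves along the visit schedule. No
#' imputation is performed. The applied filter is recorded in `meta$filters`,
#' which makes the operation idempotent.
#'
#' @param data A [trial_data] tibble.
#' @param endpoint_week Integer week of the analysis endpoint.
#' @return The filtered [trial_data] tibble.
#' @export
analysis_set <- function(data, endpoint_week) {
  data <- as_trial(data)
  endpoint_week <- as.integer(endpoint_week)
  base_ok <- as_tibble(data) %>%
    filter(.data$week == 0L, !is.na(.data$uacr), !is.na(.data$sbp),
           !is.na(.data$egfr)) %>%
    pull(.data$patient_id)
  end_ok <- as_tibble(data) %>%
    filter(.data$week == endpoint_week, !is.na(.data$uacr)) %>%
    pull(.data$patient_id)
  keep <- intersect(base_ok, end_ok)
  out <- as_tibble(data) %>% filter(.data$patient_id %in% keep)
  out <- trial_data(out, meta = trial_meta(data))
  out <- append_filter(out, paste0("analysis_set(week=", endpoint_week, ")"))
  arms <- unique(out$arm)
  if (!all(c(0L, 1L) %in% arms)) {
    abort(
      paste0("Analysis set for week ", endpoint_week,
             " leaves an empty treatment arm; estimation impossible."),
      class = "longmediate_estimation_error"
    )
  }
  out
}

#' Restrict a trial dataset to one subgroup level
#'
#' Keeps the patients whose attribute column equals `level`. An empty result
#' is allowed (downstream estimation raises); an unknown attribute is an
#' error.
#'
#' @param data A [trial_data] tibble.
#' @param attribute Name of an attribute column (e.g. `"sex"`).
#' @param level The level to keep.
#' @return The filtered [trial_data] tibble.
#' @export
subgroup <- function(data, attribute, level) {
  data <- as_trial(data)
  if (!attribute %in% attribute_names(data)) {
    abort(paste0("Unknown subgroup attribute '", attribute, "'. Available: ",
                 paste(attribute_names(data), collapse = ", ")),
          class = "longmediate_lookup_error")
  }
  out <- as_tibble(data) %>% filter(.data[[attribute]] == level)
  out <- structure(out, meta = trial_meta(data),
                   class = c("trial_data", class(as_tibble(out))))
  append_filter(out, paste0("subgroup(", attribute, "=", level, ")"))
}

as_trial <- function(data) {
  if (inherits(data, "trial_data")) data else trial_data(data)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
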