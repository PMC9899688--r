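# Percentile bootstrap for the mediation decomposition: whole patients are
# resampled with replacement (arms pooled by default), both regression
# models are refit on every resample, and intervals are empirical
# percentiles of the replicate estimates. The proportion-mediated interval
# comes from the replicate pm draws themselves, so effect and pm intervals
# are consistent replicate by replicate.

#' Percentile-bootstrap confidence intervals for a mediation analysis
#'
#' Resamples patients with replacement `B` times (default 1000), re-runs
#' the full decomposition on each resample, and returns percentile
#' intervals. Resampling operates on the one-row-per-patient analysis
#' frame, which is equivalent to resampling patients from the dataset since
#' every derived quantity is per-patient. Degenerate resamples (a missing
#' arm or a rank-deficient design) are redrawn and counted in `n_failed`;
#' the retry budget is `10 * B` redraws, after which an inference error
#' reports the failure rate. Percentiles use linear interpolation between
#' order statistics (`stats::quantile` type 7), so intervals are
#' bit-reproducible for a fixed seed.
#'
#' @param data A [trial_data] tibble, or a `mediation_fit` from
#'   [estimate_mediation()] (its frame is reused).
#' @param spec A [mediation_spec()]; ignored when `data` is a fit.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed for the resampling stream.
#' @param stratify Resample within treatment arms instead of pooled
#'   (default `FALSE`, the plain patient bootstrap).
#' @param level Nominal confidence level (default 0.95).
#' @return A `mediation_boot` object: `draws` (tibble of replicate
#'   `te_log`, `nde_log`, `nie_log`, `pm_pct`), `intervals` (tibble of
#'   per-quantity lower/upper percentiles, including the ratio-scale
#'   effects), `n_failed`, and the point-estimate `fit`.
#' @export
bootstrap_mediation <- function(data, spec = NULL, B = 1000L, seed = NULL,
                                stratify = FALSE, level = 0.95) {
  fit <- if (inherits(data, "mediation_fit")) data
         else estimate_mediation(data, spec)
  spec <- fit$spec
  mats <- frame_matrices(fit$frame, spec)
  n <- length(mats$y)
  B <- as.integer(B)
  stopifnot(B >= 1, level > 0, level < 1)
  if (!is.null(seed)) set.seed(seed)
  arm_idx <- list(which(mats$arm == 0), which(mats$arm == 1))

  draw_index <- function() {
    if (stratify) {
      c(sample(arm_idx[[1]], length(arm_idx[[1]]), replace = TRUE),
        sample(arm_idx[[2]], length(arm_idx[[2]]), replace = TRUE))
    } else {
      sample.int(n, n, replace = TRUE)
    }
  }

  draws <- matrix(NA_real_, nrow = B, ncol = 4,
                  dimnames = list(NULL, c("te_log", "nde_log", "nie_log",
                                          "pm_pct")))
  n_failed <- 0L
  budget <- 10L * B
  for (b in seq_len(B)) {
    repeat {
      idx <- draw_index()
      res <- tryCatch(
        fit_mediation_frame(mats$arm[idx], mats$y[idx],
                            mats$M[idx, , drop = FALSE],
                            mats$C[idx, , drop = FALSE],
                            spec$contrast, spec$interaction),
        longmediate_estimation_error = function(e) NULL
      )
      if (!is.null(res)) break
      n_failed <- n_failed + 1L
      if (n_failed > budget) {
        abort(sprintf(
          "Bootstrap retry budget exhausted: %d degenerate resamples over %d replicates (failure rate %.1f%%).",
          n_failed, b, 100 * n_failed / (n_failed + b)),
          class = "longmediate_inference_error")
      }
    }
    draws[b, ] <- c(res$te_log, res$nde_log, res$nie_log, res$pm_pct)
  }

  draws <- as_tibble(draws)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  log_q <- c("te_log", "nde_log", "nie_log", "pm_pct")
  ints <- purrr::map(log_q, function(q) {
    qs <- quantile(draws[[q]], probs, type = 7, names = FALSE, na.rm = TRUE)
    tibble(quantity = q, lower = qs[1], upper = qs[2])
  }) %>% bind_rows()
  ratio_ints <- ints %>%
    filter(.data$quantity != "pm_pct") %>%
    mutate(quantity = sub("_log$", "_ratio", .data$quantity),
           lower = exp(.data$lower), upper = exp(.data$upper))
  ints <- bind_rows(ints, ratio_ints) %>% mutate(level = level)

  structure(list(draws = draws, intervals = ints, n_replicates = B,
                 seed = seed, n_failed = n_failed, stratified = stratify,
                 level = level, fit = fit),
            class = "mediation_boot")
}

#' @export
print.mediation_boot <- function(x, ...) {
  cat(sprintf(
    "<mediation_boot> B = %d (%s), level = %.2f, degenerate redraws = %d\n",
    x$n_replicates, if (x$stratified) "arm-stratified" else "pooled",
    x$level, x$n_failed))
  print(boot_intervals(x))
  invisible(x)
}

#' Percentile intervals from a bootstrap run
#'
#' Recomputes intervals from the stored replicate draws at any nominal
#' level (endpoints are monotone in the level).
#'
#' @param boot A `mediation_boot`.
#' @param level Nominal level; default the level used at run time.
#' @return Tibble with `quantity`, `lower`, `upper`, `level`.
#' @export
boot_intervals <- function(boot, level = NULL) {
  stopifnot(inherits(boot, "mediation_boot"))
  level <- level %||% boot$level
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  base <- purrr::map(names(boot$draws), function(q) {
    qs <- quantile(boot$draws[[q]], probs, type = 7, names = FALSE,
                   na.rm = TRUE)
    tibble(quantity = q, lower = qs[1], upper = qs[2])
  }) %>% bind_rows()
  ratio <- base %>% filter(.data$quantity != "pm_pct") %>%
    mutate(quantity = sub("_log$", "_ratio", .data$quantity),
           lower = exp(.data$lower), upper = exp(.data$upper))
  bind_rows(base, ratio) %>% mutate(level = level)
}
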