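#' Tidy a group-comparison object
#'
#' One row per statistic, in the broom long format.
#'
#' @param x An `ith_assoc` from [compare_groups()].
#' @param ... Unused.
#' @return A tibble with `statistic`, `group`, `estimate`, `p_value`.
#' @export
tidy.ith_assoc <- function(x, ...) {
  bind_rows(
    tibble(statistic = "dcb_rate", group = x$levels,
           estimate = x$dcb_rate, p_value = x$dcb_p),
    tibble(statistic = "orr_rate", group = x$levels,
           estimate = x$orr_rate, p_value = x$orr_p),
    tibble(statistic = "median_pfs", group = x$levels,
           estimate = x$median_pfs, p_value = x$logrank_p),
    tibble(statistic = "hazard_ratio", group = paste(x$levels[2], "vs", x$levels[1]),
           estimate = x$cox$hr, p_value = x$cox$p_value)
  )
}

#' @rdname tidy.ith_assoc
#' @export
glance.ith_assoc <- function(x, ...) {
  tibble(
    group = x$group,
    n = sum(x$n),
    dcb_p = x$dcb_p,
    orr_p = x$orr_p,
    logrank_p = x$logrank_p,
    hr = x$cox$hr,
    hr_ci_low = x$cox$ci_low,
    hr_ci_high = x$cox$ci_high
  )
}

#' Tidy a pipeline report
#'
#' @param x An `ith_report` from [run_pipeline()].
#' @param ... Unused.
#' @return The per-patient biomarker tibble.
#' @export
tidy.ith_report <- function(x, ...) {
  as_tibble(x$patients)
}

#' @rdname tidy.ith_report
#' @export
glance.ith_report <- function(x, ...) {
  a <- x$associations
  tibble(
    n_patients = x$n_patients,
    n_evaluable = x$n_evaluable,
    tmb_cutoff = x$tmb_cutoff,
    ith_dcb_p = a$ith$dcb_p,
    ith_logrank_p = a$ith$logrank_p,
    ith_hr = a$ith$cox$hr,
    tmb_hr = a$tmb$cox$hr,
    interaction_p = a$interaction_p,
    ith_tmb_spearman_p = a$ith_tmb_spearman$p_value
  )
}
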