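#' Clonal architecture plot
#'
#' Stacked per-patient bars of clonal and subclonal mutation counts
#' (top) and proportions (bottom), patients ordered by increasing ITH.
#'
#' @param object An `ith_result` from [compute_ith()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ith_result <- function(object, ...) {
  df <- as_tibble(object) %>%
    filter(.data$evaluable) %>%
    arrange(.data$ith) %>%
    mutate(patient_id = factor(.data$patient_id, levels = .data$patient_id)) %>%
    tidyr::pivot_longer(c("n_clonal", "n_subclonal"),
                        names_to = "class", values_to = "count") %>%
    mutate(class = if_else(.data$class == "n_clonal", "clonal", "subclonal"))
  counts <- df %>% mutate(panel = "mutation count", value = .data$count)
  props <- df %>%
    group_by(.data$patient_id) %>%
    mutate(panel = "proportion", value = .data$count / sum(.data$count)) %>%
    ungroup()
  ggplot2::ggplot(bind_rows(counts, props),
                  ggplot2::aes(x = .data$patient_id, y = .data$value,
                               fill = .data$class)) +
    ggplot2::geom_col(width = 0.85) +
    ggplot2::facet_grid(panel ~ ., scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(clonal = "#3F3F8F",
                                          subclonal = "#3F8F5F")) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

km_curve_tbl <- function(times, events, group) {
  fit <- survival::survfit(
    survival::Surv(times, as.integer(events)) ~ group
  )
  strata <- rep(names(fit$strata), fit$strata)
  tibble(
    time = fit$time, surv = fit$surv,
    group = sub("^group=", "", strata)
  ) %>%
    group_by(.data$group) %>%
    group_modify(~ bind_rows(tibble(time = 0, surv = 1), .x)) %>%
    ungroup()
}

#' Kaplan-Meier plot for a group comparison
#'
#' @param object An `ith_assoc` from [compare_groups()].
#' @param ... Unused.
#' @return A ggplot object with one survival curve per group and the
#'   log-rank p-value in the caption.
#' @export
autoplot.ith_assoc <- function(object, ...) {
  d <- object$data
  km <- km_curve_tbl(d$pfs_days, d$pfs_event, d[[object$group]])
  ggplot2::ggplot(km, ggplot2::aes(x = .data$time, y = .data$surv,
                                   colour = .data$group)) +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Days", y = "Progression-free survival", colour = NULL,
      caption = sprintf("log-rank p = %.2g; HR %.2f [%.2f-%.2f]",
                        object$logrank_p, object$cox$hr,
                        object$cox$ci_low, object$cox$ci_high)
    ) +
    ggplot2::theme_minimal()
}
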