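#' Fisher's exact test on a 2x2 table
#'
#' Two-sided p-value by the probability-mass definition: the sum of
#' hypergeometric probabilities, at fixed margins, of every table whose
#' probability does not exceed that of the observed table (the
#' convention of [stats::fisher.test()], which performs the
#' computation). The reported odds ratio is by default the sample odds
#' ratio `ad/bc`; the conditional maximum-likelihood estimate is
#' available via `or = "conditional"`.
#'
#' @param tab A 2x2 matrix of counts `rbind(c(a, b), c(c, d))` with rows
#'   = group and columns = outcome yes/no.
#' @param or `"sample"` (default) or `"conditional"`.
#' @return Tibble with `odds_ratio` and `p_value`.
#' @export
fisher_exact <- function(tab, or = c("sample", "conditional")) {
  or <- match.arg(or)
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) abort("fisher_exact needs a 2x2 table")
  if (any(tab < 0) || any(tab != floor(tab))) {
    abort("Table entries must be non-negative integers")
  }
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    warn("Zero margin: the exact test is degenerate, p = 1")
    return(tibble(odds_ratio = NA_real_, p_value = 1))
  }
  ft <- fisher.test(tab)
  odds <- if (or == "sample") {
    (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  } else {
    unname(ft$estimate)
  }
  tibble(odds_ratio = odds, p_value = ft$p.value)
}

#' Kaplan-Meier median survival
#'
#' Product-limit estimate of median survival: the smallest observed time
#' at which the estimated survival function drops to 0.5 or below.
#' `NA` when the curve never reaches 0.5.
#'
#' @param times Positive follow-up times.
#' @param events Logical/0-1 event indicators (1 = event observed).
#' @return The median time, or `NA_real_` if undefined.
#' @export
km_median <- function(times, events) {
  if (length(times) == 0) abort("Empty group: no survival times")
  if (any(times <= 0)) abort("Survival times must be > 0")
  fit <- survival::survfit(survival::Surv(times, as.integer(events)) ~ 1)
  med <- unname(summary(fit)$table["median"])
  if (is.na(med)) NA_real_ else as.numeric(med)
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square on the pooled risk sets, with the
#' p-value from a chi-square distribution on 1 degree of freedom. With
#' no between-group difference in the risk sets the statistic is 0 and
#' p = 1.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators.
#' @param groups Two-level grouping vector.
#' @return The two-sided p-value.
#' @export
logrank <- function(times, events, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) != 2) {
    abort("logrank needs exactly two non-empty groups")
  }
  if (sum(events) < 1) abort("logrank needs at least one event")
  sd <- survival::survdiff(survival::Surv(times, as.integer(events)) ~ groups)
  as.numeric(pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Univariable Cox hazard ratio
#'
#' Cox proportional-hazards partial-likelihood fit of a single binary
#' indicator with Efron handling of tied event times. The 95% CI is the
#' Wald interval `exp(beta +/- 1.96 * se)`. The hazard ratio is reported
#' for indicator level `TRUE`/second factor level relative to the
#' reference, so code the unfavorable group as `TRUE` to obtain HR > 1.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators.
#' @param indicator Binary group indicator (logical, 0/1 or two-level
#'   factor).
#' @param conf_level Wald interval level (default 0.95).
#' @return Tibble with `hr`, `ci_low`, `ci_high`, `p_value`, `n_events`.
#' @export
cox_hr <- function(times, events, indicator, conf_level = 0.95) {
  if (is.factor(indicator) || is.character(indicator)) {
    indicator <- as.integer(as.factor(indicator)) - 1L
  }
  indicator <- as.numeric(indicator)
  if (length(unique(indicator)) < 2) {
    abort("Indicator is constant; no hazard ratio is identifiable")
  }
  ev_per_level <- tapply(as.integer(events), indicator, sum)
  if (any(ev_per_level < 5)) {
    warn("Fewer than 5 events in a group; the Wald CI may be unreliable")
  }
  fit <- survival::coxph(
    survival::Surv(times, as.integer(events)) ~ indicator,
    ties = "efron"
  )
  beta <- unname(coef(fit))
  se <- sqrt(unname(fit$var[1, 1]))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  tibble(
    hr = exp(beta),
    ci_low = exp(beta - z * se),
    ci_high = exp(beta + z * se),
    p_value = as.numeric(pchisq((beta / se)^2, 1, lower.tail = FALSE)),
    n_events = sum(as.integer(events))
  )
}

#' Wald p-value for a TMB-by-ITH interaction
#'
#' Cox fit with both group main effects and their product; returns the
#' Wald p-value of the product coefficient. A small interaction p would
#' indicate the ITH effect differs between TMB strata; a large one that
#' ITH acts as an independent predictor.
#'
#' @param times Positive follow-up times.
#' @param events Event indicators.
#' @param tmb_group,ith_group Two-level group vectors.
#' @return The Wald p-value of the interaction term.
#' @export
interaction_p <- function(times, events, tmb_group, ith_group) {
  t2 <- as.integer(as.factor(tmb_group)) - 1L
  i2 <- as.integer(as.factor(ith_group)) - 1L
  if (length(unique(t2)) < 2 || length(unique(i2)) < 2) {
    abort("Both groups must vary to fit an interaction")
  }
  if (length(unique(t2 * i2)) < 2 || all(t2 == i2) || all(t2 == 1 - i2)) {
    abort("Groups are collinear; the interaction is not identifiable")
  }
  fit <- survival::coxph(
    survival::Surv(times, as.integer(events)) ~ t2 * i2,
    ties = "efron"
  )
  beta <- coef(fit)["t2:i2"]
  se <- sqrt(diag(fit$var))[3]
  as.numeric(pchisq((beta / se)^2, 1, lower.tail = FALSE))
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties. The p-value is exact
#' (permutation distribution) for n <= 9 without ties and otherwise uses
#' the t approximation.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Tibble with `rho` and `p_value` (`rho = NA` for a constant
#'   input, with a warning).
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("Need at least 3 pairs")
  if (length(unique(x)) == 1 || length(unique(y)) == 1) {
    warn("Constant vector: Spearman rho is undefined")
    return(tibble(rho = NA_real_, p_value = NA_real_))
  }
  ties <- anyDuplicated(x) > 0 || anyDuplicated(y) > 0
  ct <- suppressWarnings(
    cor.test(x, y, method = "spearman", exact = length(x) <= 9 && !ties)
  )
  tibble(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Response and survival comparison between two biomarker groups
#'
#' Runs the full association layer for one dichotomized biomarker:
#' Fisher exact tests of DCB and objective-response rates, Kaplan-Meier
#' median PFS per group, the log-rank test and the Cox hazard ratio of
#' the unfavorable group relative to the favorable one.
#'
#' @param data Tibble with one row per patient containing the group
#'   column plus `dcb`, `orr`, `pfs_days`, `pfs_event`.
#' @param group Name of the two-level group column (string). The FIRST
#'   factor level is treated as the favorable group; the hazard ratio is
#'   for the second level relative to it.
#' @return An object of class `ith_assoc`; see [tidy.ith_assoc()].
#' @export
compare_groups <- function(data, group) {
  data <- as_tibble(data)
  g <- as.factor(data[[group]])
  g <- droplevels(g)
  if (nlevels(g) != 2) abort(sprintf("Column '%s' must have two levels", group))
  lev <- levels(g)
  rate <- function(flag) {
    tab <- rbind(
      c(sum(flag[g == lev[1]]), sum(!flag[g == lev[1]])),
      c(sum(flag[g == lev[2]]), sum(!flag[g == lev[2]]))
    )
    ft <- fisher_exact(tab)
    list(
      rate = c(mean(flag[g == lev[1]]), mean(flag[g == lev[2]])),
      n = as.vector(table(g)),
      or = ft$odds_ratio, p = ft$p_value
    )
  }
  dcb <- rate(as.logical(data$dcb))
  orr <- rate(as.logical(data$orr))
  med <- vapply(lev, function(l) {
    km_median(data$pfs_days[g == l], data$pfs_event[g == l])
  }, numeric(1))
  lr_p <- logrank(data$pfs_days, data$pfs_event, g)
  cox <- cox_hr(data$pfs_days, data$pfs_event, as.integer(g) - 1L)
  structure(
    list(
      group = group, levels = lev, n = dcb$n,
      dcb_rate = dcb$rate, dcb_or = dcb$or, dcb_p = dcb$p,
      orr_rate = orr$rate, orr_or = orr$or, orr_p = orr$p,
      median_pfs = med, logrank_p = lr_p, cox = cox,
      data = data[, c(group, "dcb", "orr", "pfs_days", "pfs_event")]
    ),
    class = "ith_assoc"
  )
}

#' @export
print.ith_assoc <- function(x, ...) {
  cat(sprintf("Group comparison by %s (%s vs %s; n = %d vs %d)\n",
              x$group, x$levels[1], x$levels[2], x$n[1], x$n[2]))
  cat(sprintf("  DCB rate: %.1f%% vs %.1f%% (Fisher p = %.3g)\n",
              100 * x$dcb_rate[1], 100 * x$dcb_rate[2], x$dcb_p))
  cat(sprintf("  ORR:      %.1f%% vs %.1f%% (Fisher p = %.3g)\n",
              100 * x$orr_rate[1], 100 * x$orr_rate[2], x$orr_p))
  cat(sprintf("  mPFS:     %s vs %s days (log-rank p = %.3g)\n",
              format(x$median_pfs[1]), format(x$median_pfs[2]), x$logrank_p))
  cat(sprintf("  HR (%s vs %s): %.2f [95%% CI %.2f-%.2f]\n",
              x$levels[2], x$levels[1], x$cox$hr, x$cox$ci_low, x$cox$ci_high))
  invisible(x)
}
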