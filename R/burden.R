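#' Tumor mutational burden
#'
#' Count of nonsynonymous variants (missense, nonsense, frameshift,
#' splice, inframe indel) per megabase of sequenced exome. The exome
#' footprint has no default: it depends on capture kit and coverage
#' filters, and a guessed value would silently rescale every TMB.
#'
#' @param variants Variant tibble with `sample_id` and `effect`.
#' @param exome_mb Sequenced exome footprint in megabases (> 0).
#' @return Tibble with `patient_id`, `n_nonsyn`, `tmb` (mutations/Mb).
#' @export
compute_tmb <- function(variants, exome_mb) {
  if (missing(exome_mb) || is.null(exome_mb)) {
    abort("exome_mb must be supplied; there is no default exome footprint")
  }
  if (!is.numeric(exome_mb) || exome_mb <= 0) abort("exome_mb must be > 0")
  as_tibble(variants) %>%
    group_by(patient_id = .data$sample_id) %>%
    summarise(
      n_nonsyn = sum(.data$effect %in% nonsynonymous_effects),
      .groups = "drop"
    ) %>%
    mutate(tmb = .data$n_nonsyn / exome_mb)
}

#' Top-fraction cutoff by nearest rank
#'
#' The cutoff dichotomizing a biomarker at its top `top_fraction` is the
#' `ceil(n * top_fraction)`-th largest value; values `>= cutoff` are
#' "high". With no ties at the cutoff exactly `ceil(n * top_fraction)`
#' observations are high. The nearest-rank (inclusive) convention is
#' used because interpolated quantile definitions differ across
#' software.
#'
#' @param values Numeric vector, length >= 3.
#' @param top_fraction Fraction of observations to call high, in (0, 1).
#' @return The cutoff value.
#' @export
quantile_cutoff <- function(values, top_fraction) {
  values <- values[!is.na(values)]
  if (length(values) < 3) abort("Need at least 3 values for a quantile cutoff")
  if (top_fraction <= 0 || top_fraction >= 1) {
    abort("top_fraction must lie in (0, 1)")
  }
  if (length(unique(values)) == 1) {
    warn("All values identical; the high/low split is degenerate")
  }
  k <- ceiling(length(values) * top_fraction)
  sort(values, decreasing = TRUE)[k]
}

#' Assign ITH, TMB and combined strata
#'
#' Dichotomizes each biomarker and assigns the three combined strata
#' used for joint stratification: TMB-H (regardless of ITH), TMB-L&ITH-L
#' and TMB-L&ITH-H. Boundary ties: `ith <= ith_cutoff` is ITH-L and
#' `tmb >= tmb_cutoff` is TMB-H, so a patient sitting exactly at the TMB
#' cutoff that defines the high group is high. Patients with
#' non-evaluable ITH keep their `tmb_group` but get `NA` ITH-dependent
#' groups.
#'
#' @param biomarkers Tibble with `patient_id`, `ith` and `tmb` columns
#'   (e.g. [compute_ith()] joined to [compute_tmb()]).
#' @param ith_cutoff ITH dichotomization point (default 0.45).
#' @param tmb_cutoff TMB dichotomization point, e.g. from
#'   [quantile_cutoff()]; no default, scale depends on the cohort.
#' @return `biomarkers` with `ith_group`, `tmb_group`, `combo_group`
#'   factor columns.
#' @export
assign_groups <- function(biomarkers, ith_cutoff = 0.45, tmb_cutoff) {
  if (missing(tmb_cutoff)) abort("tmb_cutoff must be supplied")
  out <- as_tibble(biomarkers) %>%
    mutate(
      ith_group = factor(
        if_else(.data$ith <= ith_cutoff, "ITH-L", "ITH-H"),
        levels = c("ITH-L", "ITH-H")
      ),
      tmb_group = factor(
        if_else(.data$tmb >= tmb_cutoff, "TMB-H", "TMB-L"),
        levels = c("TMB-L", "TMB-H")
      ),
      combo_group = factor(
        case_when(
          .data$tmb_group == "TMB-H" ~ "TMB-H",
          is.na(.data$ith_group) ~ NA_character_,
          .data$ith_group == "ITH-L" ~ "TMB-L&ITH-L",
          TRUE ~ "TMB-L&ITH-H"
        ),
        levels = c("TMB-H", "TMB-L&ITH-L", "TMB-L&ITH-H")
      )
    )
  out
}
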