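#' Estimate mutation multiplicity
#'
#' Number of mutated copies per tumor cell, recovered by inverting the
#' expected-VAF relation for a clonal mutation:
#' `m = round(vaf / purity * (purity * total_cn + (1 - purity) * 2))`,
#' clamped to `[1, max(major_cn, 1)]`. Vectorised over all arguments.
#'
#' @param vaf Observed variant allele frequencies in `[0, 1]`.
#' @param purity Tumor purity in `(0, 1]`.
#' @param total_cn Total copy number at the locus (>= 1).
#' @param major_cn Major-allele copy number (upper clamp for `m`).
#' @return Integer multiplicities.
#' @export
estimate_multiplicity <- function(vaf, purity, total_cn, major_cn) {
  if (any(purity <= 0 | purity > 1)) abort("purity must lie in (0, 1]")
  if (any(total_cn < 1)) abort("total_cn must be >= 1")
  m <- round(vaf / purity * (purity * total_cn + (1 - purity) * 2))
  pmin(pmax(as.integer(m), 1L), pmax(as.integer(major_cn), 1L))
}

# Clopper-Pearson (exact beta) binomial interval; vectorised
clopper_pearson <- function(k, n, conf_level = 0.95) {
  alpha <- 1 - conf_level
  low <- ifelse(k == 0, 0, qbeta(alpha / 2, k, n - k + 1))
  high <- ifelse(k == n, 1, qbeta(1 - alpha / 2, k + 1, n - k))
  list(low = low, high = high)
}

#' Estimate per-mutation cancer cell fractions
#'
#' For each variant, the cancer cell fraction (CCF) is the observed VAF
#' corrected for tumor purity, local total copy number and mutation
#' multiplicity:
#' `ccf = vaf * (purity * total_cn + (1 - purity) * 2) / (purity * m)`.
#' The 95% credible interval is the Clopper-Pearson interval of the
#' binomial proportion `alt_count / (ref_count + alt_count)` pushed
#' through the same linear map. Point estimate and bounds are clamped to
#' `[0, 1]` for reporting; the pre-clamp point estimate is kept in
#' `ccf_raw`.
#'
#' @param variants Variant tibble (see [read_maf()]); rows with missing
#'   or zero total read counts are dropped with a warning.
#' @param purity Either a single purity in `(0, 1]` applied to all
#'   samples, or a tibble with `patient_id` (or `sample_id`) and
#'   `purity` columns.
#' @param segments Optional validated copy-number segments; variants not
#'   covered fall back to the diploid default (see [lookup_cn()]).
#' @param conf_level Credible-interval level (default 0.95).
#' @param multiplicity Optional integer vector overriding
#'   [estimate_multiplicity()].
#' @return The variant tibble with `vaf`, `multiplicity`, `ccf_raw`,
#'   `ccf`, `ccf_low`, `ccf_high` columns.
#' @export
estimate_ccf <- function(variants, purity, segments = NULL,
                         conf_level = 0.95, multiplicity = NULL) {
  variants <- lookup_cn(variants, segments)
  usable <- !is.na(variants$ref_count) & !is.na(variants$alt_count) &
    (variants$ref_count + variants$alt_count) >= 1L
  if (!all(usable)) {
    warn(sprintf("Dropping %d variant(s) without usable read counts",
                 sum(!usable)))
    variants <- variants[usable, ]
  }
  if (is.data.frame(purity)) {
    key <- if ("sample_id" %in% names(purity)) "sample_id" else "patient_id"
    pv <- setNames(purity$purity, purity[[key]])
    p <- unname(pv[variants$sample_id])
    if (anyNA(p)) {
      abort(sprintf("No purity for sample(s): %s",
                    paste(unique(variants$sample_id[is.na(p)]), collapse = ", ")))
    }
  } else {
    p <- rep(purity, nrow(variants))
  }
  if (any(p <= 0 | p > 1)) abort("purity must lie in (0, 1]")

  depth <- variants$ref_count + variants$alt_count
  vaf <- variants$alt_count / depth
  m <- if (is.null(multiplicity)) {
    estimate_multiplicity(vaf, p, variants$total_cn, variants$major_cn)
  } else {
    as.integer(multiplicity)
  }
  if (any(p * m == 0)) abort("purity * multiplicity must be positive")

  scale <- (p * variants$total_cn + (1 - p) * 2) / (p * m)
  ci <- clopper_pearson(variants$alt_count, depth, conf_level)
  variants$vaf <- vaf
  variants$multiplicity <- m
  variants$ccf_raw <- vaf * scale
  variants$ccf <- pmin(pmax(variants$ccf_raw, 0), 1)
  variants$ccf_low <- pmin(ci$low * scale, 1)
  variants$ccf_high <- pmin(ci$high * scale, 1)
  variants
}

#' Classify mutations clonal vs subclonal
#'
#' Two policies are available. `"ci-overlap"` (default) calls a mutation
#' clonal when the upper bound of its CCF credible interval reaches
#' `ci_threshold` (default 0.95), i.e. the interval is compatible with
#' presence in essentially all tumor cells. `"point-threshold"` calls a
#' mutation clonal when the point estimate `ccf >= tau`. Boundary ties
#' resolve toward clonal (inclusive `>=`).
#'
#' @param ccf_tbl Output of [estimate_ccf()].
#' @param policy `"ci-overlap"` or `"point-threshold"`.
#' @param ci_threshold Clonality bound on `ccf_high` for `"ci-overlap"`.
#' @param tau Point-estimate threshold for `"point-threshold"`.
#' @return `ccf_tbl` with a `label` column (`"clonal"`/`"subclonal"`).
#' @export
classify_clonality <- function(ccf_tbl, policy = c("ci-overlap", "point-threshold"),
                               ci_threshold = 0.95, tau = 0.9) {
  if (is.character(policy) && length(policy) == 1 &&
      !policy %in% c("ci-overlap", "point-threshold")) {
    abort(sprintf("Unknown clonality policy '%s'", policy))
  }
  policy <- match.arg(policy)
  clonal <- switch(policy,
    "ci-overlap" = ccf_tbl$ccf_high >= ci_threshold,
    "point-threshold" = ccf_tbl$ccf >= tau
  )
  ccf_tbl$label <- if_else(clonal, "clonal", "subclonal")
  ccf_tbl
}

#' Intratumoral heterogeneity per patient
#'
#' ITH is the fraction of a tumor's classifiable somatic mutations that
#' are subclonal: `ith = n_subclonal / (n_clonal + n_subclonal)`. A
#' patient with fewer than `min_mutations` classified mutations is
#' flagged non-evaluable (`evaluable = FALSE`, `ith = NA`) rather than
#' silently assigned 0.
#'
#' @param labeled Output of [classify_clonality()] (needs `sample_id`
#'   and `label` columns).
#' @param min_mutations Minimum classifiable mutations for an evaluable
#'   ITH (default 5).
#' @return A tibble with one row per patient: `patient_id`, `n_clonal`,
#'   `n_subclonal`, `ith`, `evaluable`.
#' @export
compute_ith <- function(labeled, min_mutations = 5L) {
  out <- labeled %>%
    group_by(patient_id = .data$sample_id) %>%
    summarise(
      n_clonal = sum(.data$label == "clonal"),
      n_subclonal = sum(.data$label == "subclonal"),
      .groups = "drop"
    ) %>%
    mutate(
      n_total = .data$n_clonal + .data$n_subclonal,
      evaluable = .data$n_total >= min_mutations,
      ith = if_else(.data$evaluable & .data$n_total > 0,
                    .data$n_subclonal / .data$n_total, NA_real_)
    ) %>%
    select("patient_id", "n_clonal", "n_subclonal", "ith", "evaluable")
  class(out) <- c("ith_result", class(out))
  out
}

#' ITH from ctDNA panel variant frequencies
#'
#' Panel sequencing of circulating tumor DNA has no purity or copy-number
#' context, so CCFs are not identifiable. Instead each sample's VAFs are
#' normalised by the sample maximum, `f_i = vaf_i / max_j vaf_j`, and a
#' mutation is called clonal when `f_i >= rho` (default 0.5). ITH is then
#' the subclonal fraction as in [compute_ith()]. The statistic is
#' invariant to rescaling all VAFs by a positive constant; a sample whose
#' VAFs are all zero is non-evaluable.
#'
#' @param variants Variant tibble with read counts (or a `vaf` column).
#' @param rho Clonality threshold on the normalised frequency.
#' @param min_mutations Minimum mutations for evaluability (default 1).
#' @return A per-patient tibble as in [compute_ith()].
#' @export
compute_ith_ctdna <- function(variants, rho = 0.5, min_mutations = 1L) {
  variants <- as_tibble(variants)
  if (!"vaf" %in% names(variants)) {
    variants$vaf <- variants$alt_count / (variants$ref_count + variants$alt_count)
  }
  out <- variants %>%
    group_by(patient_id = .data$sample_id) %>%
    summarise(
      max_vaf = max(.data$vaf),
      n_clonal = sum(.data$vaf >= rho * max(.data$vaf)),
      n_subclonal = sum(.data$vaf < rho * max(.data$vaf)),
      .groups = "drop"
    ) %>%
    mutate(
      n_total = .data$n_clonal + .data$n_subclonal,
      evaluable = .data$n_total >= min_mutations & .data$max_vaf > 0,
      ith = if_else(.data$evaluable, .data$n_subclonal / .data$n_total, NA_real_)
    ) %>%
    select("patient_id", "n_clonal", "n_subclonal", "ith", "evaluable")
  class(out) <- c("ith_result", class(out))
  out
}
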