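#' Pipeline configuration
#'
#' Assembles and validates the configuration for [run_pipeline()].
#' Input paths may be omitted when the corresponding tables are passed
#' directly to [run_pipeline()] via `data`.
#'
#' @param maf,segments,clinical,candidates Input file paths (MAF,
#'   segment TSV, clinical TSV, neoantigen-candidate TSV). `segments`
#'   and `candidates` are optional.
#' @param epitopes Character vector of epitope sequences, or the path
#'   of a single-column text file of epitopes.
#' @param exome_mb Exome footprint in Mb for TMB (required for TMB).
#' @param ith_cutoff ITH dichotomization point (default 0.45).
#' @param tmb_top_fraction Fraction of patients called TMB-high
#'   (default 0.33).
#' @param policy,ci_threshold,tau Clonality policy, see
#'   [classify_clonality()].
#' @param min_mutations Minimum classifiable mutations for evaluable
#'   ITH.
#' @param fitness_a,fitness_k Recognition-model midpoint and steepness.
#' @param seed Integer seed recorded in the report.
#' @param out Optional path for the JSON report.
#' @return A list of class `run_config`.
#' @export
run_config <- function(maf = NULL, segments = NULL, clinical = NULL,
                       candidates = NULL, epitopes = NULL,
                       exome_mb = NULL, ith_cutoff = 0.45,
                       tmb_top_fraction = 0.33,
                       policy = "ci-overlap", ci_threshold = 0.95, tau = 0.9,
                       min_mutations = 5L, fitness_a = 26, fitness_k = 4.87,
                       seed = 1L, out = NULL) {
  if (ith_cutoff < 0 || ith_cutoff > 1) abort("ith_cutoff must lie in [0, 1]")
  if (tmb_top_fraction <= 0 || tmb_top_fraction >= 1) {
    abort("tmb_top_fraction must lie in (0, 1)")
  }
  structure(
    list(
      maf = maf, segments = segments, clinical = clinical,
      candidates = candidates, epitopes = epitopes, exome_mb = exome_mb,
      ith_cutoff = ith_cutoff, tmb_top_fraction = tmb_top_fraction,
      policy = policy, ci_threshold = ci_threshold, tau = tau,
      min_mutations = min_mutations,
      fitness_a = fitness_a, fitness_k = fitness_k,
      seed = seed, out = out
    ),
    class = "run_config"
  )
}

assoc_as_list <- function(a) {
  list(
    levels = a$levels, n = a$n,
    dcb_rate = a$dcb_rate, dcb_p = a$dcb_p,
    orr_rate = a$orr_rate, orr_p = a$orr_p,
    median_pfs = a$median_pfs, logrank_p = a$logrank_p,
    hr = a$cox$hr, hr_ci = c(a$cox$ci_low, a$cox$ci_high),
    hr_p = a$cox$p_value
  )
}

#' Run the full biomarker pipeline
#'
#' Orchestrates ingest, CCF estimation and clonality classification,
#' ITH and TMB computation, group assignment, the association layer
#' and (when candidates and epitopes are supplied) the neoantigen
#' layer. Input tables can come from files named in the config or be
#' passed pre-loaded through `data` (a list with any of `variants`,
#' `segments`, `clinical`, `candidates`).
#'
#' @param cfg A [run_config()].
#' @param data Optional list of pre-loaded tables overriding the file
#'   inputs.
#' @return An `ith_report`: per-patient biomarkers, group assignments,
#'   every association statistic, and the serialized config with its
#'   hash. Written as JSON to `cfg$out` when set.
#' @export
run_pipeline <- function(cfg, data = list()) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }
  variants <- stage("ingest", {
    if (!is.null(data$variants)) validate_variants(data$variants)
    else if (!is.null(cfg$maf)) read_maf(cfg$maf)
    else abort("No variant input (maf path or data$variants)")
  })
  segments <- stage("ingest", {
    if (!is.null(data$segments)) validate_segments(data$segments)
    else if (!is.null(cfg$segments)) read_segments(cfg$segments)
    else NULL
  })
  clinical <- stage("ingest", {
    if (!is.null(data$clinical)) validate_clinical(data$clinical)
    else if (!is.null(cfg$clinical)) read_clinical(cfg$clinical)
    else abort("No clinical input (clinical path or data$clinical)")
  })

  ccf <- stage("clonality", {
    estimate_ccf(
      variants,
      purity = clinical[, c("patient_id", "purity")] %>%
        rename(sample_id = "patient_id"),
      segments = segments
    ) %>%
      classify_clonality(policy = cfg$policy, ci_threshold = cfg$ci_threshold,
                         tau = cfg$tau)
  })
  ith <- stage("clonality", compute_ith(ccf, min_mutations = cfg$min_mutations))

  tmb <- stage("burden", {
    if (is.null(cfg$exome_mb)) abort("exome_mb is required to compute TMB")
    compute_tmb(variants, cfg$exome_mb)
  })
  tmb_cutoff <- stage("burden", quantile_cutoff(tmb$tmb, cfg$tmb_top_fraction))
  patients <- stage("burden", {
    ith %>%
      left_join(tmb, by = "patient_id") %>%
      assign_groups(ith_cutoff = cfg$ith_cutoff, tmb_cutoff = tmb_cutoff) %>%
      left_join(clinical, by = "patient_id")
  })

  evaluable <- patients %>% filter(.data$evaluable)
  assoc <- stage("association", {
    tmb_data <- patients %>%
      mutate(tmb_group = factor(.data$tmb_group,
                                levels = c("TMB-H", "TMB-L")))
    tmb_low <- evaluable %>% filter(.data$tmb_group == "TMB-L")
    list(
      ith = compare_groups(evaluable, "ith_group"),
      tmb = compare_groups(tmb_data, "tmb_group"),
      ith_within_tmb_low = if (nrow(tmb_low) > 0 &&
                               nlevels(droplevels(tmb_low$ith_group)) == 2) {
        compare_groups(tmb_low, "ith_group")
      } else NULL,
      interaction_p = interaction_p(evaluable$pfs_days, evaluable$pfs_event,
                                    evaluable$tmb_group, evaluable$ith_group),
      ith_tmb_spearman = spearman(evaluable$ith, evaluable$tmb),
      combo_logrank_p = {
        sd3 <- survival::survdiff(
          survival::Surv(evaluable$pfs_days, as.integer(evaluable$pfs_event)) ~
            evaluable$combo_group
        )
        as.numeric(pchisq(sd3$chisq, df = length(sd3$n) - 1, lower.tail = FALSE))
      },
      combo_dcb = evaluable %>%
        group_by(.data$combo_group) %>%
        summarise(n = n(), dcb_rate = mean(.data$dcb),
                  orr_rate = mean(.data$orr), .groups = "drop")
    )
  })

  neo <- NULL
  candidates <- stage("neoantigen", {
    if (!is.null(data$candidates)) as_tibble(data$candidates)
    else if (!is.null(cfg$candidates)) {
      readr::read_tsv(cfg$candidates, show_col_types = FALSE, progress = FALSE)
    } else NULL
  })
  if (!is.null(candidates) && nrow(candidates) > 0) {
    neo <- stage("neoantigen", {
      epitopes <- cfg$epitopes
      if (length(epitopes) == 1 && file.exists(epitopes)) {
        epitopes <- readr::read_lines(epitopes, progress = FALSE)
        epitopes <- epitopes[nzchar(epitopes) & !startsWith(epitopes, ">")]
      }
      scored <- neoantigen_score(candidates)
      terms <- candidate_fitness_terms(
        scored, epitope_set = epitopes %||% character(0),
        a = cfg$fitness_a, k = cfg$fitness_k
      )
      fitness <- patient_fitness(terms)
      prop <- clonal_neoantigen_proportion(candidates)
      top <- top_neoantigens(scored, 100L)
      per_patient <- prop %>%
        left_join(fitness, by = "patient_id") %>%
        left_join(
          top %>% group_by(.data$patient_id) %>%
            summarise(mean_top_score = mean(.data$score), .groups = "drop"),
          by = "patient_id"
        ) %>%
        left_join(patients[, c("patient_id", "ith_group")], by = "patient_id")
      by_ith <- per_patient %>%
        filter(!is.na(.data$ith_group)) %>%
        group_by(.data$ith_group) %>%
        summarise(
          mean_clonal_proportion = mean(.data$clonal_proportion, na.rm = TRUE),
          mean_fitness = mean(.data$fitness, na.rm = TRUE),
          mean_top_score = mean(.data$mean_top_score, na.rm = TRUE),
          .groups = "drop"
        )
      list(per_patient = per_patient, by_ith_group = by_ith)
    })
  }

  cfg_ser <- unclass(cfg)
  cfg_ser$out <- NULL  # output location is not part of the analysis config
  report <- structure(
    list(
      config = cfg_ser,
      config_hash = rlang::hash(cfg_ser),
      n_patients = nrow(patients),
      n_evaluable = nrow(evaluable),
      tmb_cutoff = tmb_cutoff,
      ith_cutoff = cfg$ith_cutoff,
      patients = patients,
      associations = assoc,
      neoantigen = neo
    ),
    class = "ith_report"
  )
  if (!is.null(cfg$out)) write_report(report, cfg$out)
  report
}

#' Serialize a pipeline report to JSON
#'
#' Deterministic serialization: identical reports produce byte-identical
#' files.
#'
#' @param report An `ith_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  out <- unclass(report)
  out$associations <- purrr::map(out$associations, function(a) {
    if (inherits(a, "ith_assoc")) assoc_as_list(a) else a
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.ith_report <- function(x, ...) {
  cat(sprintf("ITH biomarker report: %d patients (%d ITH-evaluable)\n",
              x$n_patients, x$n_evaluable))
  cat(sprintf("  cutoffs: ITH %.2f, TMB %.3g mut/Mb (top %.0f%%)\n",
              x$ith_cutoff, x$tmb_cutoff, 100 * x$config$tmb_top_fraction))
  cat("\n-- ITH-L vs ITH-H --\n"); print(x$associations$ith)
  cat("\n-- TMB-H vs TMB-L --\n"); print(x$associations$tmb)
  cat(sprintf("\nTMB x ITH interaction p = %.2f; ITH~TMB Spearman p = %.2f\n",
              x$associations$interaction_p,
              x$associations$ith_tmb_spearman$p_value))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
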