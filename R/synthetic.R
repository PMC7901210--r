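#' Configuration for the synthetic cohort generator
#'
#' Returns the full generator configuration with defaults emulating an
#' anti-PD-(L)1-treated NSCLC whole-exome cohort: 69 patients, two
#' clones per tumor (a truncal clone at CCF 1 and one subclone), ~200x
#' mean coverage, per-patient purity and truncal fraction drawn from
#' realistic ranges, and outcomes in which low ITH and high TMB are both
#' favorable (logistic model for durable clinical benefit, proportional
#' hazards for progression-free survival).
#'
#' @param ... Named overrides of any default listed below.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(...) {
  cfg <- list(
    n_patients = 69L,
    # tumor architecture
    n_clones = 2L,
    subclone_ccf_range = c(0.2, 0.5),
    truncal_fraction_range = c(0.15, 0.95),
    n_mutations_meanlog = log(120),
    n_mutations_sdlog = 0.6,
    n_mutations_min = 10L,
    # sequencing
    depth = 200,
    depth_floor = 20L,
    purity_range = c(0.3, 0.9),
    cn_profile = "diploid",
    exome_mb = 30,
    effect_probs = c(
      missense = 0.62, synonymous = 0.20, nonsense = 0.05,
      frameshift = 0.05, splice = 0.04, inframe_indel = 0.02,
      noncoding = 0.02
    ),
    # outcome model
    baseline_dcb_logodds = 1.0,
    beta_ith = -4.6,          # log-odds of DCB per unit ITH (negative)
    beta_tmb = 0.5,           # log-odds of DCB per SD of TMB (positive)
    orr_given_dcb = 0.7,
    orr_given_ndb = 0.02,
    pfs_lambda = log(2) / 160, # baseline hazard per day
    gamma_ith = log(2.71),     # log-hazard of the ITH-high group
    gamma_tmb = -log(2.66),    # log-hazard of the TMB-high group
    ith_hazard_cutoff = 0.45,
    tmb_top_fraction = 0.33,
    censoring_rate = 0.15,
    # neoantigens
    neo_rate = 0.3,            # candidates per mutation
    peptide_length = 9L,
    kd_range = c(10, 5000),
    hla_alleles = c("HLA-A*02:01", "HLA-A*11:01", "HLA-B*07:02",
                    "HLA-C*07:01")
  )
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0) {
    abort(sprintf("Unknown config field(s): %s", paste(unknown, collapse = ", ")))
  }
  cfg[names(override)] <- override
  structure(cfg, class = "cohort_config")
}

diploid_segments <- function(sample_id) {
  tibble(
    chrom = as.character(1:22), start = 1L, end = 250000000L,
    major_cn = 1L, minor_cn = 1L, sample_id = sample_id,
    total_cn = 2L
  )
}

#' Simulate one tumor's somatic variants
#'
#' Mutations are assigned to the truncal clone (CCF 1) with probability
#' `truncal_fraction`, otherwise to the subclone. The expected VAF of a
#' mutation on `m` copies in a clone at CCF `c` is
#' `purity * m * c / (purity * total_cn + (1 - purity) * 2)`; per-site
#' depth is Poisson around the mean coverage (floored), and alt reads
#' are binomial at the expected VAF.
#'
#' @param patient_id Sample identifier.
#' @param n_mutations Number of somatic mutations to simulate.
#' @param truncal_fraction Probability a mutation is truncal, in (0, 1).
#' @param subclone_ccf CCF of the subclone, in (0, 1).
#' @param depth Mean sequencing depth.
#' @param purity Tumor purity in (0, 1].
#' @param cfg A [cohort_config()] (for depth floor, effect mix, CN
#'   profile).
#' @param seed Optional integer seed for a self-contained draw.
#' @return List with `variants`, `segments`, `purity` and a `truth`
#'   tibble carrying the clone assignment and the configured true ITH
#'   (`1 - truncal_fraction`).
#' @export
simulate_tumor <- function(patient_id, n_mutations, truncal_fraction,
                           subclone_ccf, depth, purity,
                           cfg = cohort_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (truncal_fraction <= 0 || truncal_fraction >= 1) {
    abort("truncal_fraction must lie in (0, 1)")
  }
  segments <- diploid_segments(patient_id)
  total_cn <- 2L
  m <- 1L
  evaf_truncal <- purity * m * 1 / (purity * total_cn + (1 - purity) * 2)
  evaf_sub <- purity * m * subclone_ccf / (purity * total_cn + (1 - purity) * 2)
  if (evaf_truncal > 1 || evaf_sub > 1) {
    abort("Configured clone CCFs imply expected VAF > 1")
  }
  clone <- if_else(runif(n_mutations) < truncal_fraction, "truncal", "subclone")
  evaf <- if_else(clone == "truncal", evaf_truncal, evaf_sub)
  site_depth <- pmax(rpois(n_mutations, depth), cfg$depth_floor)
  alt_reads <- rbinom(n_mutations, site_depth, evaf)
  bases <- c("A", "C", "G", "T")
  ref_base <- sample(bases, n_mutations, replace = TRUE)
  alt_base <- vapply(ref_base, function(r) sample(setdiff(bases, r), 1),
                     character(1))
  ref_depth <- as.integer(site_depth - alt_reads)
  variants <- tibble(
    sample_id = patient_id,
    chrom = sample(as.character(1:22), n_mutations, replace = TRUE),
    pos = sample.int(249000000L, n_mutations, replace = TRUE),
    ref = ref_base,
    alt = unname(alt_base),
    ref_count = ref_depth,
    alt_count = as.integer(alt_reads),
    gene = sprintf("GENE%04d", sample.int(9999L, n_mutations, replace = TRUE)),
    effect = sample(names(cfg$effect_probs), n_mutations, replace = TRUE,
                    prob = cfg$effect_probs)
  )
  truth <- tibble(
    patient_id = patient_id,
    mutation_index = seq_len(n_mutations),
    clone = clone,
    clone_ccf = if_else(clone == "truncal", 1, subclone_ccf),
    true_ith = 1 - truncal_fraction
  )
  list(variants = variants, segments = segments, purity = purity, truth = truth)
}

#' Simulate response and survival outcomes with planted effects
#'
#' Durable clinical benefit is Bernoulli with log-odds
#' `alpha + beta_ith * ith + beta_tmb * tmb_z` (`tmb_z` is the cohort
#' z-score of TMB), so `beta_ith < 0` plants the low-ITH advantage and
#' `beta_tmb > 0` the high-TMB advantage. Objective response is a
#' stricter Bernoulli nested within DCB. PFS is exponential with hazard
#' `lambda * exp(gamma_ith * [ith > cutoff] + gamma_tmb * [TMB high])`;
#' a fraction `censoring_rate` of patients are censored uniformly
#' before their event time.
#'
#' @param truth Tibble with `patient_id`, `ith` (true), `tmb` and
#'   `purity` columns.
#' @param cfg A [cohort_config()].
#' @param seed Optional integer seed.
#' @return A validated clinical tibble (see [read_clinical()]).
#' @export
simulate_outcomes <- function(truth, cfg = cohort_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (cfg$censoring_rate < 0 || cfg$censoring_rate >= 1) {
    abort("censoring_rate must lie in [0, 1)")
  }
  n <- nrow(truth)
  tmb_z <- if (sd(truth$tmb) > 0) as.numeric(scale(truth$tmb)) else rep(0, n)
  p_dcb <- plogis(cfg$baseline_dcb_logodds + cfg$beta_ith * truth$ith +
                    cfg$beta_tmb * tmb_z)
  dcb <- runif(n) < p_dcb
  orr <- dcb & (runif(n) < cfg$orr_given_dcb) |
    (!dcb & runif(n) < cfg$orr_given_ndb)
  tmb_cut <- quantile_cutoff(truth$tmb, cfg$tmb_top_fraction)
  hazard <- cfg$pfs_lambda * exp(
    cfg$gamma_ith * (truth$ith > cfg$ith_hazard_cutoff) +
      cfg$gamma_tmb * (truth$tmb >= tmb_cut)
  )
  t_event <- rexp(n, rate = hazard)
  censored <- runif(n) < cfg$censoring_rate
  pfs <- if_else(censored, runif(n) * t_event, t_event)
  validate_clinical(tibble(
    patient_id = truth$patient_id,
    dcb = dcb, orr = orr,
    pfs_days = pmax(pfs, 0.5),
    pfs_event = !censored,
    purity = truth$purity
  ))
}

random_peptide <- function(n, len) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  vapply(seq_len(n), function(i) {
    paste(sample(aa, len, replace = TRUE), collapse = "")
  }, character(1))
}

#' Simulate neoantigen candidates for a tumor
#'
#' Draws `round(neo_rate * n_mutations)` candidates per patient, each a
#' random wild-type peptide with a single amino-acid substitution.
#' Dissociation constants are log-uniform on `kd_range`; the clonal flag
#' and source CCF are inherited from a uniformly sampled source
#' mutation, so the clonal candidate fraction tracks the truncal
#' fraction.
#'
#' @param truth Per-mutation truth tibble from [simulate_tumor()].
#' @param cfg A [cohort_config()].
#' @param seed Optional integer seed.
#' @return A candidate tibble (`patient_id`, `mut_peptide`,
#'   `wt_peptide`, `hla_allele`, `kd_mut`, `kd_wt`, `source_ccf`,
#'   `clonal`).
#' @export
simulate_neoantigens <- function(truth, cfg = cohort_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  purrr::map_dfr(split(truth, truth$patient_id), function(tt) {
    n_cand <- round(cfg$neo_rate * nrow(tt))
    if (n_cand == 0) return(tibble())
    src <- sample.int(nrow(tt), n_cand, replace = TRUE)
    wt <- random_peptide(n_cand, cfg$peptide_length)
    pos <- sample.int(cfg$peptide_length, n_cand, replace = TRUE)
    mut <- vapply(seq_len(n_cand), function(i) {
      old <- substr(wt[i], pos[i], pos[i])
      new <- sample(setdiff(aa, old), 1)
      paste0(substr(wt[i], 1, pos[i] - 1), new,
             substr(wt[i], pos[i] + 1, cfg$peptide_length))
    }, character(1))
    lkd <- log(cfg$kd_range)
    tibble(
      patient_id = tt$patient_id[1],
      mut_peptide = mut,
      wt_peptide = wt,
      hla_allele = sample(cfg$hla_alleles, n_cand, replace = TRUE),
      kd_mut = exp(runif(n_cand, lkd[1], lkd[2])),
      kd_wt = exp(runif(n_cand, lkd[1], lkd[2])),
      source_ccf = tt$clone_ccf[src],
      clonal = tt$clone[src] == "truncal"
    )
  })
}

#' Simulate a full synthetic cohort
#'
#' Draws per-patient architecture (mutation count, truncal fraction,
#' subclone CCF, purity) from the configured ranges, simulates read
#' counts, outcomes and neoantigen candidates, and returns everything a
#' downstream analysis needs plus the ground truth.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer seed fixing the whole stream.
#' @return List with `variants`, `segments`, `clinical`, `candidates`,
#'   `truth` (per patient) and `mutation_truth` (per mutation).
#' @export
simulate_cohort <- function(cfg = cohort_config(), seed = 1L) {
  set.seed(seed)
  n <- cfg$n_patients
  ids <- sprintf("P%03d", seq_len(n))
  t_frac <- runif(n, cfg$truncal_fraction_range[1], cfg$truncal_fraction_range[2])
  sub_ccf <- runif(n, cfg$subclone_ccf_range[1], cfg$subclone_ccf_range[2])
  purity <- runif(n, cfg$purity_range[1], cfg$purity_range[2])
  n_mut <- pmax(
    as.integer(round(rlnorm(n, cfg$n_mutations_meanlog, cfg$n_mutations_sdlog))),
    cfg$n_mutations_min
  )
  tumors <- purrr::map(seq_len(n), function(i) {
    simulate_tumor(ids[i], n_mut[i], t_frac[i], sub_ccf[i],
                   cfg$depth, purity[i], cfg)
  })
  variants <- purrr::map_dfr(tumors, "variants")
  segments <- purrr::map_dfr(tumors, "segments")
  mutation_truth <- purrr::map_dfr(tumors, "truth")
  tmb <- compute_tmb(variants, cfg$exome_mb)
  truth <- tibble(
    patient_id = ids,
    true_ith = 1 - t_frac,
    subclone_ccf = sub_ccf,
    purity = purity,
    n_mutations = n_mut
  ) %>%
    left_join(tmb, by = "patient_id") %>%
    rename(ith = "true_ith")
  clinical <- simulate_outcomes(truth, cfg)
  candidates <- simulate_neoantigens(mutation_truth, cfg)
  list(
    variants = variants, segments = segments, clinical = clinical,
    candidates = candidates,
    truth = truth %>% rename(true_ith = "ith"),
    mutation_truth = mutation_truth
  )
}

#' Write a simulated cohort to disk
#'
#' Writes the MAF, segment TSV, clinical TSV, candidate TSV and a truth
#' JSON into `dir`, the on-disk layout consumed by [run_pipeline()].
#'
#' @param sim Output of [simulate_cohort()].
#' @param dir Output directory (created if missing).
#' @return Named list of file paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    maf = file.path(dir, "cohort.maf"),
    segments = file.path(dir, "segments.tsv"),
    clinical = file.path(dir, "clinical.tsv"),
    candidates = file.path(dir, "candidates.tsv"),
    truth = file.path(dir, "truth.json")
  )
  write_maf(sim$variants, paths$maf)
  write_segments(sim$segments, paths$segments)
  write_clinical(sim$clinical, paths$clinical)
  readr::write_tsv(sim$candidates, paths$candidates, progress = FALSE)
  jsonlite::write_json(sim$truth, paths$truth, digits = NA)
  invisible(paths)
}
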