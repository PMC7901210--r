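#' MHC presentation amplitude
#'
#' Ratio of the wild-type to the mutant peptide-MHC dissociation
#' constant, `A = kd_wt / kd_mut`. Values above 1 mean the mutant
#' peptide binds MHC more strongly than its wild-type counterpart and is
#' therefore differentially presented.
#'
#' @param kd_wt,kd_mut Dissociation constants in nM (> 0). Vectorised.
#' @return Amplitudes `A > 0`.
#' @export
amplitude <- function(kd_wt, kd_mut) {
  if (any(kd_wt <= 0) || any(kd_mut <= 0)) {
    abort("Dissociation constants must be positive")
  }
  kd_wt / kd_mut
}

# gapless Smith-Waterman score of a peptide against one epitope
align_score <- function(peptide, epitopes,
                        substitution_matrix = "BLOSUM62") {
  if (length(epitopes) == 0) return(numeric(0))
  as.numeric(Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(rep(peptide, length(epitopes))),
    subject = Biostrings::AAStringSet(epitopes),
    type = "local",
    substitutionMatrix = substitution_matrix,
    gapOpening = 1e6, gapExtension = 1e6,
    scoreOnly = TRUE
  ))
}

#' T-cell recognition probability of a mutant peptide
#'
#' Aligns the peptide against a reference set of immunogenic epitopes
#' (gapless Smith-Waterman, BLOSUM62 by default) and aggregates the
#' scores through a logistic partition function:
#' `S = sum_e exp(-k * (a - score_e))`, `R = S / (1 + S)`.
#' `a` is the horizontal displacement (an alignment score at which a
#' single epitope yields R = 0.5) and `k` sets the steepness. With an
#' empty epitope set `S = 0` and `R = 0` (warned). `R` lies in `[0, 1)`
#' and increases with every alignment score.
#'
#' @param mut_peptide Mutant peptide (amino-acid string).
#' @param epitope_set Character vector of epitope sequences.
#' @param a Alignment-score midpoint (default 26).
#' @param k Logistic steepness (default 4.87).
#' @param substitution_matrix Scoring matrix name (default "BLOSUM62").
#' @return The recognition probability `R`.
#' @export
recognition_probability <- function(mut_peptide, epitope_set,
                                    a = 26, k = 4.87,
                                    substitution_matrix = "BLOSUM62") {
  if (a <= 0 || k <= 0) abort("a and k must be positive")
  if (length(epitope_set) == 0) {
    warn("Empty epitope set: recognition probability is 0")
    return(0)
  }
  sc <- align_score(mut_peptide, epitope_set, substitution_matrix)
  s <- sum(exp(-k * (a - sc)))
  s / (1 + s)
}

#' Per-candidate fitness terms
#'
#' Computes, for every neoantigen candidate, the presentation amplitude
#' `A`, recognition probability `R` and their product `A * R` — the
#' quantity aggregated into the per-patient fitness.
#'
#' @param candidates Candidate tibble with `patient_id`, `mut_peptide`,
#'   `wt_peptide`, `kd_mut`, `kd_wt` and (for downstream aggregation)
#'   `clonal` / `source_ccf` columns.
#' @param epitope_set Character vector of epitope sequences.
#' @param a,k,substitution_matrix Passed to
#'   [recognition_probability()].
#' @return `candidates` with `A`, `R` and `product` columns.
#' @export
candidate_fitness_terms <- function(candidates, epitope_set,
                                    a = 26, k = 4.87,
                                    substitution_matrix = "BLOSUM62") {
  candidates <- as_tibble(candidates)
  candidates$A <- amplitude(candidates$kd_wt, candidates$kd_mut)
  if (length(epitope_set) == 0) {
    warn("Empty epitope set: recognition probability is 0 for all candidates")
    candidates$R <- 0
  } else {
    candidates$R <- vapply(
      candidates$mut_peptide,
      recognition_probability,
      numeric(1),
      epitope_set = epitope_set, a = a, k = k,
      substitution_matrix = substitution_matrix,
      USE.NAMES = FALSE
    )
  }
  candidates$product <- candidates$A * candidates$R
  candidates
}

#' Per-patient neoantigen fitness
#'
#' Clone-frequency-weighted dominant-antigen aggregate:
#' `fitness = -sum_clones X_clone * max(A * R over the clone's
#' candidates)`. More negative fitness means the tumor's dominant
#' neoantigens are both well presented and likely recognised, i.e. the
#' tumor is predicted to be under stronger immune pressure. Clones with
#' no candidates contribute 0.
#'
#' When `clone_frequencies` is `NULL` the two-level clonal/subclonal
#' split from the clonality layer is used: the clonal population gets
#' weight 1 and the subclonal population the mean `source_ccf` of the
#' subclonal candidates.
#'
#' @param terms Output of [candidate_fitness_terms()]; needs a `clone`
#'   column (or a logical `clonal` column for the default two-level
#'   split).
#' @param clone_frequencies Named non-negative vector of clone
#'   frequencies, or `NULL` for the clonal/subclonal default.
#' @return Tibble with `patient_id` and `fitness` (<= 0).
#' @export
patient_fitness <- function(terms, clone_frequencies = NULL) {
  terms <- as_tibble(terms)
  if (nrow(terms) == 0) return(tibble(patient_id = character(), fitness = numeric()))
  if (!"clone" %in% names(terms)) {
    terms$clone <- if_else(terms$clonal, "clonal", "subclonal")
  }
  if (!is.null(clone_frequencies) && any(clone_frequencies < 0)) {
    abort("Clone frequencies must be non-negative")
  }
  terms %>%
    group_by(.data$patient_id) %>%
    group_modify(function(df, key) {
      best <- df %>%
        group_by(.data$clone) %>%
        summarise(best = max(.data$product), .groups = "drop")
      x <- if (is.null(clone_frequencies)) {
        sub_ccf <- df$source_ccf[df$clone == "subclonal"]
        c(clonal = 1,
          subclonal = if (length(sub_ccf) > 0) mean(sub_ccf) else 0)
      } else {
        clone_frequencies
      }
      w <- x[best$clone]
      w[is.na(w)] <- 0
      tibble(fitness = -sum(w * best$best))
    }) %>%
    ungroup()
}

# hydrophobic residues by Kyte-Doolittle hydropathy > 0
hydrophobic_residues <- c("A", "C", "F", "I", "L", "M", "V")

substitution_position <- function(mut, wt) {
  m <- strsplit(mut, "")[[1]]
  w <- strsplit(wt, "")[[1]]
  if (length(m) != length(w)) abort("Mutant and wild-type peptides differ in length")
  d <- which(m != w)
  if (length(d) == 0) abort("Mutant and wild-type peptides are identical")
  d[1]
}

#' Composite neoantigen quality score
#'
#' Weighted composite of four quality components, each in `[0, 1]`:
#' * `s_aa` — 1 when the substitution flips the hydrophobicity class of
#'   the residue (Kyte-Doolittle hydrophobic vs not), else 0;
#' * `s_struct` — 1 when the substitution lies outside the MHC anchor
#'   positions (position 2 and the C-terminus), else 0.5, reflecting
#'   that anchor changes alter binding more than TCR-facing changes;
#' * `s_hla` — MHC-binding term `1 / (1 + kd_mut / 500)` (0.5 at the
#'   conventional 500 nM binder threshold);
#' * `s_freq` — the CCF of the source mutation.
#'
#' Default weights are equal (0.25 each) so the score lies in `[0, 1]`.
#' The functional form is configurable via `weights`; an alternative
#' scoring function can replace this one wherever a score column is
#' consumed.
#'
#' @param candidates Candidate tibble with `mut_peptide`, `wt_peptide`,
#'   `kd_mut`, `source_ccf`.
#' @param weights Non-negative length-4 vector `(w_aa, w_struct, w_hla,
#'   w_freq)`; normalised to sum 1.
#' @return `candidates` with component columns and `score`.
#' @export
neoantigen_score <- function(candidates, weights = c(0.25, 0.25, 0.25, 0.25)) {
  if (length(weights) != 4 || any(weights < 0) || sum(weights) == 0) {
    abort("weights must be 4 non-negative values with a positive sum")
  }
  weights <- weights / sum(weights)
  candidates <- as_tibble(candidates)
  pos <- mapply(substitution_position, candidates$mut_peptide, candidates$wt_peptide)
  len <- nchar(candidates$mut_peptide)
  mut_res <- substr(candidates$mut_peptide, pos, pos)
  wt_res <- substr(candidates$wt_peptide, pos, pos)
  candidates$s_aa <- as.numeric(
    (mut_res %in% hydrophobic_residues) != (wt_res %in% hydrophobic_residues)
  )
  candidates$s_struct <- if_else(pos == 2L | pos == len, 0.5, 1)
  candidates$s_hla <- 1 / (1 + candidates$kd_mut / 500)
  candidates$s_freq <- candidates$source_ccf
  candidates$score <- weights[1] * candidates$s_aa +
    weights[2] * candidates$s_struct +
    weights[3] * candidates$s_hla +
    weights[4] * candidates$s_freq
  candidates
}

#' Stable top-n neoantigen selection
#'
#' Selects each patient's `n` highest-scoring candidates. Ties are
#' broken by mutant-peptide lexicographic order so the selection is
#' invariant to the input row order.
#'
#' @param scored Output of [neoantigen_score()].
#' @param n Candidates to keep per patient (default 100).
#' @return The selected rows, ordered by patient, descending score.
#' @export
top_neoantigens <- function(scored, n = 100L) {
  scored %>%
    group_by(.data$patient_id) %>%
    arrange(desc(.data$score), .data$mut_peptide, .by_group = TRUE) %>%
    filter(row_number() <= n) %>%
    ungroup()
}

#' Proportion of clonal neoantigens per patient
#'
#' @param candidates Candidate tibble with `patient_id` and a logical
#'   `clonal` flag inherited from the source mutation.
#' @return Tibble with `patient_id`, `n_candidates`,
#'   `clonal_proportion` (`NA` for patients with no candidates).
#' @export
clonal_neoantigen_proportion <- function(candidates) {
  as_tibble(candidates) %>%
    group_by(.data$patient_id) %>%
    summarise(
      n_candidates = n(),
      clonal_proportion = if (n() > 0) mean(.data$clonal) else NA_real_,
      .groups = "drop"
    )
}
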