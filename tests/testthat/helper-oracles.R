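# Independent oracles used across the suite. These deliberately take the
# dumbest correct route (enumeration, brute-force scanning) so they share
# no code with the implementation they check.

# Two-sided Fisher p by exhaustive hypergeometric enumeration at fixed
# margins (probability-mass definition, with the conventional relative
# tolerance for "as extreme").
fisher_p_enum <- function(a, b, c, d) {
  m <- a + b
  n2 <- c + d
  k <- a + c
  lo <- max(0L, k - n2)
  hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n2, k)
  obs <- stats::dhyper(a, m, n2, k)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# Brute-force containing-segment scan for one position
scan_segment <- function(sample_id, chrom, pos, segments) {
  for (i in seq_len(nrow(segments))) {
    if (segments$sample_id[i] == sample_id &&
        segments$chrom[i] == chrom &&
        segments$start[i] <= pos && pos <= segments$end[i]) {
      return(i)
    }
  }
  NA_integer_
}

# Nearest-rank top-fraction cutoff by counting, not sorting: the largest
# value v in the data with at least ceil(n * f) observations >= v.
cutoff_by_counting <- function(values, top_fraction) {
  k <- ceiling(length(values) * top_fraction)
  cands <- unique(values)
  ok <- vapply(cands, function(v) sum(values >= v) >= k, logical(1))
  max(cands[ok])
}

# Kaplan-Meier survival curve by direct risk-set accounting
km_by_hand <- function(times, events) {
  tt <- sort(unique(times[events == 1]))
  s <- 1
  out <- numeric(length(tt))
  for (i in seq_along(tt)) {
    at_risk <- sum(times >= tt[i])
    died <- sum(times == tt[i] & events == 1)
    s <- s * (1 - died / at_risk)
    out[i] <- s
  }
  list(time = tt, surv = out)
}

# All permutations of 1..n (n small), for the exact Spearman null
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# A small standard epitope set for alignment-based tests
test_epitopes <- c("SIINFEKLL", "GILGFVFTL", "NLVPMVATV", "GLCTLVAML")

new_variant_row <- function(sample_id = "S1", chrom = "1", pos = 100L,
                            ref = "A", alt = "T", ref_count = 60L,
                            alt_count = 40L, gene = "TP53",
                            effect = "missense") {
  tibble::tibble(
    sample_id = sample_id, chrom = chrom, pos = pos, ref = ref, alt = alt,
    ref_count = as.integer(ref_count), alt_count = as.integer(alt_count),
    gene = gene, effect = effect
  )
}
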