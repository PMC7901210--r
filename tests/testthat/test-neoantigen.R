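test_that("amplitude is the kd ratio with positivity enforced", {
  expect_equal(amplitude(500, 50), 10)
  expect_equal(amplitude(21.9, 219), 0.1)
  expect_equal(amplitude(219, 219), 1)
  expect_error(amplitude(0, 10), "positive")
  expect_error(amplitude(10, -1), "positive")
})

test_that("recognition probability is the logistic alignment aggregate", {
  expect_warning(r0 <- recognition_probability("SIINFEKLL", character(0)),
                 "Empty")
  expect_equal(r0, 0)

  # gapless self-alignment of AAAA scores 4 * BLOSUM62[A,A] = 16,
  # so at midpoint a = 16 a single identical epitope gives S = 1
  expect_equal(recognition_probability("AAAA", "AAAA", a = 16, k = 1), 0.5)
  # two identical epitopes double S: R = 2 / 3
  expect_equal(recognition_probability("AAAA", c("AAAA", "AAAA"),
                                       a = 16, k = 1), 2 / 3)
})

test_that("recognition probability increases with alignment score and stays in [0,1)", {
  # CCCC self-aligns at 4 * 9 = 36; sliding the midpoint up lowers R
  r_vals <- vapply(c(30, 36, 40), function(a) {
    recognition_probability("CCCC", "CCCC", a = a, k = 1)
  }, numeric(1))
  expect_true(all(diff(r_vals) < 0))
  expect_true(all(r_vals > 0 & r_vals < 1))

  # a better-matching epitope raises R
  weak <- recognition_probability("SIINFEKLL", "GILGFVFTL", a = 26, k = 4.87)
  strong <- recognition_probability("SIINFEKLL", "SIINFEKLL", a = 26, k = 4.87)
  expect_gt(strong, weak)
})

test_that("fitness terms multiply amplitude and recognition, monotone in kd_wt", {
  cand <- tibble::tibble(
    patient_id = "P1",
    mut_peptide = "SIINFEKLL", wt_peptide = "SIINFEKLI",
    kd_mut = 50, kd_wt = 500, source_ccf = 1, clonal = TRUE
  )
  terms <- candidate_fitness_terms(cand, epitope_set = "SIINFEKLL",
                                   a = 26, k = 4.87)
  expect_equal(terms$product, terms$A * terms$R)
  expect_equal(terms$A, 10)

  sweep <- purrr::map_dbl(c(100, 500, 2500), function(kd) {
    candidate_fitness_terms(dplyr::mutate(cand, kd_wt = kd),
                            epitope_set = "SIINFEKLL")$product
  })
  expect_true(all(diff(sweep) > 0))
})

test_that("patient fitness is the clone-weighted best product, negated", {
  terms <- tibble::tibble(
    patient_id = "P1",
    clone = c("c1", "c1", "c2"),
    product = c(5, 1, 2),
    source_ccf = c(1, 1, 0.4)
  )
  fit <- patient_fitness(terms, clone_frequencies = c(c1 = 0.6, c2 = 0.4))
  expect_equal(fit$fitness, -(0.6 * 5 + 0.4 * 2))   # -3.8

  one <- patient_fitness(
    tibble::tibble(patient_id = "P1", clone = "c1", product = 5,
                   source_ccf = 1),
    clone_frequencies = c(c1 = 1)
  )
  expect_equal(one$fitness, -5)

  none <- patient_fitness(terms[0, ])
  expect_equal(nrow(none), 0L)

  expect_error(patient_fitness(terms, clone_frequencies = c(c1 = -0.1, c2 = 1)),
               "non-negative")

  # default split: clonal weight 1, subclonal weight = mean subclonal CCF
  default_fit <- patient_fitness(
    tibble::tibble(patient_id = "P1", clonal = c(TRUE, FALSE),
                   product = c(5, 2), source_ccf = c(1, 0.4))
  )
  expect_equal(default_fit$fitness, -(1 * 5 + 0.4 * 2))
})

test_that("fitness becomes more negative as the best product grows", {
  base <- tibble::tibble(patient_id = "P1", clonal = TRUE, product = 5,
                         source_ccf = 1)
  better <- dplyr::mutate(base, product = 8)
  expect_lt(patient_fitness(better)$fitness, patient_fitness(base)$fitness)
})

test_that("neoantigen score composes its four components on [0,1]", {
  # hydrophobicity flip (L -> D), non-anchor position 5, strong binder,
  # clonal source: every component at (or arbitrarily near) 1
  best <- tibble::tibble(
    patient_id = "P1",
    mut_peptide = "AAAADAAAK", wt_peptide = "AAAALAAAK",
    kd_mut = 1e-9, source_ccf = 1
  )
  s <- neoantigen_score(best)
  expect_equal(s$s_aa, 1)
  expect_equal(s$s_struct, 1)
  expect_equal(s$score, 1, tolerance = 1e-10)

  # no flip (L -> I), anchor position 2, weak binder, absent clone
  worst <- tibble::tibble(
    patient_id = "P1",
    mut_peptide = "AIAAAAAAK", wt_peptide = "ALAAAAAAK",
    kd_mut = 1e9, source_ccf = 0
  )
  w <- neoantigen_score(worst)
  expect_equal(w$s_aa, 0)
  expect_equal(w$s_struct, 0.5)
  expect_equal(w$score, 0.125, tolerance = 1e-5)

  # binding term hits its midpoint at the 500 nM binder threshold
  mid <- neoantigen_score(dplyr::mutate(best, kd_mut = 500))
  expect_equal(mid$s_hla, 0.5)

  expect_error(neoantigen_score(best, weights = c(-1, 1, 1, 1)), "weights")
  expect_error(neoantigen_score(best, weights = c(0, 0, 0, 0)), "weights")
})

test_that("top-n selection is stable under permutation with lexicographic ties", {
  set.seed(2)
  cand <- tibble::tibble(
    patient_id = "P1",
    mut_peptide = replicate(150, paste(sample(LETTERS[1:20], 9, TRUE),
                                       collapse = "")),
    wt_peptide = "AAAAAAAAA",
    kd_mut = sample(c(50, 500, 5000), 150, replace = TRUE),
    source_ccf = sample(c(0.2, 1), 150, replace = TRUE)
  )
  cand$wt_peptide <- vapply(cand$mut_peptide, function(p) {
    paste0("A", substr(p, 2, 9))
  }, character(1))
  cand <- cand[cand$mut_peptide != cand$wt_peptide, ]
  scored <- neoantigen_score(cand)
  top <- top_neoantigens(scored, 100L)
  top_perm <- top_neoantigens(scored[sample.int(nrow(scored)), ], 100L)
  expect_equal(nrow(top), 100L)
  expect_equal(top, top_perm)
})

test_that("clonal neoantigen proportion summarises the clonal flags", {
  cand <- tibble::tibble(
    patient_id = rep(c("P1", "P2"), c(10, 4)),
    clonal = c(rep(TRUE, 8), rep(FALSE, 2), rep(FALSE, 4))
  )
  prop <- clonal_neoantigen_proportion(cand)
  expect_equal(prop$clonal_proportion[prop$patient_id == "P1"], 0.8)
  expect_equal(prop$clonal_proportion[prop$patient_id == "P2"], 0.0)
})

test_that("simulated low-ITH patients carry more clonal neoantigens", {
  set.seed(120)
  low <- simulate_tumor("L", 200, truncal_fraction = 0.8, subclone_ccf = 0.4,
                        depth = 100, purity = 0.8)
  high <- simulate_tumor("H", 200, truncal_fraction = 0.3, subclone_ccf = 0.4,
                         depth = 100, purity = 0.8)
  cand <- simulate_neoantigens(dplyr::bind_rows(low$truth, high$truth))
  prop <- clonal_neoantigen_proportion(cand)
  expect_gt(prop$clonal_proportion[prop$patient_id == "L"],
            prop$clonal_proportion[prop$patient_id == "H"])
})
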