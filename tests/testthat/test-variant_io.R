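test_that("MAF reading maps columns and effects, and round-trips", {
  maf <- file.path(tempdir(), "io.maf")
  variants <- dplyr::bind_rows(
    new_variant_row(pos = 100L, ref_count = 60L, alt_count = 40L),
    new_variant_row(pos = 200L, ref = "G", alt = "C", gene = "EGFR",
                    effect = "synonymous", ref_count = 80L, alt_count = 20L),
    new_variant_row(sample_id = "S2", pos = 300L, effect = "frameshift",
                    ref_count = 10L, alt_count = 10L)
  )
  write_maf(variants, maf)
  back <- read_maf(maf)
  expect_equal(as.data.frame(back), as.data.frame(variants))
  expect_equal(back$alt_count[1] / (back$ref_count[1] + back$alt_count[1]), 0.40)

  # header-only file -> empty table
  writeLines(readLines(maf)[1], maf)
  expect_equal(nrow(read_maf(maf)), 0L)
})

test_that("MAF errors name the missing column and the offending row", {
  maf <- file.path(tempdir(), "bad.maf")
  writeLines(c("Chromosome\tStart_Position", "1\t100"), maf)
  expect_error(read_maf(maf), "Reference_Allele")

  writeLines(c(
    paste(c("Hugo_Symbol", "Chromosome", "Start_Position", "Reference_Allele",
            "Tumor_Seq_Allele2", "Variant_Classification", "t_ref_count",
            "t_alt_count", "Tumor_Sample_Barcode"), collapse = "\t"),
    "TP53\t1\t100\tA\tT\tMissense_Mutation\t6.5\t40\tS1"
  ), maf)
  expect_error(read_maf(maf), "row")

  writeLines(c(
    paste(c("Hugo_Symbol", "Chromosome", "Start_Position", "Reference_Allele",
            "Tumor_Seq_Allele2", "Variant_Classification", "t_ref_count",
            "t_alt_count", "Tumor_Sample_Barcode"), collapse = "\t"),
    "TP53\t1\t100\tA\tT\tMissense_Mutation\t\t40\tS1"
  ), maf)
  expect_error(read_maf(maf), "missing read counts")
  expect_equal(nrow(read_maf(maf, missing_counts = "drop")), 0L)
  expect_true(is.na(read_maf(maf, missing_counts = "keep")$ref_count[1]))
})

test_that("VCF reading uses AD, splits multi-allelic records", {
  vcf <- file.path(tempdir(), "io.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"),
    "1\t100\t.\tA\tT\t.\tPASS\t.\tGT:AD\t0/1:70,30",
    "2\t200\t.\tG\tA,C\t.\tPASS\t.\tGT:AD\t0/1:50,20,10"
  ), vcf)
  calls <- read_vcf(vcf)
  expect_equal(nrow(calls), 3L)
  expect_equal(calls$ref_count[1], 70L)
  expect_equal(calls$alt_count[1], 30L)
  expect_equal(calls$alt[2:3], c("A", "C"))
  expect_equal(calls$alt_count[2:3], c(20L, 10L))
  expect_equal(calls$ref_count[2:3], c(50L, 50L))
})

test_that("VCF without AD is refused; VAFs reproduce AD ratios at scale", {
  vcf <- file.path(tempdir(), "noad.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"),
    "1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1"
  ), vcf)
  expect_error(read_vcf(vcf), "AD")

  set.seed(11)
  n <- 50
  ref_d <- sample(20:200, n, replace = TRUE)
  alt_d <- sample(1:100, n, replace = TRUE)
  body <- sprintf("%d\t%d\t.\tA\tT\t.\tPASS\t.\tGT:AD\t0/1:%d,%d",
                  sample(1:22, n, replace = TRUE), seq_len(n) * 1000L,
                  ref_d, alt_d)
  vcf2 <- file.path(tempdir(), "fifty.vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    '##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1"), collapse = "\t"),
    body
  ), vcf2)
  calls <- read_vcf(vcf2)
  expect_equal(nrow(calls), n)
  expect_equal(calls$alt_count / (calls$ref_count + calls$alt_count),
               alt_d / (ref_d + alt_d))
})

test_that("segment validation enforces ordering, CN sanity and non-overlap", {
  seg <- tibble::tibble(
    chrom = "1", start = 1L, end = 1000L, major_cn = 2L, minor_cn = 1L,
    sample_id = "S1"
  )
  v <- validate_segments(seg)
  expect_equal(v$total_cn, 3L)

  overlapping <- dplyr::bind_rows(seg, dplyr::mutate(seg, start = 500L, end = 2000L))
  expect_error(validate_segments(overlapping), "Overlap")
  expect_error(
    validate_segments(dplyr::mutate(seg, major_cn = 0L)),
    "major_cn < minor_cn"
  )

  path <- file.path(tempdir(), "seg.tsv")
  write_segments(v, path)
  expect_equal(as.data.frame(read_segments(path)), as.data.frame(v))
})

test_that("clinical table validates and round-trips a 69-patient cohort", {
  cl <- tibble::tibble(
    patient_id = sprintf("P%03d", 1:69),
    dcb = rep(c(TRUE, FALSE, FALSE), 23),
    orr = rep(c(TRUE, FALSE, FALSE), 23),
    pfs_days = seq(10, 690, by = 10),
    pfs_event = rep(c(TRUE, TRUE, FALSE), 23),
    purity = seq(0.3, 0.98, length.out = 69)
  )
  path <- file.path(tempdir(), "clin.tsv")
  write_clinical(cl, path)
  back <- read_clinical(path)
  expect_equal(as.data.frame(back), as.data.frame(cl))
  expect_true(back$dcb[1])

  expect_error(validate_clinical(dplyr::bind_rows(cl, cl[1, ])), "Duplicate")
  expect_error(validate_clinical(dplyr::mutate(cl, pfs_days = 0)), "pfs_days")
  expect_error(validate_clinical(dplyr::mutate(cl, purity = 1.2)), "purity")
})

test_that("copy-number lookup is inclusive at both ends and defaults off-segment", {
  seg <- validate_segments(tibble::tibble(
    chrom = "1", start = 100L, end = 200L, major_cn = 3L, minor_cn = 1L,
    sample_id = "S1"
  ))
  at_start <- lookup_cn(new_variant_row(pos = 100L), seg)
  at_end <- lookup_cn(new_variant_row(pos = 200L), seg)
  past_end <- lookup_cn(new_variant_row(pos = 201L), seg)
  expect_equal(at_start$total_cn, 4L)
  expect_equal(at_end$total_cn, 4L)
  expect_equal(past_end$total_cn, 2L)
  expect_true(past_end$cn_default)
})

test_that("interval lookup matches a brute-force scan on random positions", {
  set.seed(31)
  seg <- list()
  for (s in c("S1", "S2")) {
    for (chr in c("1", "2")) {
      starts <- sort(sample.int(9000L, 12L)) * 10L
      seg[[paste(s, chr)]] <- tibble::tibble(
        chrom = chr,
        start = starts,
        end = starts + sample(5:80, 12L, replace = TRUE),
        major_cn = sample(1:4, 12L, replace = TRUE),
        minor_cn = 1L,
        sample_id = s
      )
    }
  }
  seg <- validate_segments(dplyr::bind_rows(seg))
  variants <- tibble::tibble(
    sample_id = sample(c("S1", "S2"), 1000, replace = TRUE),
    chrom = sample(c("1", "2"), 1000, replace = TRUE),
    pos = sample.int(100000L, 1000, replace = TRUE),
    ref = "A", alt = "T", ref_count = 50L, alt_count = 50L,
    gene = "G", effect = "missense"
  )
  looked <- lookup_cn(variants, seg)
  expected <- vapply(seq_len(1000), function(i) {
    j <- scan_segment(variants$sample_id[i], variants$chrom[i],
                      variants$pos[i], seg)
    if (is.na(j)) 2L else seg$total_cn[j]
  }, integer(1))
  expect_equal(looked$total_cn, expected)
})
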