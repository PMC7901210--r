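#' Functional effect classes recognised by the pipeline
#'
#' Somatic variants carry one of these pre-annotated functional classes.
#' The first five are counted as nonsynonymous for tumor mutational burden.
#'
#' @export
effect_levels <- c(
  "missense", "nonsense", "frameshift", "splice",
  "inframe_indel", "synonymous", "noncoding"
)

#' @rdname effect_levels
#' @export
nonsynonymous_effects <- c(
  "missense", "nonsense", "frameshift", "splice", "inframe_indel"
)

# MAF Variant_Classification -> internal effect class
maf_effect_map <- c(
  Missense_Mutation       = "missense",
  Nonsense_Mutation       = "nonsense",
  Nonstop_Mutation        = "missense",
  Translation_Start_Site  = "missense",
  Frame_Shift_Del         = "frameshift",
  Frame_Shift_Ins         = "frameshift",
  Splice_Site             = "splice",
  Splice_Region           = "splice",
  In_Frame_Del            = "inframe_indel",
  In_Frame_Ins            = "inframe_indel",
  Silent                  = "synonymous"
)

maf_required_cols <- c(
  "Chromosome", "Start_Position", "Reference_Allele", "Tumor_Seq_Allele2",
  "t_ref_count", "t_alt_count", "Hugo_Symbol", "Variant_Classification",
  "Tumor_Sample_Barcode"
)

as_count <- function(x, what, path) {
  if (is.numeric(x)) {
    bad <- which(!is.na(x) & (x < 0 | x != floor(x)))
  } else {
    xn <- suppressWarnings(as.numeric(x))
    bad <- which(!is.na(x) & x != "" & (is.na(xn) | xn < 0 | xn != floor(xn)))
    x <- xn
  }
  if (length(bad) > 0) {
    abort(sprintf(
      "Non-integer or negative %s in '%s' at data row(s) %s",
      what, path, paste(head(bad, 5L), collapse = ", ")
    ))
  }
  as.integer(x)
}

#' Read somatic variant calls from a MAF file
#'
#' Reads a tab-separated MAF (TCGA dialect) and normalises it to the
#' internal variant table: one row per somatic call with `sample_id`,
#' `chrom`, `pos` (1-based), `ref`, `alt`, `ref_count`, `alt_count`,
#' `gene` and `effect` (see [effect_levels]). MAF
#' `Variant_Classification` values are mapped onto the effect classes;
#' unrecognised classes become `"noncoding"`.
#'
#' @param path Path to a MAF file. Lines starting with `#` are skipped.
#' @param missing_counts What to do with rows whose `t_ref_count` or
#'   `t_alt_count` is missing: `"error"` (default), `"drop"`, or `"keep"`
#'   (kept with `NA` counts; such variants are excluded from CCF
#'   estimation but still counted by [compute_tmb()]).
#' @return A tibble of variant calls.
#' @export
read_maf <- function(path, missing_counts = c("error", "drop", "keep")) {
  missing_counts <- match.arg(missing_counts)
  raw <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         progress = FALSE, col_types = readr::cols(.default = "c"))
  missing <- setdiff(maf_required_cols, names(raw))
  if (length(missing) > 0) {
    abort(sprintf("MAF '%s' is missing required column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  out <- tibble(
    sample_id = raw$Tumor_Sample_Barcode,
    chrom     = raw$Chromosome,
    pos       = as_count(raw$Start_Position, "Start_Position", path),
    ref       = raw$Reference_Allele,
    alt       = raw$Tumor_Seq_Allele2,
    ref_count = as_count(raw$t_ref_count, "t_ref_count", path),
    alt_count = as_count(raw$t_alt_count, "t_alt_count", path),
    gene      = raw$Hugo_Symbol,
    effect    = unname(maf_effect_map[raw$Variant_Classification])
  )
  out$effect[is.na(out$effect)] <- "noncoding"
  na_counts <- is.na(out$ref_count) | is.na(out$alt_count)
  if (any(na_counts)) {
    if (missing_counts == "error") {
      abort(sprintf("MAF '%s' has missing read counts at data row(s) %s",
                    path, paste(head(which(na_counts), 5L), collapse = ", ")))
    }
    if (missing_counts == "drop") out <- out[!na_counts, ]
  }
  validate_variants(out)
}

#' Write a variant table as MAF
#'
#' Inverse of [read_maf()]; a written table re-reads field-for-field.
#'
#' @param variants Variant tibble as returned by [read_maf()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_maf <- function(variants, path) {
  inv_map <- c(
    missense = "Missense_Mutation", nonsense = "Nonsense_Mutation",
    frameshift = "Frame_Shift_Del", splice = "Splice_Site",
    inframe_indel = "In_Frame_Del", synonymous = "Silent",
    noncoding = "Intron"
  )
  out <- tibble(
    Hugo_Symbol            = variants$gene,
    Chromosome             = variants$chrom,
    Start_Position         = variants$pos,
    Reference_Allele       = variants$ref,
    Tumor_Seq_Allele2      = variants$alt,
    Variant_Classification = unname(inv_map[variants$effect]),
    t_ref_count            = variants$ref_count,
    t_alt_count            = variants$alt_count,
    Tumor_Sample_Barcode   = variants$sample_id
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Read somatic variant calls from a VCF file
#'
#' Requires a per-sample `AD` (allelic depths) FORMAT field. Each ALT
#' allele of each record yields one variant call per sample: `AD[1]` is
#' the reference depth, `AD[1 + i]` the depth of the i-th ALT allele.
#' Gene and effect annotations are not parsed from VCF; both are `NA`
#' and must be supplied downstream if TMB is to be computed.
#'
#' @param path Path to a VCF (v4.x) file.
#' @return A tibble of variant calls (columns as in [read_maf()]).
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@gt) == 0 || ncol(v@gt) < 2) {
    abort(sprintf("VCF '%s' has no sample genotype columns", path))
  }
  fmt <- v@gt[, "FORMAT"]
  if (!all(vapply(strsplit(fmt, ":"), function(k) "AD" %in% k, logical(1)))) {
    abort(sprintf(
      "VCF '%s' lacks the AD FORMAT field on some records; supply allelic depths",
      path
    ))
  }
  ad <- vcfR::extract.gt(v, element = "AD")
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  samples <- colnames(ad)
  rows <- purrr::map_dfr(seq_len(nrow(fix)), function(i) {
    alts <- strsplit(fix$ALT[i], ",", fixed = TRUE)[[1]]
    purrr::map_dfr(samples, function(s) {
      depths <- suppressWarnings(as.integer(strsplit(ad[i, s], ",", fixed = TRUE)[[1]]))
      if (length(depths) < length(alts) + 1L || anyNA(depths)) {
        abort(sprintf("VCF '%s': malformed AD '%s' at record %d sample %s",
                      path, ad[i, s], i, s))
      }
      tibble(
        sample_id = s, chrom = fix$CHROM[i],
        pos = as.integer(fix$POS[i]),
        ref = fix$REF[i], alt = alts,
        ref_count = depths[1L], alt_count = depths[seq_along(alts) + 1L],
        gene = NA_character_, effect = NA_character_
      )
    })
  })
  validate_variants(rows)
}

validate_variants <- function(variants) {
  stopifnot(all(c("sample_id", "chrom", "pos", "ref", "alt",
                  "ref_count", "alt_count", "gene", "effect") %in% names(variants)))
  if (any(variants$pos < 1, na.rm = TRUE)) abort("Variant positions must be >= 1")
  same <- !is.na(variants$ref) & !is.na(variants$alt) & variants$ref == variants$alt
  if (any(same)) abort("Variants with ref == alt are not somatic calls")
  known <- is.na(variants$effect) | variants$effect %in% effect_levels
  if (!all(known)) {
    abort(sprintf("Unknown effect class(es): %s",
                  paste(unique(variants$effect[!known]), collapse = ", ")))
  }
  as_tibble(variants)
}

#' Read allele-specific copy-number segments
#'
#' Tab-separated file with columns `chrom`, `start`, `end` (1-based
#' inclusive), `major_cn`, `minor_cn`, `sample_id`. Segments of one
#' sample must not overlap.
#'
#' @param path Path to the segment file.
#' @return A validated tibble of segments with a `total_cn` column.
#' @export
read_segments <- function(path) {
  seg <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("chrom", "start", "end", "major_cn", "minor_cn", "sample_id")
  missing <- setdiff(need, names(seg))
  if (length(missing) > 0) {
    abort(sprintf("Segment file '%s' is missing column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  validate_segments(seg)
}

#' @rdname read_segments
#' @param segments A segment tibble to validate in place.
#' @export
validate_segments <- function(segments) {
  segments <- as_tibble(segments)
  segments$chrom <- as.character(segments$chrom)
  segments$start <- as.integer(segments$start)
  segments$end <- as.integer(segments$end)
  segments$major_cn <- as.integer(segments$major_cn)
  segments$minor_cn <- as.integer(segments$minor_cn)
  if (any(segments$start > segments$end)) abort("Segment start > end")
  if (any(segments$minor_cn < 0)) abort("Negative minor_cn")
  bad <- segments$major_cn < segments$minor_cn
  if (any(bad)) {
    abort(sprintf("major_cn < minor_cn at segment %s:%d-%d",
                  segments$chrom[bad][1], segments$start[bad][1],
                  segments$end[bad][1]))
  }
  ord <- segments %>%
    group_by(.data$sample_id, .data$chrom) %>%
    arrange(.data$start, .by_group = TRUE) %>%
    mutate(overlap = .data$start <= lag(.data$end, default = -1L)) %>%
    ungroup()
  if (any(ord$overlap)) {
    i <- which(ord$overlap)[1]
    abort(sprintf(
      "Overlapping segments for sample %s: %s:%d-%d overlaps %s:%d-%d",
      ord$sample_id[i], ord$chrom[i - 1], ord$start[i - 1], ord$end[i - 1],
      ord$chrom[i], ord$start[i], ord$end[i]
    ))
  }
  segments$total_cn <- segments$major_cn + segments$minor_cn
  segments
}

#' @rdname read_segments
#' @param segments Segment tibble.
#' @export
write_segments <- function(segments, path) {
  readr::write_tsv(
    segments[, c("chrom", "start", "end", "major_cn", "minor_cn", "sample_id")],
    path, progress = FALSE
  )
  invisible(path)
}

#' Read the clinical outcome table
#'
#' Tab-separated file with one row per patient: `patient_id`, `dcb`
#' (durable clinical benefit, 0/1), `orr` (objective response, 0/1),
#' `pfs_days` (> 0), `pfs_event` (1 = progression observed), `purity`
#' (tumor purity in (0, 1]).
#'
#' @param path Path to the clinical TSV.
#' @return A validated tibble keyed by `patient_id`.
#' @export
read_clinical <- function(path) {
  cl <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("patient_id", "dcb", "orr", "pfs_days", "pfs_event", "purity")
  missing <- setdiff(need, names(cl))
  if (length(missing) > 0) {
    abort(sprintf("Clinical file '%s' is missing column(s): %s",
                  path, paste(missing, collapse = ", ")))
  }
  validate_clinical(cl)
}

#' @rdname read_clinical
#' @param clinical A clinical tibble to validate in place.
#' @export
validate_clinical <- function(clinical) {
  clinical <- as_tibble(clinical)
  dup <- clinical$patient_id[duplicated(clinical$patient_id)]
  if (length(dup) > 0) {
    abort(sprintf("Duplicate patient_id: %s", paste(unique(dup), collapse = ", ")))
  }
  clinical$dcb <- as.logical(clinical$dcb)
  clinical$orr <- as.logical(clinical$orr)
  clinical$pfs_event <- as.logical(clinical$pfs_event)
  if (any(clinical$pfs_days <= 0)) abort("pfs_days must be > 0")
  if (any(clinical$purity <= 0 | clinical$purity > 1)) {
    abort("purity must lie in (0, 1]")
  }
  clinical
}

#' @rdname read_clinical
#' @export
write_clinical <- function(clinical, path) {
  out <- clinical[, c("patient_id", "dcb", "orr", "pfs_days", "pfs_event", "purity")]
  out$dcb <- as.integer(out$dcb)
  out$orr <- as.integer(out$orr)
  out$pfs_event <- as.integer(out$pfs_event)
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' Attach copy number to each variant
#'
#' Joins every variant to the copy-number segment containing its position
#' (1-based inclusive on both sides, matched within `sample_id`). Variants
#' not covered by any segment receive the configurable default, a diploid
#' prior of major 1 / minor 1.
#'
#' @param variants Variant tibble.
#' @param segments Validated segment tibble, or `NULL` to use the default
#'   everywhere.
#' @param default_major,default_minor Copy numbers assumed where no
#'   segment covers a variant.
#' @return `variants` with `major_cn`, `minor_cn`, `total_cn` and a
#'   logical `cn_default` column.
#' @export
lookup_cn <- function(variants, segments = NULL, default_major = 1L,
                      default_minor = 1L) {
  variants <- as_tibble(variants)
  if (is.null(segments) || nrow(segments) == 0) {
    variants$major_cn <- as.integer(default_major)
    variants$minor_cn <- as.integer(default_minor)
    variants$total_cn <- variants$major_cn + variants$minor_cn
    variants$cn_default <- TRUE
    return(variants)
  }
  seg <- segments[, c("sample_id", "chrom", "start", "end", "major_cn", "minor_cn")]
  out <- dplyr::left_join(
    variants, seg,
    by = join_by("sample_id", "chrom", between("pos", "start", "end"))
  )
  out$cn_default <- is.na(out$major_cn)
  out$major_cn <- if_else(out$cn_default, as.integer(default_major), out$major_cn)
  out$minor_cn <- if_else(out$cn_default, as.integer(default_minor), out$minor_cn)
  out$total_cn <- out$major_cn + out$minor_cn
  out$start <- NULL
  out$end <- NULL
  out
}
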