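Package: ithmark
Title: Intratumoral Heterogeneity Biomarkers for Immunotherapy Response
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates per-mutation cancer cell fractions from somatic variant
    calls, tumor purity and allele-specific copy number, classifies mutations
    as clonal or subclonal, and summarises each tumor by an intratumoral
    heterogeneity (ITH) statistic -- the subclonal fraction of its mutations --
    alongside tumor mutational burden (TMB). Provides a panel/ctDNA variant of
    the ITH statistic, threshold and quantile dichotomization of biomarkers,
    combined TMB-by-ITH strata, and the response and survival association
    layer used to evaluate ITH as an immune-checkpoint-inhibitor biomarker
    (Fisher exact tests, Kaplan-Meier medians, log-rank tests, Cox hazard
    ratios, interaction tests, Spearman correlation). Also implements a
    neoantigen quality score and a neoantigen fitness model (MHC presentation
    amplitude times T-cell recognition probability), and a synthetic-cohort
    generator with known clone structure and planted outcome effects for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    survival,
    stats,
    utils,
    Biostrings,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
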