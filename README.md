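# ithmark

Intratumoral heterogeneity (ITH) as an immunotherapy biomarker, from
single-region somatic variant calls.

Most advanced NSCLC patients do not benefit from anti-PD-(L)1 therapy,
and tumor mutational burden (TMB) alone is an incomplete predictor. A
tumor whose mutations are split across subclones presents each
neoantigen in only part of its cells, which weakens the T-cell
response even at high total burden. `ithmark` is for translational
oncology analysts who have per-patient somatic calls (MAF/VCF with
allelic depths), purity and allele-specific copy number, and a clinical
outcome table, and who want to quantify that heterogeneity and test it
as a response/survival biomarker.

The core statistic: each mutation's cancer cell fraction is

```
CCF = f (ρ·Ct + 2(1 − ρ)) / (ρ·m)
```

(`f` = VAF, `ρ` = purity, `Ct` = local total copy number, `m` =
multiplicity), with an exact Clopper–Pearson interval pushed through
the same map; mutations are classified clonal vs subclonal (interval or
point-threshold policy), and

```
ITH = n_subclonal / (n_clonal + n_subclonal)  ∈ [0, 1].
```

Around it the package provides TMB with nearest-rank dichotomization,
combined TMB×ITH strata (TMB-H, TMB-L&ITH-L, TMB-L&ITH-H), a ctDNA
panel variant of ITH (max-VAF normalisation, no purity/CN needed), the
full association layer (Fisher exact, Kaplan–Meier medians, log-rank,
Efron-tie Cox hazard ratios, TMB×ITH interaction, Spearman), a
neoantigen quality score and amplitude×recognition fitness model, and a
seeded synthetic-cohort generator with planted effects used to validate
every layer.

## Worked example

Everything is tibble-in / tibble-out and pipes; a full cohort run is
three calls:

```r
library(ithmark)

sim    <- simulate_cohort(cohort_config(), seed = 42)   # or read_maf()/read_clinical()
report <- run_pipeline(run_config(exome_mb = 30),
                       data = sim[c("variants", "segments", "clinical")])
report
#> ITH biomarker report: 69 patients (69 ITH-evaluable)
#>   cutoffs: ITH 0.45, TMB 3.53 mut/Mb (top 33%)
#>
#> -- ITH-L vs ITH-H --
#> Group comparison by ith_group (ITH-L vs ITH-H; n = 40 vs 29)
#>   DCB rate: 55.0% vs 13.8% (Fisher p = 0.000871)
#>   ORR:      42.5% vs 13.8% (Fisher p = 0.0162)
#>   mPFS:     170.1836 vs 66.11487 days (log-rank p = 0.00142)
#>   HR (ITH-H vs ITH-L): 2.32 [95% CI 1.37-3.95]
#>
#> -- TMB-H vs TMB-L --
#> ...
#> TMB x ITH interaction p = 0.32; ITH~TMB Spearman p = 0.70
```

Reading it: the simulated cohort plants a low-ITH advantage, and the
pipeline recovers it — patients below the 0.45 ITH cutoff have a
four-fold higher durable-clinical-benefit rate, a ~2.6× longer median
PFS, and a progression hazard ratio of 2.32 for the ITH-high group. The
large interaction p says the ITH effect is not a TMB artifact.
`tidy(report)` returns the per-patient biomarker table, `glance(report)`
the one-row cohort summary, and `autoplot()` on `compute_ith()` output
or on `report$associations$ith` draws the clonal-architecture and KM
figures. The methods vignette (`vignettes/ith-biomarkers.Rmd`) explains
the model, every tunable constant, and what the generator does and does
not emulate.

A thin CLI wrapper (`inst/cli/ith-biomarker.R`) exposes `simulate` and
`run` subcommands for shell use.

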