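# aise — allelic imbalance and super-enhancer analysis

`aise` is an R package for case/control regulatory-genomics analyses built
around **allelic imbalance** (AI): unequal read support for the two alleles at
a heterozygous SNP in chromatin-accessibility (ATAC-seq) or RNA data. Its
motivating use case is autoimmune-disease B-cell studies, where a risk variant
can show allele-specific chromatin accessibility and expression that changes
across B-cell developmental stages (rN → T3 → SM → DN), in the neighbourhood
of a cell-type-restricted super-enhancer. The package is aimed at analysts who
have variant tables, chromHMM segmentations, tag tracks, CpG methylation
counts and genotype dosages in hand and want a tested, reproducible pipeline
from QC to validated calls — plus a synthetic-data module so every stage can
be exercised with no data download.

## What it computes

**Discovery.** After a site/sample QC cascade (MQ < 20, QD < 2, FS > 50,
chains of ≥ 3 SNPs within 10 bp, het calls with GQ ≥ 15 and allelic depth
≥ 8, and ≥ 3 het samples per group), each SNP's allelic ratio
`AR = alt/(ref+alt)` is regressed on the disease code:

    AR_i = α + β·g_i + ε_i ,   g ∈ {0 = control, 1 = case}

so β̂ is the case−control difference in mean AR and its t-test equals the
pooled two-sample t-test. Per-dataset p-values are combined with Fisher's
method, `X² = −2·Σ ln pᵢ ~ χ²(2k)`, and a SNP is validated reciprocally iff
every per-dataset p < 0.05 and the combined p < 0.01, within a matched
cell-state stratum.

**Annotation.**

* Super-enhancers: maximal runs of exactly-abutting chromHMM enhancer-state
  segments (6_EnhG, 7_Enh) spanning ≥ 3 kb, with cross-epigenome specificity
  ranking.
* Activity: 50 bp-window tags-per-million (`TPM = count·10⁶/library`), ECDF/Q3
  summaries, per-group developmental-stage trend regressions with 95% CIs,
  and length-matched background sampling with add-one empirical p-values.
* Methylation: per-window site-mean CpG fractions (missing ≠ 0), stage
  trends, and methylation–accessibility Pearson correlation.
* Association: log-additive logistic OR with Wald 95% CI, conditional
  adjustment for index SNPs, two-SNP EM haplotype frequencies and
  posterior-weighted haplotype association, and LD `r² = D²/(pA qA pB qB)`.

## Worked example

```r
library(aise)

## two ATAC-style datasets, 10 cases / 10 controls, with AI planted at two
## SNPs (case allelic fraction 0.65 vs control 0.50)
cfg <- sim_config(seed = 2024L, n_snps = 40L, n_datasets = 2L,
                  n_case = 10L, n_control = 10L, cell_states = "rN",
                  planted_ai = data.frame(snp = c(3L, 17L),
                                          case_af = 0.65, control_af = 0.50))
d <- gen_allelic_dataset(cfg)
disc <- run_discovery(d$variants, d$annotations, pipeline_config())
head(disc$validated[, c("snp_id", "max_p_dataset", "p_combined", "fdr", "pass")], 4)
#>    snp_id max_p_dataset p_combined      fdr  pass
#>  snp00017      0.000181   1.84e-08 7.36e-07  TRUE
#>  snp00003      0.147847   2.33e-02 4.50e-01 FALSE
#>  snp00023      0.289979   4.34e-02 4.50e-01 FALSE
#>  snp00016      0.184278   5.56e-02 4.50e-01 FALSE
```

`snp00017` passes both gates (worst per-dataset p = 1.8×10⁻⁴, combined
p = 1.8×10⁻⁸). `snp00003` — the other planted SNP — misses the nominal
gate in one dataset in this particular draw (p = 0.15): at this effect size
the design's recovery rate is ≈ 90%, not 100%, and the null SNPs below it
are correctly rejected by the combined-p gate.

```r
## a 7 kb enhancer run planted in a chromHMM segmentation is called exactly
se_cfg <- sim_config(seed = 7L, planted_se = data.frame(start = 20000, length = 7000))
call_superenhancers(gen_segmentation(se_cfg))
#>  chrom start   end length_bp n_segments epigenome_id
#>   chrS 20000 27000      7000         18        E_SYN

## protective association (true per-allele OR 0.77) at n = 2,000
g <- gen_genotypes(sim_config(seed = 99L, n_individuals = 2000L,
                              maf = 0.25, assoc_effect = log(0.77)))
a <- additive_logistic(g$dosage[, 1], g$phenotype)
#> OR = 0.72 (95% CI 0.63-0.84), p = 1.22e-05, n = 2000
```

A command-line front end for the same workflow lives in
`inst/cli/pipeline.R` (`simulate | discover | annotate | all`, JSON config).

## Package layout

* `R/synthetic_data.R` — seeded generators for every input type
* `R/variant_qc.R` — site/sample filter cascade with audit log
* `R/allelic_imbalance.R` — AR, AI test, Fisher combination, validation
* `R/superenhancer.R` — segmentation parsing, SE calling, specificity
* `R/quantify.R` — window TPM, ECDF/Q3, trends, background sampling
* `R/methylation.R` — window methylation and trends
* `R/association.R` — logistic, conditional, EM haplotypes, LD r²
* `R/pipeline.R`, `inst/cli/pipeline.R` — orchestration and CLI
* `vignettes/allelic-imbalance-pipeline.Rmd` — models, assumptions, design
  choices and limitations
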