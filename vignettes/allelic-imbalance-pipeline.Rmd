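---
title: "Allelic imbalance and super-enhancer analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allelic imbalance and super-enhancer analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aise)
```

# Scope

`aise` implements a two-stage case/control analysis of regulatory variation
in chromatin-accessibility (ATAC-seq-style), RNA, bisulfite-methylation and
genotype data:

1. **Discovery** — find heterozygous SNPs whose allelic ratio differs between
   cases and controls in several independent datasets (allelic imbalance, AI),
   validated reciprocally across datasets.
2. **Annotation** — characterise the regulatory context: super-enhancers (SEs)
   from chromHMM segmentations, window-based activity and methylation across
   B-cell developmental stages, and genetic association of candidate SNPs.

The package consumes variant tables, segmentations, tag tracks, CpG counts and
dosage matrices; read alignment and variant calling are upstream and out of
scope. A synthetic-data module generates every input with the statistical
structure the analysis assumes, so the full pipeline is testable offline.

# The allelic-imbalance model

At a heterozygous SNP with ref/alt read depths $(r, a)$ the allelic ratio is
$AR = a/(r + a)$, oriented to the alt allele for every sample and dataset so
that effect signs are comparable. For each SNP (within a dataset and cell
state) we fit ordinary least squares of $AR$ on the disease code
$g \in \{0, 1\}$:

$$AR_i = \alpha + \beta g_i + \varepsilon_i .$$

With a single binary regressor, $\hat\beta$ is exactly the difference of group
means and the $t$-test on the slope is algebraically the pooled-variance
two-sample $t$-test; the test suite asserts this identity to $10^{-10}$
against `t.test()`. A linear (rather than logistic or count-based) model is
used deliberately: at the small per-group sample sizes the design targets
(3–10 het samples per group) it is the most stable choice, at the cost of
ignoring per-sample depth differences — a known limitation, discussed below.

Per-dataset p-values within a matched cell-state stratum are combined by
Fisher's method, $X^2 = -2\sum_k \ln p_k \sim \chi^2_{2k}$, and a SNP is
**validated** iff it was testable in every dataset, each per-dataset
$p < 0.05$, and the combined $p < 0.01$. Effect-direction concordance across
datasets is *not* required: AI can genuinely flip sign between resting-naive
and activated B cells, which is why combination is stratified by cell state
instead. Benjamini–Hochberg FDR over combined p-values is reported alongside
but never used for gating, matching the nominal-threshold design.

## Variant QC cascade

Sites are removed for mapping quality $< 20$, quality-by-depth $< 2$,
strand-bias score $> 50$ (a caller annotation, never recomputed), and for
membership in an SNP cluster. The cluster rule is interpreted as *chains*:
link consecutive sorted SNPs at most 10 bp apart and remove every member of a
chain of size $\ge 3$. For sorted positions this equals the transitive closure
of the pairwise 10 bp relation, so the rule is order-independent; the test
suite checks it against an independent closure-based re-evaluation.
Multiallelic sites are dropped with a warning. Per sample, a call qualifies if
heterozygous with genotype quality $\ge 15$ and allelic-depth sum $\ge 8$; the
depth rule uses `ref_depth + alt_depth` (not the caller's `DP`) because those
are the same counts the AR is built from. All boundaries are applied exactly
as stated: depth 8 and FS 50 pass, GQ 14 fails. A SNP is testable in a
dataset only with $\ge 3$ qualifying het cases *and* $\ge 3$ het controls.

# Super-enhancer calling

A chromHMM 15-state segmentation tiles the genome with 0-based half-open
intervals. An SE is a maximal run of segments whose state is an enhancer
state (6_EnhG, 7_Enh by default) and whose intervals abut exactly
(`next start == previous end`), with total span $\ge 3$ kb. "Contiguous" is
taken strictly: any intervening non-enhancer segment or coordinate gap breaks
the run. Real Roadmap segmentations are gap-free, so gap tolerance would only
mask malformed input; this choice is noted for any real-data reproduction
where dialects may differ. Both `7_Enh` and bare `E7` state labels parse.
Cross-epigenome specificity of a region is summarised by ranking epigenomes
on their enhancer-state bp overlapping the region and reporting the fraction
with any overlap.

The caller is verified against an independent oracle that expands
segmentations to per-bin state vectors and scans runs with `rle()`, on 1,000
random segmentations.

# Window quantification and trends

Regions are tiled into 50 bp windows; a tag (the 5' end of a read/fragment)
belongs to the half-open window containing it; window counts are scaled to
tags per million: $TPM = c \cdot 10^6 / L$ for library size $L$. TPM is not
additionally divided by window length — with constant 50 bp windows that is a
global scale factor with no effect on any comparison. Summaries use the
right-continuous ECDF and type-7 (linearly interpolated) quantiles, the
convention of the analysis environment the procedure originates from; Q3 of
the window TPM vector is the headline per-sample activity summary.

Developmental-stage trends fit OLS of a per-sample summary on the integer
stage index (configurable ordering, e.g. rN=0, T3=1, SM=2, DN=3 —
accessibility analyses may start at T3, methylation at rN), reported with a
95% CI per group. Exactly constant input returns slope 0 with $p = 1$ by
convention rather than a 0/0 failure.

**Background sampling.** The null for "is this region's activity pattern
special" draws 1,000 length-matched regions uniformly from the same
chromosome, excluding the query and any supplied intervals, and reports the
add-one empirical p-value $(1 + \#\{b \ge s\})/(N + 1)$. With discrete count
summaries, ties make this p-value *super-uniform* (conservative): the test
suite asserts super-uniformity always and two-sided calibration only on dense
tracks where the summary is near-continuous.

# Methylation

Per-window CpG methylation is the **unweighted site mean** of per-CpG
fractions `methylated/total` among CpGs meeting a coverage floor (default 1,
since no floor is prescribed); each CpG contributes one methylation *level*,
not one read. The read-weighted pooled alternative is available behind
`weighted = TRUE` for sensitivity analysis. Windows without qualifying CpGs
are missing (`NA`), never 0 — an unmeasured window is not an unmethylated
one, and the distinction is preserved through aggregation. Methylation–
accessibility coupling uses Pearson correlation of per-subtype means, as does
region–region correlation of activity.

# Genetic association

Single-marker tests fit a log-additive logistic model of case status on
effect-allele dosage (0/1/2) plus covariates; the per-allele odds ratio is
$e^{\hat\beta}$ with Wald 95% intervals — the standard GWAS reporting scale;
profile-likelihood intervals were deliberately not used. Complete or
quasi-complete separation raises an explicit error instead of returning a
diverged estimate. Missing dosages are handled complete-case per model.
Conditional analysis appends index-SNP dosages to the covariates and flags
near-collinearity ($r^2 > 0.99$) between the test SNP and any index SNP.

Two-SNP haplotype frequencies come from the standard EM over the four
haplotypes; only double heterozygotes are phase-ambiguous, with cis posterior
$p_{11}p_{00} / (p_{11}p_{00} + p_{10}p_{01})$. Convergence is declared when
the largest frequency change falls below $10^{-8}$ (cap 1,000 iterations);
the observed-data log-likelihood is recorded each iteration and asserted
non-decreasing. Haplotype association regresses case status on
posterior-expected haplotype dosages (each individual's four expected counts
sum to 2) against a baseline haplotype — by default the most frequent; the
reduced-risk-alleles convention is available via the `baseline` argument.
LD is $r^2 = D^2 / (p_A q_A p_B q_B)$ with $D$ from EM haplotype
frequencies, or the squared dosage correlation.

A subtlety worth recording: dosage-based and haplotype-based $r^2$ are equal
only in expectation on randomly paired haplotypes, because the dosage
covariance also absorbs the sampled inter-gametic disequilibrium. The exact
$10^{-6}$ agreement contract is therefore tested on *doubled haploids*
(each individual two copies of one haplotype), where phase is unambiguous and
the identity is algebraic.

# The synthetic-data generators

The generators state one fixed world; none of their defaults were chosen by
looking at test outcomes.

* **Allelic counts**: per het site, total depth is negative-binomial
  (mean 50, dispersion 10 — typical useful het-site coverage after the
  depth-8 floor) and the alt count beta-binomial with intra-class correlation
  $\rho$ (default 0.01; real allelic ATAC data are mildly overdispersed, and
  $\rho = 0$ recovers the binomial for calibration tests). Null SNPs use
  fraction 0.5 in both groups; planted SNPs use group-specific fractions,
  mirrored ($f \to 1-f$) in configured cell states to emulate the
  direction flip between resting-naive and activated B cells. Two datasets of
  10 cases / 10 controls per state is the default design scale.
* **Segmentation**: one synthetic chromosome `chrS` (no reference download),
  tiled gap-free in 200 bp multiples (the chromHMM bin), background states
  drawn from the 13 non-enhancer states so planted enhancer runs have exactly
  the requested span.
* **Window tracks**: Poisson counts with case mean
  $\mu_0 (1 + s \cdot \text{stage})$ and flat controls; library size fixed at
  $10^7$ tags.
* **Methylation**: binomial CpG counts with case fraction declining linearly
  per stage from 0.8; coverage Poisson(20) floored at 1.
* **Genotypes**: Hardy–Weinberg at the configured MAF; disease Bernoulli with
  log-additive effect; an optional second SNP at a requested $r^2$ via the
  implied haplotype frequencies.

What a green test does and does not establish: the generators reproduce the
*sampling distributions* the statistics assume (overdispersed allelic counts,
Poisson windows, HWE genotypes), so passing tests demonstrate the estimators
and gates behave as designed under that model. They do not emulate mapping
bias toward the reference allele, GC or fragment-length effects, linked-SNP
haplotype structure beyond two loci, population stratification, or spatially
correlated chromatin signal — so green tests say nothing about robustness to
those real-data pathologies.

# Numerical and interface choices

* Determinism: every generator evaluates under `with_seed()`, restoring the
  caller's RNG stream; identical configs give byte-identical outputs, and the
  pipeline writes a config hash (excluding the output path) into every report.
* Degenerate inputs: zero residual variance with zero slope gives $p = 1$;
  with nonzero slope the p-value is clamped to the smallest positive double
  so it stays in $(0, 1]$.
* Configuration is JSON (`jsonlite`), with the same schema and defaults as
  the in-code constructors; a schema validator rejects unknown fields.
* Test-suite scaling: a few Monte-Carlo properties run at reduced replicate
  counts in the per-module suites (e.g. 100 random segmentations) and at full
  stated scale in the acceptance suite (1,000 segmentations, 10,000 null
  SNPs, 1,000 coverage replicates); the background-uniformity check uses 200
  replicates of 99 draws to stay within the test-time budget.

# Known limitations

* The AI test ignores per-sample depth heterogeneity (each AR counts equally)
  and includes no covariates; with 3+ samples per group there is little power
  for anything richer, but confounding cannot be removed.
* No mapping-bias correction (WASP-style allele-aware realignment) — inputs
  are assumed already debiased or robust.
* Strict SE contiguity may split runs in segmentation dialects that contain
  tiny gaps.
* The background-sampling p-value is conservative under heavy ties.
* Wald intervals undercover slightly at very low minor-allele counts;
  acceptance tolerances account for this at the tested scales.
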