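---
title: "Partitioned polygenic scores: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioned polygenic scores: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(partprs)
```

# The problem

A polygenic score (PRS) summarizes a participant's burden of common risk
alleles for a trait — here a psychiatric disorder — as a weighted sum of
allele dosages, with weights taken from an external discovery GWAS. A
genome-wide PRS mixes signals of very different biology. When the question is
whether a *specific* biological pathway (for example the complement cascade
of innate immunity, whose genes cluster inside the MHC region of chromosome
6) carries the association between polygenic risk and a brain phenotype,
the score can instead be restricted to genomic compartments:

* **genome-wide** — every QC-passing variant;
* **genic** — variants within an asymmetric window around annotated genes;
* **intergenic** — the complement of the genic compartment;
* **gene-set** — genic variants restricted to a user-supplied gene list.

Because the MHC has famously extreme linkage disequilibrium (LD), every
compartment score is also recomputed with that region excised
(`chr6:25-35 Mb` in the human genome; configurable here). Comparing a
compartment score with its region-masked counterpart shows whether the
association survives outside the high-LD region — the central sensitivity
analysis this package automates.

# The scoring model

For participant $i$ with alt-allele dosages $g_{ij}$ and harmonized
per-allele weights $w_j$ (oriented so they count the discovery effect allele
on the alt-dosage scale), the raw score at p-value threshold $T$ over a
clumped variant set $S$ is

$$\mathrm{PRS}_i(S, T) = \sum_{j \in S,\; p_j \le T} w_j\, g_{ij}.$$

Scores are residualized on ancestry principal components and the genotyping
array indicator, then z-scored. Association models are ordinary least
squares of the standardized phenotype on the standardized score with sex,
age (linear) and scan site (categorical dummies) as covariates; the reported
effect size is the standardized beta with its two-tailed t-test p-value.
Multiple testing is handled by Bonferroni *families* that mirror the natural
table layouts: a single-compartment table of 5 thresholds x 4 tracts is a
family of 20 tests (threshold 0.0025), a three-compartment table is 60
(0.00083 after rounding), and a per-autosome scan over 22 autosomes x 4
tracts is 88. A sensitivity column (e.g. chromosome 6 minus the masked
region) is judged against the family threshold but never counted in the
family size.

## Pipeline stages and the parameters that matter

| Stage | Parameter | Default | Rationale |
|---|---|---|---|
| QC | MAF minimum | 0.05 | common-variant scores; strict `<` fails 0.04 |
| QC | HWE exact p minimum | 1e-6 | conventional hard filter |
| Gene windows | upstream / downstream | 35 kb / 10 kb | regulatory neighbourhood is larger upstream |
| Clumping | r² / window | 0.1 / 1 Mb | "r² ≤ 0.1 retained" convention; pairs at exactly 0.1 survive |
| Scoring | p-thresholds | 1e-5 … 0.1 | the conventional five-threshold series |
| Adjustment | PCs + array | first 15 + array | ancestry and platform artefacts |
| Phenotypes | outlier trim | ±3 SD, single pass, strict | see below |
| Local rg | eigen truncation | 0.99 cumulative variance | drops near-null LD components |

Three conventions deserve a note because the underlying field practice is
genuinely ambiguous, and each is exposed as a switch:

* **Strand-aware windows.** "35 kb upstream" is only meaningful relative to
  a gene's strand, so for a minus-strand gene the window extends 35 kb past
  its 3'-coordinate end. A `strand_aware = FALSE` mode applies the
  plus-strand convention to every gene, since some toolchains ignore strand.
* **Half-open region masks.** A mask `chrom:start-end` covers positions
  `start <= pos < end`, making adjacent masks non-overlapping and exactly
  tiling. The boundary convention is asserted in the tests.
* **Clumping tie-break.** Equal p-values are ordered by (chromosome,
  position) so output is deterministic; the greedy pass removes a neighbour
  only when r² strictly exceeds the threshold.

Harmonization matches variants by (chromosome, position) — synthetic ids are
arbitrary — flips the weight sign when the effect allele equals the
reference allele, drops allele pairs that do not match {ref, alt}, and
treats palindromic (A/T, C/G) pairs by the standard frequency rule: dropped
when the effect-allele frequency is in (0.4, 0.6), otherwise oriented by
comparing frequencies across the two files. Standardized scores are
invariant under relabeling ref/alt with dosage recoding $g \mapsto 2-g$
(the raw score changes only by a participant-constant offset), which the
test suite asserts.

Few-SNP scores (`snp_set_score`) support a GWAS-weighted mode — used for
"added-risk" scores over a handful of conditionally independent SNPs, and
for per-gene scores summed over genes — and a single-SNP risk-allele-count
mode, where the dosage is recoded to count the allele with positive oriented
weight. Per-gene scores default to the most inclusive threshold (0.1),
clumped within the gene window; this is a free choice exposed as
configuration, as the convention is not standardized.

## Phenotype preparation

Tract phenotypes arrive as left/right hemisphere values per measure (axonal
density and orientation dispersion per white-matter tract). Cleaning is:
flag values beyond ±3 SD of the column mean (mean and SD computed once on
the full column — a single, non-iterated pass — with a strict inequality, so
a value at exactly 3 SD survives); a participant flagged in *any*
hemisphere or measure of a tract is excluded for that whole tract; surviving
left/right pairs are averaged. Trimming before averaging follows the natural
reading of "excluded, then averaged"; under normality the expected exclusion
rate is $2\Phi(-3) \approx 0.27\%$, which the tests verify on 20,000
synthetic draws.

# Local heritability and local genetic correlation

To corroborate score-based results without the scoring machinery, the
package estimates per-LD-block heritability and cross-trait genetic
correlation directly from two sets of summary statistics plus reference
genotypes, in the spirit of local-correlation tools built on
quasi-independent LD blocks (~1 Mb; 2,495 such blocks genome-wide in the
human genome, so the univariate Bonferroni filter there is
$0.05/2495 \approx 2.004\times10^{-5}$).

The estimator is deliberately compact. For a block with LD matrix $R = U
\Lambda U^\top$ (from reference dosages), retain the leading components
covering 99% of the variance, and project the standardized marginal effects
$\hat\beta$ onto them: $w_k = u_k^\top \hat\beta / \sqrt{\lambda_k}$. Under
the null the $w_k$ are iid $N(0, 1/n)$, so a method-of-moments local
heritability is $\sum_k w_k^2 - K/n$, with a p-value from parametric
simulation of the null (default 10,000 draws). The local genetic covariance
of two traits with non-overlapping GWAS samples is $\sum_k w_{Ak} w_{Bk}$
(no noise correction on the cross term), and

$$\hat r_g = \frac{\sum_k w_{Ak} w_{Bk}}
  {\sqrt{(\sum w_{Ak}^2 - K/n_A)(\sum w_{Bk}^2 - K/n_B)}},$$

clipped to $[-1, 1]$. The clip also makes the self-correlation of a trait
with itself exactly 1 (the cross term keeps the noise the denominators
remove). p-values and confidence intervals come from parametric simulation
with the per-component signal variance set homogeneously to the estimated
$h^2/K$ — independent signals for the null, correlation fixed at the point
estimate for the CI. This inference is a simplification of the full
fixed-effects machinery of dedicated local-correlation software; declaring
overlapping GWAS samples is an error rather than silently wrong, because no
sampling-covariance correction is implemented. Blocks are defined by a
uniform tiling rule or an explicit table, and a merge directive collapses
the many blocks spanning a high-LD region into one, mirroring the
"MHC as a single block" sensitivity analysis.

# The synthetic cohort

Every stage is exercised end-to-end on generated data; nothing is
downloaded. The generator's defaults are the package's study conditions and
are not tuned per test.

**Genotypes.** Each chromosome is tiled by 1 Mb LD blocks of 20 SNPs.
Per block, two haplotypes per participant are drawn from a latent AR(1)
Gaussian and thresholded at the MAF quantile; the latent correlation is
calibrated by numerically inverting the thresholded-bivariate-normal
correlation so that adjacent-SNP dosage r² hits its target — 0.25 in
ordinary blocks and 0.8 inside the designated region (`chr2:8-18 Mb` of a
4 x 25 Mb genome, a 10 Mb stand-in for the MHC's width and LD grade). MAFs
within a block share a base frequency drawn from U(0.05, 0.5) with ±5%
jitter: tightly linked SNPs have similar frequencies, and widely different
MAFs would make high indicator correlations unattainable. LD decays with
SNP distance within a block and is ~0 across blocks.

**Annotation.** Non-overlapping 300 kb genes every 1.5 Mb with alternating
strands; the gene set takes four genes inside the designated region (echoing
the four complement genes inside the MHC) plus one member elsewhere, so
"in-set but outside the region" is a populated category.

**Architecture.** A point-normal model: inside the region, variants are
causal with probability `prop_causal` multiplied by `set_enrichment` for
gene-set variants (`Inf` = gene-set only); outside, with `prop_causal`.
The discovery-trait and phenotype effect vectors share region causal
variants with correlation `rho_traits` (default −0.5: risk alleles lower
the phenotype, matching the direction of reported SZ-axonal-density
associations). Effect vectors are rescaled so the realized genetic variance
equals the `h2` targets exactly (default 0.02 each for region and
background; the effect-size scale for this phenotype class is not
published, so these are free parameters chosen to be small but detectable
at n = 20,000). Summary statistics are generated analytically as
$R\beta + \varepsilon$, $\varepsilon \sim N(0, R/n)$ per block — exact
control of sampling noise without simulating a discovery cohort
(n = 100,000 by default). A fifth of rows are emitted ref-oriented and ~5%
of variants get palindromic allele pairs, so harmonization is exercised for
real.

**Phenotypes and covariates.** Tracts (CG, iFO, sL, Unc) share the genetic
component; axonal density carries it, orientation dispersion is genetically
null (covariates + noise only), matching the intended contrast. Left/right
hemisphere values are shared tract signal plus independent noise (shared
fraction 0.9). Covariates: sex (Bernoulli 0.5), age uniform on 45-81 years
(the cohort age span), site (3 levels), array (2 levels) and 15 N(0,1)
principal-component columns.

**What the generator does not emulate** — and hence what passing tests do
not certify about real data: population structure and ancestry gradients
(PCs here are pure noise), imputation uncertainty, realistic recombination
maps or allele-frequency spectra, the X chromosome, structural variation
(notably C4-type copy-number/HERV biology), genotyping batch artefacts, and
participant relatedness.

# Verification and problem sizes

The suite checks each stage against an independent oracle: greedy clumping
against a plain-loop re-implementation on 200 random instances of up to 200
variants; the HWE exact test against full factorial enumeration for every
genotype configuration up to n = 20; OLS associations against a
normal-equations + t-CDF oracle at 1e-10 and a 1,000-replicate null
simulation at n = 2,000 (type-I error within 0.05 ± 0.014); and scoring
against brute-force summation. The headline end-to-end property uses 20
synthetic cohorts of n = 20,000 with effects planted only on the designated
region's gene set: the gene-set and intergenic scores must reach family
significance (0.05/60), the region-masked gene-set score must lose it, the
gene-set score must beat a size-matched null gene set, and the per-autosome
intergenic scan must single out the region's chromosome — each in at least
90% of replicates. Local-correlation checks: planted local $r_g = 0.5$
recovered within ±0.1 (mean of 50 replicates at generous sample sizes),
null calibration of the univariate test over 1,000 blocks, and exact
self-correlation. These sizes keep the full suite reproducible on a single
CPU while leaving Monte-Carlo margins that the asserted tolerances respect.

# Known limitations

* LD for clumping and for the local estimators comes from the target cohort
  itself; no external reference panel is supported.
* Indels, multi-character alleles and build liftover are out of scope
  (multiallelic VCF records are skipped with a count).
* The local-rg inference is simulation-based and assumes non-overlapping
  GWAS samples; conditional/multivariate local models are not implemented.
* Mean-imputation of sporadic missing genotypes is the only missing-data
  strategy, appropriate for the imputed-array data this mirrors.
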