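# partprs — partitioned polygenic scores with gene-set restriction and region masking

`partprs` builds and evaluates polygenic scores (PRS) restricted to genomic
compartments. The motivating analysis asks whether the association between
polygenic risk for a psychiatric disorder and white-matter microstructure
(per-tract axonal density and orientation dispersion) is carried by genic,
intergenic, or pathway-specific variation — in particular by complement-
cascade genes clustered in the high-LD MHC region of chromosome 6 — rather
than by the genome-wide signal as a whole.

For participant $i$, harmonized per-allele weights $w_j$ from a discovery
GWAS and alt-allele dosages $g_{ij}$, the score over a clumped variant set
$S$ at p-value threshold $T$ is

$$\mathrm{PRS}_i(S, T) = \sum_{j \in S,\ p_j \le T} w_j\, g_{ij},$$

with $S$ drawn from one of four compartments — genome-wide, genic (35 kb
upstream / 10 kb downstream strand-aware gene windows), intergenic, or a
user-supplied gene set — each optionally recomputed after masking a named
region such as the MHC (`chr6:25-35 Mb`). Variants are QC-filtered
(MAF ≥ 0.05, HWE exact p ≥ 1e-6), greedily clumped within each compartment
(r² ≤ 0.1, 1 Mb), and scores are adjusted for 15 principal components plus
genotyping array and standardized. Associations are OLS with sex, age and
scan-site covariates on standardized outcome and predictor, under Bonferroni
test families that mirror the table layouts (20 / 60 / 88 tests). A
block-wise method-of-moments estimator of local heritability and local
genetic correlation corroborates score results directly from two summary-
statistics sets. A synthetic-cohort generator with calibrated blockwise LD
makes the whole pipeline testable without cohort data.

## Worked example

Simulate a cohort whose phenotype effects are planted entirely on a gene set
inside a 6 Mb high-LD region, then compare compartment scores:

```r
library(partprs)

co <- simulate_cohort(genome_spec(n_chromosomes = 2, chrom_length_bp = 10e6,
                                  special_region = "chr2:2000000-8000000",
                                  n_participants = 2000, seed = 7),
                      effect_spec(h2_region = 0.05, set_enrichment = Inf,
                                  rho_traits = -0.6, seed = 8))
part   <- partition_variants(co$genotypes, co$annotation$genes,
                             co$annotation$gene_sets,
                             mask_regions = list(MHC = "chr2:2000000-8000000"))
harm   <- harmonize(co$sumstats, co$genotypes)
scores <- build_score_series(co$genotypes, harm, part,
                             compartments = c("genome_wide", "complement",
                                              "intergenic"),
                             masks = list(MHC = "chr2:2000000-8000000"))

phen <- prepare_phenotypes(co$phenotypes)
d <- merge(merge(phen, co$covariates, by = "participant_id"),
           transform(as.data.frame(scores$adjusted),
                     participant_id = rownames(scores$adjusted)),
           by = "participant_id")
cols <- c("genome_wide_all_p0.1", "complement_all_p0.1",
          "intergenic_all_p0.1", "intergenic_MHC_p0.1")
res <- apply_bonferroni(
  do.call(rbind, lapply(cols, function(col)
    fit_association(d, "CG_axonal_density", col))),
  family = "demo")
res[, c("score", "beta", "se", "p", "significant")]
#>                  score   beta     se        p significant
#> 1 genome_wide_all_p0.1 -0.191 0.0220 1.00e-17        TRUE
#> 2  complement_all_p0.1 -0.194 0.0220 2.77e-18        TRUE
#> 3  intergenic_all_p0.1 -0.198 0.0220 4.20e-19        TRUE
#> 4  intergenic_MHC_p0.1 -0.084 0.0224 1.77e-04        TRUE
```

The gene-set score — 4 SNPs after clumping, versus 46 genome-wide — carries
the full association (standardized beta −0.194, i.e. one SD of score shifts
axonal density by a fifth of an SD, negative as planted via
`rho_traits = -0.6`). The intergenic score is equally strong because the
region's dense LD spreads the causal signal into neighbouring intergenic
variants, and masking the region attenuates it sharply (−0.198 → −0.084) —
the compartment/masking contrast the package exists to automate. The same
analysis runs from one config via `run_pipeline()`
(see `?run_pipeline` and `?write_cohort`), which also emits per-autosome
intergenic scans and the local genetic-correlation table.

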