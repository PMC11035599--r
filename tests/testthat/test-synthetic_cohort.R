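test_that("invalid specifications are rejected naming the offending field", {
  expect_error(genome_spec(maf_range = c(0, 0.6)), "maf_range")
  expect_error(genome_spec(n_chromosomes = 0), "n_chromosomes")
  expect_error(genome_spec(snps_per_block = 0), "snps_per_block")
  expect_error(genome_spec(special_region = "chr9:1-2000000"), "special_region")
  expect_error(genome_spec(special_region = "chr1:1-99000000"), "special_region")
  expect_error(effect_spec(h2_background = 0.6, h2_region = 0.5), "h2")
  expect_error(effect_spec(prop_causal = 0), "prop_causal")
  expect_error(effect_spec(rho_traits = -1.5), "rho_traits")
  expect_error(effect_spec(n_discovery = 5), "n_discovery")
})

test_that("dosages are valid hard calls and deterministic under the seed", {
  g1 <- tiny_cohort$genotypes
  expect_true(all(g1$dosage %in% 0:2))
  g2 <- simulate_genotypes(tiny_spec())
  expect_identical(g1$dosage, g2$dosage)
  expect_identical(g1$map, g2$map)
  g3 <- simulate_genotypes(tiny_spec(seed = 99))
  expect_false(identical(g1$dosage, g3$dosage))
})

test_that("within-block LD hits its target, decays with distance, and blocks are independent", {
  sp <- genome_spec(n_chromosomes = 1, chrom_length_bp = 3e6,
                    snps_per_block = 10, special_region = "chr1:1-1000000",
                    r2_special = 0.8, r2_within = 0.25,
                    n_participants = 5000, seed = 7)
  g <- simulate_genotypes(sp)
  r <- cor(g$dosage)
  # special block (variants 1-10): adjacent r2 near 0.8
  adj_special <- r[cbind(1:9, 2:10)]^2
  expect_lt(abs(mean(adj_special) - 0.8), 0.05)
  # ordinary blocks: adjacent r2 near 0.25
  adj_ord <- c(r[cbind(11:19, 12:20)]^2, r[cbind(21:29, 22:30)]^2)
  expect_lt(abs(mean(adj_ord) - 0.25), 0.05)
  # decay with distance inside the special block
  lag3 <- mean(r[cbind(1:7, 4:10)]^2)
  expect_lt(lag3, mean(adj_special))
  # across blocks r2 ~ 0
  expect_lt(mean(r[1:10, 11:20]^2), 0.01)

  # independence case: target r2 = 0
  sp0 <- genome_spec(n_chromosomes = 1, chrom_length_bp = 1e6,
                     snps_per_block = 2, special_region = "chr1:1-1000000",
                     r2_special = 0, r2_within = 0, n_participants = 5000,
                     seed = 3)
  g0 <- simulate_genotypes(sp0)
  expect_lt(cor(g0$dosage[, 1], g0$dosage[, 2])^2, 0.05)
})

test_that("allele frequencies track their spec MAF at n = 5000", {
  sp <- genome_spec(n_chromosomes = 1, chrom_length_bp = 2e6,
                    snps_per_block = 10, special_region = "chr1:1-1000000",
                    n_participants = 5000, seed = 11)
  g <- simulate_genotypes(sp)
  f <- alt_freq(g)
  maf <- pmin(f, 1 - f)
  expect_lt(max(abs(maf - g$map$maf_spec)), 0.02)
})

test_that("annotation yields contained, non-overlapping, stranded genes and a nested gene set", {
  anno <- tiny_cohort$annotation
  sp <- tiny_cohort$spec
  genes <- anno$genes
  expect_true(all(genes$strand %in% c("+", "-")))
  expect_true(all(genes$start < genes$end))
  for (ci in seq_along(sp$chroms)) {
    gc <- genes[genes$chrom == sp$chroms[ci], ]
    expect_true(all(gc$end <= sp$chrom_length_bp[ci]))
    expect_true(all(gc$start >= 0))
    if (nrow(gc) > 1)  # sorted, non-overlapping
      expect_true(all(gc$start[-1] >= gc$end[-nrow(gc)]))
  }
  set_ids <- anno$gene_sets$complement
  sg <- genes[genes$gene_id %in% set_ids, ]
  reg <- sp$special_region
  n_in <- sum(sg$chrom == reg$chrom & sg$start + 1 >= reg$start &
                sg$end <= reg$end)
  expect_gte(n_in, 2)
  expect_gte(nrow(sg) - n_in, 1)
  # a region too small to host the set is an error
  expect_error(
    simulate_annotation(genome_spec(special_region = "chr2:1000000-1500000")),
    "too small")
})

test_that("annotation files round-trip through the readers", {
  anno <- tiny_cohort$annotation
  bed <- withr::local_tempfile(fileext = ".bed")
  write_genes_bed(anno$genes, bed)
  back <- read_genes_bed(bed)
  expect_equal(back[order(back$gene_id), ],
               anno$genes[order(anno$genes$gene_id), ],
               ignore_attr = TRUE)
  gs <- withr::local_tempfile(fileext = ".txt")
  write_geneset(anno$gene_sets$complement, gs)
  expect_identical(read_geneset(gs), anno$gene_sets$complement)
})

test_that("null architecture gives uniform discovery p-values", {
  sp <- genome_spec(n_chromosomes = 1, chrom_length_bp = 50e6,
                    snps_per_block = 10, special_region = "chr1:1-5000000",
                    r2_within = 0.05, r2_special = 0.05,
                    n_participants = 400, seed = 21)
  g <- simulate_genotypes(sp)
  anno <- simulate_annotation(sp)
  eff <- effect_spec(h2_background = 0, h2_region = 0, seed = 5)
  ss <- simulate_discovery_sumstats(g, eff, anno, sp$special_region)
  expect_equal(nrow(ss), ncol(g$dosage))
  frac <- mean(ss$p < 0.05)
  expect_lt(abs(frac - 0.05), 0.02)  # 5000 variants, mild LD
})

test_that("a single strong causal variant dominates the summary statistics", {
  sp <- tiny_spec(seed = 31)
  g <- simulate_genotypes(sp)
  anno <- simulate_annotation(sp)
  eff <- effect_spec(h2_background = 0, h2_region = 0.3, prop_causal = 0.001,
                     set_enrichment = Inf, n_discovery = 1e6, seed = 6)
  ss <- simulate_discovery_sumstats(g, eff, anno, sp$special_region)
  truth <- attr(ss, "truth")
  expect_gte(sum(truth$causal), 1)
  top_block <- g$map$block[match(ss$snp[which.min(ss$p)], g$map$id)]
  expect_true(top_block %in% g$map$block[truth$causal])
})

test_that("summary statistics are byte-identical under the same seed", {
  sp <- tiny_spec(seed = 41)
  g <- simulate_genotypes(sp)
  anno <- simulate_annotation(sp)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(simulate_discovery_sumstats(g, effect_spec(seed = 9), anno,
                                             sp$special_region), f1)
  write_sumstats(simulate_discovery_sumstats(g, effect_spec(seed = 9), anno,
                                             sp$special_region), f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
})

test_that("null phenotypes are independent of genotype", {
  sp <- tiny_spec(seed = 51, n = 600)
  g <- simulate_genotypes(sp)
  anno <- simulate_annotation(sp)
  eff <- effect_spec(h2_background = 0, h2_region = 0, seed = 12)
  ph <- simulate_phenotypes(g, eff, anno, sp$special_region)
  y <- ph$phenotypes$CG_axonal_density_L
  p <- apply(g$dosage[, seq(1, 120, by = 2)], 2,
             function(col) cor.test(y, col)$p.value)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.07)
  expect_gt(min(p), 1e-5 / length(p))
})

test_that("realized variance decomposition and hemisphere sharing match the generator targets", {
  truth <- tiny_cohort$truth
  eff <- tiny_cohort$effects
  expect_lt(abs(var(truth$g_region) - eff$h2_region), 1e-8)
  expect_lt(abs(var(truth$g_background) - eff$h2_background), 1e-8)
  ph <- tiny_cohort$phenotypes
  r_lr <- cor(ph$CG_axonal_density_L, ph$CG_axonal_density_R)
  expect_gt(r_lr, 0.85)
  expect_lt(abs(r_lr - 0.9), 0.05)
  cov <- tiny_cohort$covariates
  expect_true(all(c("sex", "age", "site", "array", paste0("PC", 1:15))
                  %in% names(cov)))
  expect_true(all(cov$age >= 45 & cov$age <= 81))
  expect_true(all(cov$sex %in% 0:1))
  expect_error(simulate_phenotypes(tiny_cohort$genotypes, eff,
                                   tiny_cohort$annotation,
                                   tiny_cohort$spec$special_region,
                                   n_tracts = 0),
               "n_tracts")
})
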