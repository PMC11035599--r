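# Shared fixtures, built once per test run.

# small cohort: 2 chromosomes x 6 Mb, 10 SNPs per 1 Mb block, designated
# high-LD region on chr2
tiny_spec <- function(seed = 1, n = 400) {
  genome_spec(n_chromosomes = 2, chrom_length_bp = 6e6, snps_per_block = 10,
              special_region = "chr2:2000000-4000000", n_participants = n,
              seed = seed)
}

tiny_cohort <- simulate_cohort(tiny_spec(), effect_spec(seed = 2))

tiny_partition <- partition_variants(
  tiny_cohort$genotypes, tiny_cohort$annotation$genes,
  tiny_cohort$annotation$gene_sets,
  mask_regions = list(MHC = "chr2:2000000-4000000"))

tiny_harm <- suppressMessages(
  harmonize(tiny_cohort$sumstats, tiny_cohort$genotypes))

# build a genotype_matrix directly from a dosage matrix (one chromosome,
# evenly spaced positions unless given)
make_genotypes <- function(dosage, chrom = "chr1", pos = NULL,
                           ref = NULL, alt = NULL) {
  m <- ncol(dosage)
  map <- data.frame(id = paste0("v", seq_len(m)), chrom = chrom,
                    pos = pos %||% (seq_len(m) * 1000),
                    ref = ref %||% rep("A", m), alt = alt %||% rep("G", m),
                    stringsAsFactors = FALSE)
  genotype_matrix(dosage, map)
}

# harmonized-table literal for scoring tests
make_harmonized <- function(genotypes, weight, p = rep(0.5, length(weight))) {
  map <- genotypes$map
  out <- data.frame(id = map$id, col_index = seq_len(nrow(map)),
                    chrom = map$chrom, pos = map$pos, weight = weight, p = p,
                    stringsAsFactors = FALSE)
  class(out) <- c("harmonized", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
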