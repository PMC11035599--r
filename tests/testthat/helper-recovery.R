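# One replicate of the planted-architecture recovery experiment: a cohort of
# 20,000 with phenotype effects planted only on the designated region's gene
# set, scored and tested exactly as the pipeline does. Returns the per-score
# minimum p-values needed by the recovery checks.
recovery_replicate <- function(genome_seed, effect_seed) {
  sp <- genome_spec(seed = genome_seed)
  eff <- effect_spec(h2_background = 0, h2_region = 0.02,
                     set_enrichment = Inf, seed = effect_seed)
  co <- simulate_cohort(sp, eff)
  reg <- sp$special_region
  genes <- co$annotation$genes
  set_ids <- co$annotation$gene_sets$complement
  # matched null set: same number of genes, genic but away from the region
  pool <- genes$gene_id[!(genes$gene_id %in% set_ids) &
                          genes$chrom != reg$chrom]
  null_ids <- head(pool, length(set_ids))
  part <- partition_variants(
    co$genotypes, genes,
    gene_sets = list(complement = set_ids, nullset = null_ids),
    mask_regions = list(MHC = format_region_str(reg)))
  harm <- suppressMessages(harmonize(co$sumstats, co$genotypes))
  sc_covar <- co$covariates[match(rownames(co$genotypes$dosage),
                                  co$covariates$participant_id),
                            c(paste0("PC", 1:15), "array")]
  scores <- suppressMessages(build_score_series(
    co$genotypes, harm, part,
    compartments = c("genic", "intergenic", "complement", "nullset"),
    masks = list(MHC = format_region_str(reg)),
    score_covariates = sc_covar))
  phen <- prepare_phenotypes(co$phenotypes)
  d <- merge(phen, co$covariates, by = "participant_id")
  adj <- as.data.frame(scores$adjusted)
  adj$participant_id <- rownames(scores$adjusted)
  d <- merge(d, adj, by = "participant_id")
  tracts <- grep("axonal_density", names(phen), value = TRUE)
  min_p <- function(comp, mask) {
    cols <- scores$info$column[scores$info$compartment == comp &
                                 scores$info$mask == mask &
                                 scores$info$n_snps > 0]
    ps <- unlist(lapply(cols, function(cl)
      vapply(tracts, function(tr)
        fit_association(d, tr, cl)$p, 0)))
    if (!length(ps)) 1 else min(ps)
  }
  scan <- suppressMessages(per_chromosome_scan(
    co$genotypes, harm, part, d, outcomes = tracts, mask = "MHC",
    score_covariates = sc_covar))
  out <- list(
    p_complement = min_p("complement", "all"),
    p_intergenic = min_p("intergenic", "all"),
    p_complement_masked = min_p("complement", "MHC"),
    p_nullset = min_p("nullset", "all"),
    scan_sig_chroms = unique(scan$score[scan$significant & scan$in_family]),
    scan_masked_sig = any(scan$significant[scan$score ==
                                             paste0(reg$chrom, "-MHC")]))
  rm(co, part, harm, scores, d); gc(FALSE)
  out
}

format_region_str <- function(reg) {
  sprintf("%s:%s-%s", reg$chrom, format(reg$start, scientific = FALSE),
          format(reg$end, scientific = FALSE))
}
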