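## Variant QC and compartment labelling: genic / intergenic via strand-aware
## gene windows, gene-set membership, and named region masks (MHC-style).

#' Hardy-Weinberg exact test
#'
#' Two-sided exact test conditional on the observed allele counts: the
#' p-value sums the probabilities of all heterozygote counts whose
#' conditional probability does not exceed that of the observed
#' configuration.
#'
#' @param n_AA,n_Aa,n_aa genotype counts (non-negative, total >= 1).
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n < 1) stop("need at least one genotype")
  ## work with the minor allele
  n_minor <- 2 * n_aa + n_Aa
  if (n_minor > n) n_minor <- 2 * n - n_minor
  if (n_minor == 0) return(1)
  hets <- seq(n_minor %% 2, n_minor, by = 2)
  ## log conditional probability of x heterozygotes given allele counts
  logp <- lchoose(n, (n_minor - hets) / 2) +
    lchoose(n - (n_minor - hets) / 2, hets) + hets * log(2) -
    lchoose(2 * n, n_minor)
  ## normalize the combinatorial weights (lchoose form is proportional)
  w <- exp(logp - max(logp))
  pr <- w / sum(w)
  obs <- which(hets == n_Aa)
  if (!length(obs)) stop("heterozygote count has wrong parity for allele count")
  min(1, sum(pr[pr <= pr[obs] * (1 + 1e-12)]))
}

#' Variant QC on minor-allele frequency and Hardy-Weinberg equilibrium
#'
#' Fails variants with MAF below `maf_min` (strict) or HWE exact-test p-value
#' below `hwe_p_min`, computed from hard-call genotype counts (non-integer,
#' i.e. imputed, dosages are rounded for counting). Monomorphic variants fail
#' the MAF criterion.
#'
#' @param genotypes a [genotype_matrix()].
#' @param maf_min minimum minor-allele frequency (default 0.05).
#' @param hwe_p_min minimum HWE exact p (default 1e-6).
#' @return logical vector, `TRUE` = passes QC, named by variant id.
#' @export
qc_filter <- function(genotypes, maf_min = 0.05, hwe_p_min = 1e-6) {
  D <- genotypes$dosage
  f <- colMeans(D, na.rm = TRUE) / 2
  maf <- pmin(f, 1 - f)
  Dr <- if (is.integer(D) || all(D == floor(D), na.rm = TRUE)) D else round(D)
  n0 <- colSums(Dr == 0, na.rm = TRUE)
  n1 <- colSums(Dr == 1, na.rm = TRUE)
  n2 <- colSums(Dr == 2, na.rm = TRUE)
  hwe_p <- vapply(seq_len(ncol(D)), function(j)
    hwe_exact_test(n0[j], n1[j], n2[j]), 0)
  setNames(maf >= maf_min & hwe_p >= hwe_p_min, genotypes$map$id)
}

## strand-aware gene windows in 0-based half-open coordinates:
## + strand: [start - up, end + down); - strand: [start - down, end + up)
gene_windows <- function(genes, up_kb = 35, down_kb = 10, strand_aware = TRUE) {
  up <- up_kb * 1000; down <- down_kb * 1000
  plus <- if (strand_aware) genes$strand == "+" else rep(TRUE, nrow(genes))
  data.frame(chrom = genes$chrom,
             start = pmax(0, ifelse(plus, genes$start - up, genes$start - down)),
             end = ifelse(plus, genes$end + down, genes$end + up),
             gene_id = genes$gene_id, stringsAsFactors = FALSE)
}

## TRUE for each map row falling inside any gene window
genic_flags <- function(map, genes, up_kb = 35, down_kb = 10,
                        strand_aware = TRUE) {
  if (!nrow(genes)) return(rep(FALSE, nrow(map)))
  win <- gene_windows(genes, up_kb, down_kb, strand_aware)
  ## variants: 1-based pos; half-open 0-based windows become 1-based closed
  lev <- union(unique(map$chrom), unique(win$chrom))
  v <- GenomicRanges::GRanges(factor(map$chrom, lev),
                              IRanges::IRanges(map$pos, map$pos))
  w <- GenomicRanges::GRanges(factor(win$chrom, lev),
                              IRanges::IRanges(win$start + 1, win$end))
  hits <- GenomicRanges::countOverlaps(v, w)
  hits > 0
}

#' Label variants genic or intergenic using strand-aware gene windows
#'
#' A variant is genic iff it lies within `up_kb` upstream to `down_kb`
#' downstream of a gene, where upstream/downstream follow the gene's strand
#' (for a `+` gene the window is `[start - up, end + down)`; for a `-` gene
#' `[start - down, end + up)`). Variants on chromosomes without genes are
#' intergenic. Set `strand_aware = FALSE` to apply the upstream extension on
#' both sides regardless of strand.
#'
#' @param map variant map (data.frame with `chrom`, `pos`).
#' @param genes gene models (data.frame `gene_id`, `chrom`, `start`, `end`,
#'   `strand`; 0-based half-open).
#' @param up_kb,down_kb window sizes in kb (defaults 35 and 10).
#' @param strand_aware logical; see above.
#' @return character vector `"genic"`/`"intergenic"` per variant.
#' @export
annotate_genic <- function(map, genes, up_kb = 35, down_kb = 10,
                           strand_aware = TRUE) {
  ifelse(genic_flags(map, genes, up_kb, down_kb, strand_aware),
         "genic", "intergenic")
}

#' Flag variants inside a masked region
#'
#' The region is half-open on 1-based positions: a variant at `pos` is masked
#' iff `start <= pos < end` on the region's chromosome.
#'
#' @param map variant map (`chrom`, `pos`).
#' @param region region string `"chrom:start-end"` or parsed list.
#' @return logical vector per variant.
#' @export
apply_region_mask <- function(map, region) {
  in_region(map$chrom, map$pos, region)
}

#' Build the full variant partition
#'
#' Combines QC, genic/intergenic labels, per-set membership (set membership
#' implies genic by construction: the same windows restricted to set genes)
#' and named region-mask flags into one per-variant table.
#'
#' @param genotypes a [genotype_matrix()].
#' @param genes gene models data.frame.
#' @param gene_sets named list of gene-id vectors.
#' @param mask_regions named list/character vector of region strings, e.g.
#'   `c(MHC = "chr6:25000000-35000000")`.
#' @param maf_min,hwe_p_min QC thresholds (see [qc_filter()]).
#' @param up_kb,down_kb,strand_aware gene-window parameters
#'   (see [annotate_genic()]).
#' @return data.frame with one row per variant: `id`, `chrom`, `pos`,
#'   `qc_pass`, `compartment`, one logical `set_<name>` column per gene set,
#'   one logical `mask_<name>` column per region.
#' @export
partition_variants <- function(genotypes, genes, gene_sets = list(),
                               mask_regions = list(),
                               maf_min = 0.05, hwe_p_min = 1e-6,
                               up_kb = 35, down_kb = 10, strand_aware = TRUE) {
  map <- genotypes$map
  part <- data.frame(id = map$id, chrom = map$chrom, pos = map$pos,
                     stringsAsFactors = FALSE)
  part$qc_pass <- unname(qc_filter(genotypes, maf_min, hwe_p_min))
  part$compartment <- annotate_genic(map, genes, up_kb, down_kb, strand_aware)
  for (s in names(gene_sets)) {
    sg <- genes[genes$gene_id %in% gene_sets[[s]], , drop = FALSE]
    part[[paste0("set_", s)]] <- genic_flags(map, sg, up_kb, down_kb,
                                             strand_aware)
  }
  for (r in names(mask_regions)) {
    part[[paste0("mask_", r)]] <- apply_region_mask(map, mask_regions[[r]])
  }
  part
}

## variant-id selector for a (compartment, mask-state) cell of the partition
compartment_ids <- function(partition, compartment, mask = NULL) {
  keep <- partition$qc_pass
  keep <- keep & switch(
    compartment,
    genome_wide = TRUE,
    genic = partition$compartment == "genic",
    intergenic = partition$compartment == "intergenic",
    {
      col <- paste0("set_", compartment)
      if (!col %in% names(partition))
        stop("unknown compartment or gene set: ", compartment)
      partition[[col]]
    })
  if (!is.null(mask)) {
    col <- paste0("mask_", mask)
    if (!col %in% names(partition)) stop("unknown mask region: ", mask)
    keep <- keep & !partition[[col]]
  }
  partition$id[keep]
}
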