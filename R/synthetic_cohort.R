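## Synthetic cohort generator: genotypes with blockwise LD, gene annotation
## with a nested gene set inside a designated high-LD region, discovery-GWAS
## summary statistics from a point-normal architecture, and tract phenotypes
## with covariates. Everything is deterministic under the seed fields of
## genome_spec() and effect_spec().

#' Genome specification for the synthetic cohort
#'
#' Describes the simulated genome: chromosomes tiled by LD blocks, SNP density,
#' allele-frequency range, and one designated high-LD "MHC-like" region whose
#' geometry stands in for chr6:25-35 Mb.
#'
#' @param n_chromosomes number of chromosomes (named `chr1..chrK`).
#' @param chrom_length_bp chromosome length in bp (scalar, recycled, or one
#'   per chromosome).
#' @param block_length_bp mean LD-block length in bp (blocks tile each
#'   chromosome).
#' @param snps_per_block SNPs simulated per block.
#' @param maf_range length-2 vector of minor-allele-frequency bounds, within
#'   (0, 0.5].
#' @param special_region the designated high-LD region, `"chrom:start-end"`
#'   (half-open on 1-based positions).
#' @param r2_within target r-squared between adjacent SNPs in ordinary blocks.
#' @param r2_special target adjacent r-squared inside blocks overlapping
#'   `special_region` (elevated, emulating MHC-grade LD).
#' @param n_participants cohort size.
#' @param seed integer RNG seed.
#' @return validated list of class `genome_spec`.
#' @export
genome_spec <- function(n_chromosomes = 4,
                        chrom_length_bp = 25e6,
                        block_length_bp = 1e6,
                        snps_per_block = 20,
                        maf_range = c(0.05, 0.5),
                        special_region = "chr2:8000000-18000000",
                        r2_within = 0.25,
                        r2_special = 0.8,
                        n_participants = 20000,
                        seed = 1L) {
  if (!is.numeric(n_chromosomes) || n_chromosomes < 1)
    stop_field("n_chromosomes", "must be a positive count")
  n_chromosomes <- as.integer(n_chromosomes)
  chrom_length_bp <- rep_len(as.numeric(chrom_length_bp), n_chromosomes)
  if (any(chrom_length_bp <= 0)) stop_field("chrom_length_bp", "must be positive")
  if (block_length_bp <= 0) stop_field("block_length_bp", "must be positive")
  if (snps_per_block < 1) stop_field("snps_per_block", "must be a positive count")
  if (length(maf_range) != 2 || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2])
    stop_field("maf_range", "bounds must satisfy 0 < min <= max <= 0.5")
  region <- parse_region(special_region)
  chroms <- paste0("chr", seq_len(n_chromosomes))
  if (!region$chrom %in% chroms)
    stop_field("special_region", paste0("chromosome ", region$chrom,
                                        " not among ", paste(chroms, collapse = ",")))
  if (region$end > chrom_length_bp[match(region$chrom, chroms)] + 1)
    stop_field("special_region", "extends beyond its chromosome")
  for (f in c("r2_within", "r2_special")) {
    v <- get(f)
    if (v < 0 || v >= 1) stop_field(f, "must lie in [0, 1)")
  }
  if (n_participants < 2) stop_field("n_participants", "must be >= 2")
  structure(list(n_chromosomes = n_chromosomes,
                 chrom_length_bp = chrom_length_bp,
                 block_length_bp = block_length_bp,
                 snps_per_block = as.integer(snps_per_block),
                 maf_range = maf_range,
                 special_region = region,
                 r2_within = r2_within, r2_special = r2_special,
                 n_participants = as.integer(n_participants),
                 seed = as.integer(seed),
                 chroms = chroms),
            class = "genome_spec")
}

#' Genetic-architecture specification for the synthetic cohort
#'
#' The planted architecture mirrors the study's qualitative finding: phenotype
#' signal concentrated on causal variants inside the designated high-LD
#' region's gene set, on top of a thin polygenic background, with the
#' discovery trait's effect vector correlated with the phenotype's inside the
#' region.
#'
#' @param h2_background phenotype variance from the genome-wide polygenic
#'   background (outside the special region).
#' @param h2_region phenotype variance from causal variants inside the
#'   special region.
#' @param prop_causal fraction of variants causal.
#' @param set_enrichment multiplier on the causal probability for gene-set
#'   variants inside the region; `Inf` restricts region causals to the gene
#'   set entirely.
#' @param rho_traits correlation between the discovery-trait and phenotype
#'   effect vectors within the region, in `[-1, 1]`. Negative by default:
#'   higher polygenic burden, lower phenotype value.
#' @param covariate_betas named numeric: effects of `sex` (0/1), `age`
#'   (per year, centred at 63) and `site` (linear spread across sites) on
#'   every phenotype.
#' @param n_discovery discovery-GWAS sample size (controls sampling noise of
#'   the summary statistics).
#' @param seed integer seed for effect drawing and phenotype noise (kept
#'   separate from the genome seed so architectures can be varied on a fixed
#'   genome).
#' @return validated list of class `effect_spec`.
#' @export
effect_spec <- function(h2_background = 0.02,
                        h2_region = 0.02,
                        prop_causal = 0.05,
                        set_enrichment = 20,
                        rho_traits = -0.5,
                        covariate_betas = c(sex = 0.1, age = -0.005, site = 0.05),
                        n_discovery = 100000,
                        seed = 1L) {
  if (h2_background < 0 || h2_region < 0 || h2_background + h2_region > 1)
    stop_field("h2_background/h2_region", "must be >= 0 and sum to <= 1")
  if (prop_causal <= 0 || prop_causal > 1)
    stop_field("prop_causal", "must lie in (0, 1]")
  if (set_enrichment < 1) stop_field("set_enrichment", "must be >= 1")
  if (abs(rho_traits) > 1) stop_field("rho_traits", "must lie in [-1, 1]")
  if (n_discovery < 10) stop_field("n_discovery", "must be >= 10")
  structure(list(h2_background = h2_background, h2_region = h2_region,
                 prop_causal = prop_causal, set_enrichment = set_enrichment,
                 rho_traits = rho_traits, covariate_betas = covariate_betas,
                 n_discovery = n_discovery, seed = as.integer(seed)),
            class = "effect_spec")
}

## ---- latent-correlation calibration -------------------------------------
## Dosages are sums of two thresholded-Gaussian haplotypes; the indicator
## correlation induced by a latent correlation rho at thresholds t1, t2 is
## computed by one-dimensional integration, and inverted by uniroot so the
## generated dosage r2 matches the requested target.

.rho_cache <- new.env(parent = emptyenv())

threshold_corr <- function(rho, maf1, maf2) {
  t1 <- qnorm(1 - maf1); t2 <- qnorm(1 - maf2)
  if (abs(rho) < 1e-12) return(0)
  p11 <- integrate(function(x)
    dnorm(x) * pnorm((t2 - rho * x) / sqrt(1 - rho^2), lower.tail = FALSE),
    lower = t1, upper = Inf, rel.tol = 1e-9)$value
  (p11 - maf1 * maf2) / sqrt(maf1 * (1 - maf1) * maf2 * (1 - maf2))
}

latent_rho <- function(target_r, maf1, maf2) {
  if (target_r <= 0) return(0)
  key <- sprintf("%.3f|%.3f|%.3f", target_r, min(maf1, maf2), max(maf1, maf2))
  hit <- .rho_cache[[key]]
  if (!is.null(hit)) return(hit)
  upper <- 0.9995
  f <- function(rho) threshold_corr(rho, maf1, maf2) - target_r
  rho <- if (f(upper) <= 0) upper else uniroot(f, c(0, upper), tol = 1e-5)$root
  .rho_cache[[key]] <- rho
  rho
}

## ---- genotypes -----------------------------------------------------------

#' Simulate genotype dosages with blockwise LD
#'
#' Each LD block is generated from a latent AR(1) Gaussian per haplotype,
#' thresholded at the MAF quantile, so within-block LD decays with SNP
#' distance and adjacent-SNP r-squared matches the block's target
#' (`r2_within`, or `r2_special` inside the designated region). Blocks are
#' mutually independent.
#'
#' @param spec a [genome_spec()].
#' @return a [genotype_matrix()]; its map carries extra columns `block`
#'   (LD-block id) and `maf_spec` (the MAF each variant was simulated at).
#' @export
simulate_genotypes <- function(spec) {
  if (!inherits(spec, "genome_spec")) spec <- do.call(genome_spec, spec)
  withr::with_seed(spec$seed, {
    maps <- list(); dosages <- list(); blk <- 0L
    for (ci in seq_len(spec$n_chromosomes)) {
      chrom <- spec$chroms[ci]
      starts <- seq(1, spec$chrom_length_bp[ci], by = spec$block_length_bp)
      for (bs in starts) {
        blk <- blk + 1L
        blen <- min(spec$block_length_bp, spec$chrom_length_bp[ci] - bs + 1)
        m <- spec$snps_per_block
        pos <- bs - 1L + sort(sample.int(max(blen, m), m))
        ## SNPs on a shared haplotype background have similar frequencies;
        ## a common block MAF (small multiplicative jitter) also keeps the
        ## within-block r2 target attainable for thresholded indicators
        base_maf <- runif(1, spec$maf_range[1], spec$maf_range[2])
        maf <- pmin(spec$maf_range[2],
                    pmax(spec$maf_range[1], base_maf * runif(m, 0.95, 1.05)))
        special <- chrom == spec$special_region$chrom &&
          bs < spec$special_region$end && (bs + blen) > spec$special_region$start
        r2 <- if (special) spec$r2_special else spec$r2_within
        target_r <- sqrt(r2)
        ## calibration on 2-decimal MAFs: adjacent MAFs differ by < 10%, so
        ## the induced r2 error is well below the generator's tolerance,
        ## and the memoised grid stays small
        rhos <- if (m > 1)
          vapply(seq_len(m - 1), function(j)
            latent_rho(target_r, round(maf[j], 2), round(maf[j + 1], 2)), 0)
        else numeric(0)
        dos <- haplotype_pair(spec$n_participants, rhos, maf)
        ref <- sample(c("A", "C", "G", "T"), m, replace = TRUE)
        alt <- vapply(ref, pick_alt, "", USE.NAMES = FALSE)
        maps[[blk]] <- data.frame(
          id = sprintf("snp_%s_%d", chrom, pos), chrom = chrom, pos = pos,
          ref = ref, alt = alt, block = blk, maf_spec = maf,
          stringsAsFactors = FALSE)
        dosages[[blk]] <- dos
      }
    }
    map <- do.call(rbind, maps)
    genotype_matrix(do.call(cbind, dosages), map)
  })
}

## latent AR(1) haplotypes thresholded at the MAF quantile; dosage = h1 + h2
haplotype_pair <- function(n, rhos, maf) {
  m <- length(maf)
  thr <- qnorm(1 - maf)
  dos <- matrix(0L, n, m)
  for (h in 1:2) {
    z <- rnorm(n)
    dos[, 1] <- dos[, 1] + (z > thr[1])
    if (m > 1) for (j in 2:m) {
      z <- rhos[j - 1] * z + sqrt(1 - rhos[j - 1]^2) * rnorm(n)
      dos[, j] <- dos[, j] + (z > thr[j])
    }
  }
  dos
}

pick_alt <- function(ref) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")[[ref]]
  if (runif(1) < 0.05) comp else sample(setdiff(c("A", "C", "G", "T"), c(ref, comp)), 1)
}

## ---- annotation ----------------------------------------------------------

#' Simulate gene models and a nested gene set
#'
#' Genes are non-overlapping stranded intervals tiling each chromosome
#' (0-based half-open coordinates, BED convention). The gene set contains
#' several genes inside the designated region — mirroring a gene set whose
#' members cluster in the MHC — plus at least one member outside it.
#'
#' @param spec a [genome_spec()].
#' @param gene_length_bp length of each gene.
#' @param gene_spacing_bp distance between successive gene starts.
#' @param n_set_genes_region number of set genes placed inside the region
#'   (at least 2).
#' @param set_name name of the gene set.
#' @return list with `genes` (data.frame `gene_id`, `chrom`, `start`, `end`,
#'   `strand`; 0-based half-open) and `gene_sets` (named list of gene-id
#'   vectors).
#' @export
simulate_annotation <- function(spec, gene_length_bp = 3e5,
                                gene_spacing_bp = 1.5e6,
                                n_set_genes_region = 4,
                                set_name = "complement") {
  if (!inherits(spec, "genome_spec")) spec <- do.call(genome_spec, spec)
  genes <- list()
  for (ci in seq_len(spec$n_chromosomes)) {
    chrom <- spec$chroms[ci]
    starts <- seq(5e5, spec$chrom_length_bp[ci] - gene_length_bp,
                  by = gene_spacing_bp)
    genes[[ci]] <- data.frame(
      gene_id = sprintf("gene_%s_%d", chrom, seq_along(starts)),
      chrom = chrom,
      start = as.integer(starts),
      end = as.integer(starts + gene_length_bp),
      strand = rep_len(c("+", "-"), length(starts)),
      stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  reg <- spec$special_region
  inside <- genes$chrom == reg$chrom & genes$start + 1 >= reg$start &
    genes$end <= reg$end
  if (sum(inside) < 2)
    stop("special_region too small to host the gene set (needs >= 2 genes, has ",
         sum(inside), ")")
  k <- min(max(2, n_set_genes_region), sum(inside))
  picks <- which(inside)[unique(round(seq(1, sum(inside), length.out = k)))]
  outside <- which(!inside & !(genes$chrom == reg$chrom &
                                 genes$end + 35000 > reg$start - 35000 &
                                 genes$start < reg$end + 35000))
  if (!length(outside)) stop("no gene available outside the special region")
  set_ids <- c(genes$gene_id[picks], genes$gene_id[tail(outside, 1)])
  sets <- list(); sets[[set_name]] <- set_ids
  list(genes = genes, gene_sets = sets)
}

## ---- true effects --------------------------------------------------------

## Draw the point-normal architecture once (deterministic given
## effects$seed): causal indicators, discovery-trait and phenotype effect
## vectors on the standardized-dosage scale, rescaled so realized genetic
## variance hits the h2 targets exactly.
draw_true_effects <- function(genotypes, effects, annotation, special_region) {
  map <- genotypes$map
  m <- nrow(map)
  region <- parse_region(special_region)
  set_genes <- annotation$genes[
    annotation$genes$gene_id %in% unlist(annotation$gene_sets), , drop = FALSE]
  in_set <- genic_flags(map, set_genes)
  in_reg <- in_region(map$chrom, map$pos, region)
  withr::with_seed(effects$seed, {
    pr_reg <- rep(0, m)
    if (is.infinite(effects$set_enrichment)) {
      pr_reg[in_reg & in_set] <- min(1, effects$prop_causal * 10)
    } else {
      pr_reg[in_reg] <- pmin(1, effects$prop_causal *
                               ifelse(in_set[in_reg], effects$set_enrichment, 1))
    }
    causal_reg <- runif(m) < pr_reg
    if (effects$h2_region > 0 && !any(causal_reg)) {
      pool <- which(in_reg & in_set)
      if (!length(pool)) pool <- which(in_reg)
      causal_reg[sample(pool, 1)] <- TRUE
    }
    causal_bg <- !in_reg & runif(m) < effects$prop_causal
    if (effects$h2_background > 0 && !any(causal_bg))
      causal_bg[sample(which(!in_reg), 1)] <- TRUE

    b_disc <- b_phen <- rep(0, m)
    nr <- sum(causal_reg)
    if (nr) {
      z1 <- rnorm(nr)
      b_disc[causal_reg] <- z1
      b_phen[causal_reg] <- effects$rho_traits * z1 +
        sqrt(1 - effects$rho_traits^2) * rnorm(nr)
    }
    nb <- sum(causal_bg)
    if (nb) {
      b_disc[causal_bg] <- rnorm(nb)
      b_phen[causal_bg] <- rnorm(nb)
    }
    sds <- col_sds(genotypes$dosage)
    g_std <- function(idx, b) {
      if (!any(idx)) return(rep(0, nrow(genotypes$dosage)))
      X <- genotypes$dosage[, idx, drop = FALSE]
      X <- sweep(X, 2, colMeans(X)); X <- sweep(X, 2, sds[idx], "/")
      as.vector(X %*% b[idx])
    }
    rescale <- function(b, idx, g, h2) {
      v <- stats::var(g)
      if (h2 == 0 || v == 0) {
        b[idx] <- 0
        list(b = b, g = rep(0, length(g)))
      } else {
        s <- sqrt(h2 / v)
        b[idx] <- b[idx] * s
        list(b = b, g = g * s)
      }
    }
    ## phenotype scaling (the phenotype h2 targets)
    rp <- rescale(b_phen, causal_reg, g_std(causal_reg, b_phen), effects$h2_region)
    b_phen <- rp$b
    bp2 <- rescale(b_phen, causal_bg, g_std(causal_bg, b_phen), effects$h2_background)
    b_phen <- bp2$b
    ## discovery trait gets the same variance split on its own effect vector
    rd <- rescale(b_disc, causal_reg, g_std(causal_reg, b_disc),
                  max(effects$h2_region, 1e-12) * (effects$h2_region > 0))
    b_disc <- rd$b
    rd2 <- rescale(b_disc, causal_bg, g_std(causal_bg, b_disc),
                   max(effects$h2_background, 1e-12) * (effects$h2_background > 0))
    b_disc <- rd2$b
    list(beta_disc = b_disc, beta_phen = b_phen,
         causal = causal_reg | causal_bg, causal_region = causal_reg,
         causal_background = causal_bg, in_set = in_set, in_region = in_reg,
         g_region = rp$g, g_background = bp2$g, dosage_sd = sds)
  })
}

## ---- discovery summary statistics ---------------------------------------

#' Simulate discovery-GWAS summary statistics
#'
#' Marginal standardized effects are generated analytically as the
#' LD-convolution of the true joint effects (`R %*% beta` per block) plus
#' correlated sampling noise with per-variant variance `1/n_discovery`;
#' p-values follow from the implied z-scores. About a fifth of rows are
#' emitted with the effect allele set to the reference allele (effect sign
#' and frequency complemented) so downstream harmonization is exercised.
#'
#' @param genotypes a [genotype_matrix()] (provides the LD structure).
#' @param effects an [effect_spec()].
#' @param annotation output of [simulate_annotation()].
#' @param special_region the designated region (string or parsed).
#' @param truth optional pre-drawn effect architecture (as returned in the
#'   `truth` attribute); drawn from `effects$seed` when omitted.
#' @return a [sumstats()] data.frame with attribute `truth`.
#' @export
simulate_discovery_sumstats <- function(genotypes, effects, annotation,
                                        special_region, truth = NULL) {
  if (effects$n_discovery < 10) stop("n_discovery must be >= 10")
  if (is.null(truth))
    truth <- draw_true_effects(genotypes, effects, annotation, special_region)
  map <- genotypes$map
  n <- effects$n_discovery
  blocks <- map$block %||% rep(1L, nrow(map))
  withr::with_seed(effects$seed + 1L, {
    bhat <- numeric(nrow(map))
    for (b in unique(blocks)) {
      idx <- which(blocks == b)
      X <- genotypes$dosage[, idx, drop = FALSE]
      R <- stats::cor(X)
      mu <- as.vector(R %*% truth$beta_disc[idx])
      L <- chol(R + diag(1e-6, length(idx)))
      noise <- as.vector(t(L) %*% rnorm(length(idx))) / sqrt(n)
      bhat[idx] <- mu + noise
    }
    z <- bhat * sqrt(n)
    p <- pmax(2 * pnorm(-abs(z)), 1e-320)
    sdj <- truth$dosage_sd
    sdj[sdj == 0] <- 1
    beta_allele <- bhat / sdj
    freq <- alt_freq(genotypes)
    flip <- runif(nrow(map)) < 0.2
    ss <- data.frame(
      snp = map$id, chrom = map$chrom, pos = map$pos,
      a1 = ifelse(flip, map$ref, map$alt),
      a2 = ifelse(flip, map$alt, map$ref),
      beta = ifelse(flip, -beta_allele, beta_allele),
      p = p,
      freq = ifelse(flip, 1 - freq, freq),
      n = n, stringsAsFactors = FALSE)
  })
  out <- sumstats(ss)
  attr(out, "truth") <- truth
  out
}

## ---- phenotypes and covariates -------------------------------------------

#' Simulate tract phenotypes and covariates
#'
#' Each tract's axonal-density phenotype shares one genetic component
#' (region + background, from the phenotype effect vector) plus tract-specific
#' noise scaled so total non-covariate variance is 1; orientation dispersion
#' carries covariate effects and noise only. Left and right hemisphere values
#' are emitted separately as shared tract signal plus independent hemisphere
#' noise (shared variance fraction 0.9). Covariates: sex (0/1), age uniform on
#' 45-81 years, scan site (1-3), genotyping array (1-2) and 15 standard-normal
#' principal-component columns.
#'
#' @inheritParams simulate_discovery_sumstats
#' @param n_tracts number of tracts (>= 1); the first four are named
#'   `CG`, `iFO`, `sL`, `Unc`.
#' @return list with `phenotypes` (columns `<tract>_<measure>_<L|R>`),
#'   `covariates`, and `truth`.
#' @export
simulate_phenotypes <- function(genotypes, effects, annotation, special_region,
                                n_tracts = 4, truth = NULL) {
  if (n_tracts < 1) stop("n_tracts must be >= 1")
  if (is.null(truth))
    truth <- draw_true_effects(genotypes, effects, annotation, special_region)
  n <- nrow(genotypes$dosage)
  tracts <- c("CG", "iFO", "sL", "Unc",
              if (n_tracts > 4) sprintf("tract%d", 5:n_tracts))[seq_len(n_tracts)]
  withr::with_seed(effects$seed + 2L, {
    covar <- data.frame(
      participant_id = rownames(genotypes$dosage),
      sex = rbinom(n, 1, 0.5),
      age = runif(n, 45, 81),
      site = sample(1:3, n, replace = TRUE),
      array = sample(1:2, n, replace = TRUE),
      stringsAsFactors = FALSE)
    pcs <- matrix(rnorm(n * 15), n, 15,
                  dimnames = list(NULL, paste0("PC", 1:15)))
    covar <- cbind(covar, as.data.frame(pcs))
    cb <- effects$covariate_betas
    site_off <- (covar$site - 2) * (cb[["site"]] %||% 0)
    cov_contrib <- covar$sex * (cb[["sex"]] %||% 0) +
      (covar$age - 63) * (cb[["age"]] %||% 0) + site_off
    g <- truth$g_region + truth$g_background
    e_var <- max(0, 1 - effects$h2_region - effects$h2_background)
    phen <- data.frame(participant_id = covar$participant_id,
                       stringsAsFactors = FALSE)
    hemi_sd <- function(v) sqrt(stats::var(v) * (1 / 0.9 - 1))
    for (tr in tracts) {
      ad <- g + rnorm(n, sd = sqrt(e_var)) + cov_contrib
      od <- rnorm(n) + cov_contrib
      s_ad <- hemi_sd(ad); s_od <- hemi_sd(od)
      phen[[paste0(tr, "_axonal_density_L")]] <- ad + rnorm(n, sd = s_ad)
      phen[[paste0(tr, "_axonal_density_R")]] <- ad + rnorm(n, sd = s_ad)
      phen[[paste0(tr, "_orientation_dispersion_L")]] <- od + rnorm(n, sd = s_od)
      phen[[paste0(tr, "_orientation_dispersion_R")]] <- od + rnorm(n, sd = s_od)
    }
    list(phenotypes = phen, covariates = covar, truth = truth)
  })
}

## ---- one-call cohort ------------------------------------------------------

#' Simulate a complete synthetic cohort
#'
#' Convenience wrapper generating genotypes, annotation, discovery summary
#' statistics, covariates and tract phenotypes with one shared effect
#' architecture.
#'
#' @param spec a [genome_spec()] (or argument list).
#' @param effects an [effect_spec()] (or argument list).
#' @param n_tracts number of tracts.
#' @return list with `genotypes`, `annotation`, `sumstats`, `phenotypes`,
#'   `covariates`, `truth`, `spec`, `effects`.
#' @export
simulate_cohort <- function(spec = genome_spec(), effects = effect_spec(),
                            n_tracts = 4) {
  if (!inherits(spec, "genome_spec")) spec <- do.call(genome_spec, spec)
  if (!inherits(effects, "effect_spec")) effects <- do.call(effect_spec, effects)
  geno <- simulate_genotypes(spec)
  anno <- simulate_annotation(spec)
  truth <- draw_true_effects(geno, effects, anno, spec$special_region)
  ss <- simulate_discovery_sumstats(geno, effects, anno, spec$special_region,
                                    truth = truth)
  ph <- simulate_phenotypes(geno, effects, anno, spec$special_region,
                            n_tracts = n_tracts, truth = truth)
  list(genotypes = geno, annotation = anno, sumstats = ss,
       phenotypes = ph$phenotypes, covariates = ph$covariates,
       truth = truth, spec = spec, effects = effects)
}
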