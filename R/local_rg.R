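## Block-wise local heritability and bivariate local genetic correlation
## from summary statistics plus reference LD: eigendecomposition of the
## block LD matrix, projection of standardized marginal effects onto the
## retained components, method-of-moments estimates with simulation-based
## inference. A deliberately compact estimator in the spirit of local
## genetic correlation tools built on quasi-independent LD blocks.

#' Define LD blocks over a variant map
#'
#' @param map variant map (`id`, `chrom`, `pos`).
#' @param source either `"uniform:<bp>"` (tile each chromosome with fixed-
#'   width blocks, half-open on 1-based positions) or a data.frame / TSV path
#'   with columns `chrom`, `start`, `end` (optional `block_id`).
#' @return object of class `ld_blocks`: list with `blocks` (data.frame
#'   `block_id`, `chrom`, `start`, `end`) and `assignment` (named character
#'   vector, variant id -> block id; every variant assigned to exactly one
#'   block, variants outside all blocks to the nearest one, with a message).
#' @export
define_blocks <- function(map, source = "uniform:1000000") {
  if (is.character(source) && length(source) == 1 &&
      grepl("^uniform:", source)) {
    bp <- as.numeric(sub("^uniform:", "", source))
    if (!is.finite(bp) || bp <= 0) stop("bad uniform block width: ", source)
    blocks <- do.call(rbind, lapply(unique(map$chrom), function(ch) {
      pos <- map$pos[map$chrom == ch]
      idx <- 0:floor((max(pos) - 1) / bp)
      data.frame(block_id = sprintf("%s_b%d", ch, idx + 1), chrom = ch,
                 start = idx * bp + 1, end = (idx + 1) * bp + 1,
                 stringsAsFactors = FALSE)
    }))
  } else {
    blocks <- if (is.character(source))
      data.table::fread(source, sep = "\t", data.table = FALSE,
                        colClasses = list(character = "chrom"))
    else as.data.frame(source, stringsAsFactors = FALSE)
    if (!all(c("chrom", "start", "end") %in% names(blocks)))
      stop("block source needs columns chrom, start, end")
    if (!"block_id" %in% names(blocks))
      blocks$block_id <- sprintf("%s_b%d", blocks$chrom,
                                 stats::ave(seq_len(nrow(blocks)),
                                            blocks$chrom, FUN = seq_along))
  }
  blocks <- blocks[, c("block_id", "chrom", "start", "end")]
  assignment <- rep(NA_character_, nrow(map))
  n_outside <- 0L
  for (ch in unique(map$chrom)) {
    vi <- which(map$chrom == ch)
    bl <- blocks[blocks$chrom == ch, , drop = FALSE]
    if (!nrow(bl)) next
    for (v in vi) {
      hit <- which(map$pos[v] >= bl$start & map$pos[v] < bl$end)
      if (length(hit)) {
        assignment[v] <- bl$block_id[hit[1]]
      } else {
        n_outside <- n_outside + 1L
        d <- pmax(bl$start - map$pos[v], map$pos[v] - (bl$end - 1), 0)
        assignment[v] <- bl$block_id[which.min(d)]
      }
    }
  }
  if (anyNA(assignment))
    stop("variant(s) on chromosome(s) with no blocks: ",
         paste(unique(map$chrom[is.na(assignment)]), collapse = ", "))
  if (n_outside)
    message("define_blocks: ", n_outside,
            " variant(s) outside all blocks assigned to the nearest block")
  structure(list(blocks = blocks,
                 assignment = setNames(assignment, map$id)),
            class = "ld_blocks")
}

#' Merge named blocks into a single block
#'
#' Collapses the listed blocks (same chromosome) into one spanning their
#' union — e.g. treating the many blocks tiling the MHC as a single block.
#'
#' @param x an `ld_blocks` object.
#' @param block_ids blocks to merge.
#' @param new_id id of the merged block (default `<first>_merged`).
#' @return the modified `ld_blocks` object.
#' @export
merge_blocks <- function(x, block_ids, new_id = NULL) {
  b <- x$blocks
  sel <- b$block_id %in% block_ids
  if (sum(sel) < 2) stop("need at least two existing blocks to merge")
  if (length(unique(b$chrom[sel])) != 1)
    stop("cannot merge blocks across chromosomes")
  new_id <- new_id %||% paste0(b$block_id[sel][1], "_merged")
  merged <- data.frame(block_id = new_id, chrom = b$chrom[sel][1],
                       start = min(b$start[sel]), end = max(b$end[sel]),
                       stringsAsFactors = FALSE)
  x$blocks <- rbind(b[!sel, , drop = FALSE], merged)
  x$assignment[x$assignment %in% block_ids] <- new_id
  x
}

#' Read/write a block list as TSV
#' @param x an `ld_blocks` object (write) — only the block table round-trips;
#'   re-derive assignments with [define_blocks()].
#' @param path TSV path.
#' @export
write_blocks <- function(x, path) {
  data.table::fwrite(x$blocks, path, sep = "\t")
  invisible(path)
}

#' @rdname write_blocks
#' @export
read_blocks_tsv <- function(path) {
  data.table::fread(path, sep = "\t", data.table = FALSE,
                    colClasses = list(character = c("block_id", "chrom")))
}

## ---- projections ----------------------------------------------------------

## standardized marginal effects for the given genotype columns, from a
## harmonized table (oriented per-allele weights x dosage SD)
std_effects <- function(harmonized, genotypes, col_index) {
  w <- harmonized$weight[match(col_index, harmonized$col_index)]
  if (anyNA(w)) stop("sumstats do not cover all block variants")
  w * col_sds(genotypes$dosage[, col_index, drop = FALSE])
}

## eigenbasis of a block's reference LD matrix, truncated at cumulative
## variance cum_var
block_eigen <- function(genotypes, col_index, cum_var = 0.99) {
  if (length(col_index) < 2) stop("block needs >= 2 variants")
  R <- stats::cor(genotypes$dosage[, col_index, drop = FALSE])
  e <- eigen(R, symmetric = TRUE)
  lam <- pmax(e$values, 0)
  K <- which(cumsum(lam) / sum(lam) >= cum_var)[1]
  if (is.na(K) || K < 1) stop("all LD components truncated")
  list(U = e$vectors[, seq_len(K), drop = FALSE], lambda = lam[seq_len(K)],
       K = K)
}

## project standardized marginal effects onto the retained components; under
## the null the projections are iid N(0, 1/n)
project_effects <- function(eig, b_std) {
  as.vector(crossprod(eig$U, b_std)) / sqrt(eig$lambda)
}

#' Local heritability of one LD block
#'
#' Method-of-moments estimate from summary statistics and reference LD:
#' the block LD matrix is eigendecomposed, components up to a cumulative-
#' variance fraction `cum_var` retained, standardized marginal effects
#' projected onto them, and the estimate is the summed squared projections
#' minus the expected sampling noise `K/n`. The p-value is obtained by
#' parametric simulation under the null (projections iid `N(0, 1/n)`).
#'
#' @param block_ids variant ids of the block.
#' @param harmonized [harmonize()]d summary statistics for the trait
#'   (oriented against `genotypes`).
#' @param genotypes reference [genotype_matrix()].
#' @param n GWAS sample size for the trait.
#' @param cum_var eigen-truncation fraction (default 0.99).
#' @param nsim null simulations for the p-value (default 10000).
#' @return list: `h2`, `p`, `K` (retained components), `n_var`.
#' @export
local_h2 <- function(block_ids, harmonized, genotypes, n, cum_var = 0.99,
                     nsim = 10000) {
  ci <- harmonized$col_index[harmonized$id %in% block_ids]
  if (length(ci) < 2) stop("block has < 2 variants after sumstats overlap")
  eig <- block_eigen(genotypes, ci, cum_var)
  w <- project_effects(eig, std_effects(harmonized, genotypes, ci))
  obs <- sum(w^2) - eig$K / n
  null <- colSums(matrix(rnorm(eig$K * nsim, sd = 1 / sqrt(n)),
                         eig$K, nsim)^2) - eig$K / n
  p <- (1 + sum(null >= obs)) / (nsim + 1)
  list(h2 = obs, p = p, K = eig$K, n_var = length(ci))
}

#' Bivariate local genetic correlation of one LD block
#'
#' Local genetic covariance is the cross-product of the two traits'
#' projected effects (no noise-correction term: GWAS samples are assumed
#' non-overlapping; declaring overlap is an error); `rg` is the covariance
#' over the geometric mean of the noise-corrected local heritabilities,
#' clipped to `[-1, 1]`. The p-value simulates the null of independent
#' per-component signals at the estimated heritabilities; the confidence
#' interval simulates at the estimated correlation.
#'
#' @param block_ids variant ids of the block.
#' @param harmonized_a,harmonized_b [harmonize()]d summary statistics of the
#'   two traits (both oriented against `genotypes`).
#' @param genotypes reference [genotype_matrix()].
#' @param n_a,n_b GWAS sample sizes.
#' @param cum_var eigen-truncation fraction.
#' @param nsim simulations for p-value and CI.
#' @param sample_overlap must be `FALSE`; the estimator has no
#'   sampling-covariance correction.
#' @return list: `h2_a`, `h2_b`, `cov`, `rg` (`NA` when either heritability
#'   estimate is non-positive), `ci` (length-2), `p`, `K`.
#' @export
local_rg_bivariate <- function(block_ids, harmonized_a, harmonized_b,
                               genotypes, n_a, n_b, cum_var = 0.99,
                               nsim = 10000, sample_overlap = FALSE) {
  if (isTRUE(sample_overlap))
    stop("overlapping GWAS samples are not supported by this estimator")
  ci_a <- harmonized_a$col_index[harmonized_a$id %in% block_ids]
  ci_b <- harmonized_b$col_index[harmonized_b$id %in% block_ids]
  ci <- intersect(ci_a, ci_b)
  if (length(ci) < 2) stop("block has < 2 variants shared by both sumstats")
  eig <- block_eigen(genotypes, ci, cum_var)
  wa <- project_effects(eig, std_effects(harmonized_a, genotypes, ci))
  wb <- project_effects(eig, std_effects(harmonized_b, genotypes, ci))
  K <- eig$K
  h2a <- sum(wa^2) - K / n_a
  h2b <- sum(wb^2) - K / n_b
  cv <- sum(wa * wb)
  if (h2a <= 0 || h2b <= 0)
    return(list(h2_a = h2a, h2_b = h2b, cov = cv, rg = NA_real_,
                ci = c(NA_real_, NA_real_), p = NA_real_, K = K))
  rg <- max(-1, min(1, cv / sqrt(h2a * h2b)))
  sim_rg <- function(rho) {
    a <- matrix(rnorm(K * nsim, sd = sqrt(h2a / K)), K, nsim)
    z <- matrix(rnorm(K * nsim, sd = sqrt(h2b / K)), K, nsim)
    b <- rho * sqrt(h2b / h2a) * a + sqrt(1 - rho^2) * z
    wa_s <- a + matrix(rnorm(K * nsim, sd = 1 / sqrt(n_a)), K, nsim)
    wb_s <- b + matrix(rnorm(K * nsim, sd = 1 / sqrt(n_b)), K, nsim)
    h2a_s <- colSums(wa_s^2) - K / n_a
    h2b_s <- colSums(wb_s^2) - K / n_b
    r <- colSums(wa_s * wb_s) / sqrt(pmax(h2a_s * h2b_s, 1e-12))
    pmax(-1, pmin(1, r[h2a_s > 0 & h2b_s > 0]))
  }
  null <- sim_rg(0)
  p <- (1 + sum(abs(null) >= abs(rg))) / (length(null) + 1)
  ci_draws <- sim_rg(rg)
  ci_est <- unname(stats::quantile(ci_draws, c(0.025, 0.975), na.rm = TRUE))
  list(h2_a = h2a, h2_b = h2b, cov = cv, rg = rg, ci = ci_est, p = p, K = K)
}

#' Genome-wide local-rg scan over all blocks
#'
#' Runs [local_h2()] for both traits on every block, applies the univariate
#' Bonferroni filter at `alpha / n_blocks` (both traits must pass), runs
#' [local_rg_bivariate()] on the surviving blocks, and Bonferroni-corrects
#' the bivariate p-values over the tested blocks.
#'
#' @param blocks an `ld_blocks` object.
#' @param harmonized_a,harmonized_b harmonized summary statistics.
#' @param genotypes reference [genotype_matrix()].
#' @param n_a,n_b GWAS sample sizes.
#' @param alpha family-wise error rate (default 0.05).
#' @param cum_var,nsim passed through.
#' @return data.frame, one row per block: heritabilities with p-values,
#'   and — for blocks passing both filters — `rg`, CI bounds, `p_rg`,
#'   `rg_significant`.
#' @export
local_rg_scan <- function(blocks, harmonized_a, harmonized_b, genotypes,
                          n_a, n_b, alpha = 0.05, cum_var = 0.99,
                          nsim = 10000) {
  ids_by_block <- split(names(blocks$assignment), blocks$assignment)
  bl <- blocks$blocks
  uni_thr <- bonferroni_threshold(nrow(bl), alpha)
  rows <- lapply(bl$block_id, function(bid) {
    vids <- ids_by_block[[bid]]
    base <- data.frame(block_id = bid, n_var = length(vids),
                       h2_a = NA_real_, p_a = NA_real_, h2_b = NA_real_,
                       p_b = NA_real_, rg = NA_real_, ci_lo = NA_real_,
                       ci_hi = NA_real_, p_rg = NA_real_,
                       tested = FALSE, stringsAsFactors = FALSE)
    if (length(vids) < 2) return(base)
    ha <- try(local_h2(vids, harmonized_a, genotypes, n_a, cum_var, nsim),
              silent = TRUE)
    hb <- try(local_h2(vids, harmonized_b, genotypes, n_b, cum_var, nsim),
              silent = TRUE)
    if (inherits(ha, "try-error") || inherits(hb, "try-error")) return(base)
    base$h2_a <- ha$h2; base$p_a <- ha$p
    base$h2_b <- hb$h2; base$p_b <- hb$p
    if (ha$p < uni_thr && hb$p < uni_thr) {
      bv <- local_rg_bivariate(vids, harmonized_a, harmonized_b, genotypes,
                               n_a, n_b, cum_var, nsim)
      base$rg <- bv$rg; base$ci_lo <- bv$ci[1]; base$ci_hi <- bv$ci[2]
      base$p_rg <- bv$p; base$tested <- TRUE
    }
    base
  })
  res <- do.call(rbind, rows)
  m <- sum(res$tested)
  res$rg_significant <- res$tested & !is.na(res$p_rg) &
    res$p_rg < bonferroni_threshold(max(m, 1), alpha)
  attr(res, "univariate_threshold") <- uni_thr
  res
}
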