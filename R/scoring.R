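## Score construction: per-compartment / per-threshold PRS, covariate
## adjustment + standardization, few-SNP added-risk and per-gene scores.

#' Compute a raw polygenic score
#'
#' `score_i = sum_j w_j g_ij` over the retained variants whose discovery
#' p-value passes the threshold, with `w` the harmonized (oriented,
#' per-allele) weights and `g` the alt-allele dosage. An empty selection
#' yields an all-`NA` vector with `n_snps = 0` (reported, not an error).
#'
#' @param harmonized a [harmonize()] table.
#' @param genotypes a [genotype_matrix()].
#' @param retained_ids variant ids retained by clumping (defaults to all
#'   harmonized variants).
#' @param p_threshold include variants with discovery `p <= p_threshold`.
#' @return numeric vector (one value per participant) with attribute
#'   `n_snps`.
#' @export
compute_prs <- function(harmonized, genotypes, retained_ids = NULL,
                        p_threshold = 1) {
  sel <- harmonized$p <= p_threshold
  if (!is.null(retained_ids)) sel <- sel & harmonized$id %in% retained_ids
  if (!any(sel)) {
    message("compute_prs: no variants pass p <= ", p_threshold,
            "; emitting missing column")
    out <- rep(NA_real_, nrow(genotypes$dosage))
    attr(out, "n_snps") <- 0L
    return(out)
  }
  idx <- harmonized$col_index[sel]
  w <- harmonized$weight[sel]
  out <- as.vector(genotypes$dosage[, idx, drop = FALSE] %*% w)
  names(out) <- rownames(genotypes$dosage)
  attr(out, "n_snps") <- sum(sel)
  out
}

#' Adjust a raw score for covariates and standardize
#'
#' Residualizes the raw score on the supplied covariates (by default the
#' first 15 principal components plus the genotyping-array indicator, with an
#' intercept) via OLS, then z-scores the residual. With no covariates the
#' score is simply z-scored.
#'
#' @param score raw score vector.
#' @param covariates data.frame of adjustment covariates (numeric columns
#'   used as-is; character/factor columns expanded to dummies), or `NULL`.
#' @return standardized adjusted score (mean 0, variance 1).
#' @export
adjust_and_standardize <- function(score, covariates = NULL) {
  if (all(is.na(score))) return(score)
  covariates <- as.data.frame(covariates %||% data.frame())
  if (ncol(covariates)) {
    ## constant columns carry no adjustment information; drop them rather
    ## than report them as collinear with the intercept
    keep <- vapply(covariates, function(v)
      length(unique(v[!is.na(v)])) > 1, TRUE)
    covariates <- covariates[, keep, drop = FALSE]
  }
  if (!ncol(covariates)) return(zscore(score, "score"))
  X <- stats::model.matrix(~ ., data = covariates)
  q <- qr(X)
  if (q$rank < ncol(X)) {
    bad <- colnames(X)[q$pivot[(q$rank + 1):ncol(X)]]
    stop("rank-deficient covariates; collinear column(s): ",
         paste(bad, collapse = ", "))
  }
  res <- stats::lm.fit(X, score)$residuals
  if (stats::sd(res) <= 1e-10 * max(stats::sd(score), 1))
    stop("cannot standardize adjusted score: zero variance ",
         "(raw score lies in the covariate span)")
  zscore(res, "adjusted score")
}

#' Score over an explicit SNP list
#'
#' `mode = "weighted"`: GWAS-weighted sum over the listed SNPs (equivalent to
#' [compute_prs()] restricted to them with no p-threshold).
#' `mode = "allele_count"`: risk-allele dosage for a single SNP, where the
#' risk allele is the allele with positive oriented weight (dosage is recoded
#' `2 - g` when the oriented weight is negative).
#'
#' @param harmonized a [harmonize()] table.
#' @param genotypes a [genotype_matrix()].
#' @param snp_ids variant ids (genotype ids); all must be present after
#'   harmonization.
#' @param mode `"weighted"` or `"allele_count"`.
#' @return numeric score vector with attribute `n_snps`.
#' @export
snp_set_score <- function(harmonized, genotypes, snp_ids,
                          mode = c("weighted", "allele_count")) {
  mode <- match.arg(mode)
  miss <- setdiff(snp_ids, harmonized$id)
  if (length(miss))
    stop("SNP(s) absent after harmonization: ", paste(miss, collapse = ", "))
  h <- harmonized[match(snp_ids, harmonized$id), , drop = FALSE]
  if (mode == "weighted") {
    out <- as.vector(genotypes$dosage[, h$col_index, drop = FALSE] %*% h$weight)
  } else {
    if (length(snp_ids) != 1)
      stop("allele_count mode scores a single SNP")
    g <- genotypes$dosage[, h$col_index]
    out <- if (h$weight < 0) 2 - g else g
  }
  names(out) <- rownames(genotypes$dosage)
  attr(out, "n_snps") <- length(snp_ids)
  out
}

#' Build the full score series
#'
#' One column per (compartment, mask-state, p-threshold): clumping is re-run
#' within each (compartment, mask) variant set, thresholds are then applied
#' to the retained variants. Columns are adjusted for `score_covariates`
#' (PCs + array) and standardized.
#'
#' @param genotypes a [genotype_matrix()].
#' @param harmonized a [harmonize()] table.
#' @param partition a [partition_variants()] table.
#' @param compartments compartments to score: any of `"genome_wide"`,
#'   `"genic"`, `"intergenic"` and set names.
#' @param masks named region strings already flagged in the partition (e.g.
#'   `c(MHC = ...)`); every compartment is scored both unmasked (`all`) and
#'   with each mask removed before clumping.
#' @param thresholds p-value thresholds (default the conventional five).
#' @param score_covariates adjustment covariates for
#'   [adjust_and_standardize()] (or `NULL` for plain standardization).
#' @param params a [clump_params()].
#' @return object of class `score_matrix`: list with `raw` and `adjusted`
#'   participant x column matrices and `info` (per-column compartment, mask,
#'   threshold, `n_snps`).
#' @export
build_score_series <- function(genotypes, harmonized, partition,
                               compartments = c("genome_wide", "genic",
                                                "intergenic"),
                               masks = NULL,
                               thresholds = c(1e-5, 1e-4, 1e-3, 0.01, 0.1),
                               score_covariates = NULL,
                               params = clump_params()) {
  pvals <- setNames(harmonized$p, harmonized$id)
  mask_states <- c("all", names(masks))
  cols <- list(); info <- list()
  for (comp in compartments) {
    for (ms in mask_states) {
      ids <- compartment_ids(partition, comp,
                             mask = if (ms == "all") NULL else ms)
      ids <- intersect(ids, harmonized$id)
      cr <- clump(ids, pvals, genotypes, params)
      for (thr in thresholds) {
        cname <- sprintf("%s_%s_p%g", comp, ms, thr)
        sc <- compute_prs(harmonized, genotypes, cr$retained, thr)
        cols[[cname]] <- sc
        info[[cname]] <- data.frame(column = cname, compartment = comp,
                                    mask = ms, threshold = thr,
                                    n_snps = attr(sc, "n_snps"),
                                    stringsAsFactors = FALSE)
      }
    }
  }
  raw <- do.call(cbind, cols)
  rownames(raw) <- rownames(genotypes$dosage)
  adjusted <- apply(raw, 2, function(x) {
    if (all(is.na(x))) x else adjust_and_standardize(x, score_covariates)
  })
  structure(list(raw = raw, adjusted = adjusted,
                 info = do.call(rbind, info)),
            class = "score_matrix")
}

#' @export
print.score_matrix <- function(x, ...) {
  cat(sprintf("<score_matrix> %d participants x %d score columns\n",
              nrow(x$raw), ncol(x$raw)))
  print(x$info[, c("column", "n_snps")], row.names = FALSE)
  invisible(x)
}

#' Write a score matrix with its sidecar metadata
#'
#' TSV of adjusted scores (one row per participant) plus `<path>.json` with
#' per-column SNP counts and parameters.
#'
#' @param x a `score_matrix`.
#' @param path output TSV path.
#' @export
write_score_matrix <- function(x, path) {
  df <- data.frame(participant_id = rownames(x$adjusted))
  df <- cbind(df, as.data.frame(x$adjusted))
  data.table::fwrite(df, path, sep = "\t")
  jsonlite::write_json(x$info, paste0(path, ".json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
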