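## Association models: standardized-outcome / standardized-predictor OLS
## with sex/age/site covariates, Bonferroni test families, and the
## per-autosome intergenic scan.

#' Fit covariate-adjusted score-phenotype associations
#'
#' OLS of the standardized phenotype on the standardized score(s) plus
#' covariates, on complete cases (listwise deletion across phenotype, scores
#' and covariates; standardization is computed on that analysis sample).
#' With several score columns all are entered simultaneously, so each beta is
#' conditional on the others. Covariates named in `factor_covariates`
#' (default `"site"`) are expanded to dummies; the rest enter linearly.
#'
#' @param data data.frame holding outcome, scores and covariates.
#' @param outcome name of the phenotype column.
#' @param scores character vector of score column names.
#' @param covariates covariate column names (default sex, age, site).
#' @param factor_covariates covariates to treat as categorical.
#' @return data.frame with one row per score: `score`, `outcome`, `beta`
#'   (standardized), `se`, `p` (two-tailed, from the t distribution at the
#'   residual df), `n`.
#' @export
fit_association <- function(data, outcome, scores,
                            covariates = c("sex", "age", "site"),
                            factor_covariates = "site") {
  need <- c(outcome, scores, covariates)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  d <- data[, need, drop = FALSE]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n <= length(covariates) + length(scores) + 2)
    stop("too few complete cases (n = ", n, ") for the model")
  ## internal safe names so arbitrary column names survive the formula
  md <- data.frame(.y = zscore(d[[outcome]], paste0("outcome ", outcome)))
  snames <- sprintf(".s%d", seq_along(scores))
  for (i in seq_along(scores))
    md[[snames[i]]] <- zscore(d[[scores[i]]], paste0("score ", scores[i]))
  cnames <- sprintf(".c%d", seq_along(covariates))
  for (i in seq_along(covariates)) {
    v <- d[[covariates[i]]]
    if (covariates[i] %in% factor_covariates) v <- factor(v)
    md[[cnames[i]]] <- v
  }
  fit <- stats::lm(stats::as.formula(
    paste(".y ~", paste(c(snames, cnames), collapse = " + "))), data = md)
  cf <- summary(fit)$coefficients
  rows <- match(snames, rownames(cf))
  if (anyNA(rows))
    stop("score coefficient dropped from the model (collinear scores?)")
  data.frame(score = scores, outcome = outcome,
             beta = cf[rows, 1], se = cf[rows, 2], p = cf[rows, 4],
             n = n, row.names = NULL, stringsAsFactors = FALSE)
}

#' Bonferroni threshold for a test family
#'
#' @param m number of tests in the family.
#' @param alpha family-wise error rate (default 0.05).
#' @return the per-test threshold `alpha / m`.
#' @export
bonferroni_threshold <- function(m, alpha = 0.05) {
  if (m < 1) stop("family size must be >= 1")
  alpha / m
}

#' Attach a Bonferroni family to association results
#'
#' Adds `family`, `m` (family size, by default the number of rows counted in
#' the family), the per-test `family_threshold`, and the `significant` flag
#' (`p < alpha/m`). Rows marked `in_family = FALSE` (e.g. sensitivity
#' columns) are judged against the same threshold but do not count towards
#' `m`.
#'
#' @param results data.frame with a `p` column.
#' @param family family identifier string.
#' @param m family size; default `sum(in_family)`.
#' @param alpha family-wise error rate.
#' @param in_family logical vector (recycled) marking rows counted in `m`.
#' @return `results` with family columns appended.
#' @export
apply_bonferroni <- function(results, family, m = NULL, alpha = 0.05,
                             in_family = TRUE) {
  in_family <- rep_len(in_family, nrow(results))
  m <- m %||% sum(in_family)
  thr <- bonferroni_threshold(m, alpha)
  results$family <- family
  results$m <- m
  results$family_threshold <- thr
  results$in_family <- in_family
  results$significant <- results$p < thr
  results
}

#' Per-chromosome intergenic score scan
#'
#' Builds the intergenic score for each chromosome separately at one
#' p-threshold (clumped within the chromosome's intergenic set), plus a
#' masked sensitivity column for the chromosome carrying the masked region
#' (`"<chrom>-<mask>"`), and tests every column against every phenotype.
#' One Bonferroni family covers the chromosome x phenotype tests; the masked
#' column is reported against the same threshold but not counted in the
#' family.
#'
#' @param genotypes a [genotype_matrix()].
#' @param harmonized a [harmonize()] table.
#' @param partition a [partition_variants()] table (with the mask flagged).
#' @param data data.frame with phenotypes and covariates per participant
#'   (rows aligned with the genotype participants).
#' @param outcomes phenotype column names to test.
#' @param mask name of the mask region in the partition (or `NULL` for no
#'   sensitivity column).
#' @param threshold discovery p-value threshold (default 1e-4, the scan's
#'   most predictive threshold).
#' @param covariates,factor_covariates passed to [fit_association()].
#' @param score_covariates adjustment covariates for the scores.
#' @param params a [clump_params()].
#' @return association data.frame (one row per chromosome x outcome) with
#'   Bonferroni family columns and per-column `n_snps`.
#' @export
per_chromosome_scan <- function(genotypes, harmonized, partition, data,
                                outcomes, mask = NULL, threshold = 1e-4,
                                covariates = c("sex", "age", "site"),
                                factor_covariates = "site",
                                score_covariates = NULL,
                                params = clump_params()) {
  pvals <- setNames(harmonized$p, harmonized$id)
  chroms <- unique(partition$chrom)
  mask_col <- if (!is.null(mask)) paste0("mask_", mask)
  mask_chrom <- if (!is.null(mask))
    unique(partition$chrom[partition[[mask_col]]])
  cells <- lapply(chroms, function(ch) list(chrom = ch, masked = FALSE))
  if (!is.null(mask) && length(mask_chrom))
    cells <- c(cells, lapply(mask_chrom, function(ch)
      list(chrom = ch, masked = TRUE)))
  out <- list()
  for (cell in cells) {
    keep <- partition$qc_pass & partition$compartment == "intergenic" &
      partition$chrom == cell$chrom
    if (cell$masked) keep <- keep & !partition[[mask_col]]
    ids <- intersect(partition$id[keep], harmonized$id)
    label <- if (cell$masked) paste0(cell$chrom, "-", mask) else cell$chrom
    cr <- clump(ids, pvals, genotypes, params)
    sc <- compute_prs(harmonized, genotypes, cr$retained, threshold)
    if (attr(sc, "n_snps") == 0L) {
      message("per_chromosome_scan: no qualifying SNPs on ", label,
              "; column skipped")
      next
    }
    adj_sc <- adjust_and_standardize(sc, score_covariates)
    d <- data
    ## align by participant id when available; otherwise rows must already
    ## be in genotype order
    if ("participant_id" %in% names(d)) {
      d$.scan_score <- adj_sc[match(d$participant_id,
                                    rownames(genotypes$dosage))]
    } else d$.scan_score <- adj_sc
    for (oc in outcomes) {
      r <- fit_association(d, oc, ".scan_score", covariates,
                           factor_covariates)
      r$score <- label
      r$n_snps <- attr(sc, "n_snps")
      r$in_family <- !cell$masked
      out[[paste(label, oc)]] <- r
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  apply_bonferroni(res, family = "per_chromosome_scan",
                   in_family = res$in_family)
}
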