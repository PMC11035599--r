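## Greedy p-value-ordered LD clumping within a variant set, with pairwise
## r2 computed from the target cohort's dosages.

#' Clumping parameters
#'
#' @param r2_max r-squared threshold: a neighbour is removed when its r2 with
#'   the index variant strictly exceeds this (pairs at exactly `r2_max` are
#'   retained, matching the "r2 <= 0.1" retained-condition convention).
#' @param window_bp maximum physical distance (bp) at which a pair is
#'   considered (default 1 Mb).
#' @return list of class `clump_params`.
#' @export
clump_params <- function(r2_max = 0.1, window_bp = 1e6) {
  if (r2_max <= 0 || r2_max > 1) stop_field("r2_max", "must lie in (0, 1]")
  if (window_bp <= 0) stop_field("window_bp", "must be positive")
  structure(list(r2_max = r2_max, window_bp = window_bp),
            class = "clump_params")
}

#' Pairwise LD between two variants
#'
#' Squared Pearson correlation of the two dosage columns.
#'
#' @param genotypes a [genotype_matrix()].
#' @param i,j variant ids or column indices.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(genotypes, i, j) {
  gi <- genotypes$dosage[, i]
  gj <- genotypes$dosage[, j]
  if (stats::sd(gi) == 0 || stats::sd(gj) == 0)
    stop("monomorphic variant: r2 undefined (QC-filter first)")
  stats::cor(gi, gj)^2
}

#' Greedy p-value-ordered LD clumping
#'
#' Variants are sorted by ascending p-value (ties broken by chromosome then
#' position); repeatedly the best not-yet-removed variant becomes an index
#' variant and removes all other unprocessed same-chromosome variants within
#' `window_bp` whose r2 with it strictly exceeds `r2_max`. Clumping is always
#' restricted to the supplied set, so it runs within a compartment.
#'
#' @param variant_ids variants to clump (must exist in the genotype map).
#' @param pvalues named p-value vector covering `variant_ids` (typically the
#'   discovery-GWAS p-values from the harmonized table).
#' @param genotypes a [genotype_matrix()] providing dosages for r2.
#' @param params a [clump_params()].
#' @return list of class `clump_result`: `retained` (index-variant ids, in
#'   p-value order) and `absorbed` (data.frame `variant`, `index` for every
#'   removed variant).
#' @export
clump <- function(variant_ids, pvalues, genotypes, params = clump_params()) {
  if (!length(variant_ids))
    return(structure(list(retained = character(0),
                          absorbed = data.frame(variant = character(0),
                                                index = character(0))),
                     class = "clump_result"))
  miss <- setdiff(variant_ids, names(pvalues))
  if (length(miss))
    stop("no p-value for variant(s): ", paste(head(miss, 5), collapse = ", "))
  map <- genotypes$map
  ridx <- match(variant_ids, map$id)
  if (anyNA(ridx))
    stop("variant(s) absent from genotype map: ",
         paste(head(variant_ids[is.na(ridx)], 5), collapse = ", "))
  p <- unname(pvalues[variant_ids])
  chrom <- map$chrom[ridx]; pos <- map$pos[ridx]
  ord <- order(p, chrom, pos)
  removed <- logical(length(ord))
  absorbed_by <- rep(NA_character_, length(ord))
  retained <- character(0)
  D <- genotypes$dosage
  for (k in seq_along(ord)) {
    v <- ord[k]
    if (removed[v]) next
    retained <- c(retained, variant_ids[v])
    later <- ord[-seq_len(k)]
    cand <- later[!removed[later] & chrom[later] == chrom[v] &
                    abs(pos[later] - pos[v]) <= params$window_bp]
    if (!length(cand)) next
    r <- as.vector(stats::cor(D[, ridx[v]], D[, ridx[cand], drop = FALSE]))
    hit <- cand[!is.na(r) & r^2 > params$r2_max]
    removed[hit] <- TRUE
    absorbed_by[hit] <- variant_ids[v]
  }
  structure(list(retained = retained,
                 absorbed = data.frame(variant = variant_ids[removed],
                                       index = absorbed_by[removed],
                                       stringsAsFactors = FALSE)),
            class = "clump_result")
}

#' @export
print.clump_result <- function(x, ...) {
  cat(sprintf("<clump_result> %d index variants, %d absorbed\n",
              length(x$retained), nrow(x$absorbed)))
  invisible(x)
}

#' Serialize / read a clump result
#'
#' TSV with one row per input variant: `variant`, `index` (itself for
#' retained variants), `retained` flag.
#'
#' @param x a `clump_result`.
#' @param path output file.
#' @export
write_clump_result <- function(x, path) {
  df <- rbind(
    data.frame(variant = x$retained, index = x$retained, retained = TRUE,
               stringsAsFactors = FALSE),
    data.frame(variant = x$absorbed$variant, index = x$absorbed$index,
               retained = FALSE, stringsAsFactors = FALSE))
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}
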