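#' Genotype matrix container
#'
#' Participants x variants alt-allele dosage matrix (values 0/1/2, possibly
#' fractional after mean-imputation of sporadic missing calls) together with
#' its variant map. Positions are 1-based and non-decreasing within each
#' chromosome.
#'
#' @param dosage numeric matrix, participants in rows, variants in columns.
#' @param map data.frame with columns `id`, `chrom`, `pos`, `ref`, `alt`
#'   (one row per dosage column, same order).
#' @param participants character vector of participant ids; defaults to
#'   existing rownames or `P1..Pn`.
#' @return an object of class `genotype_matrix`: a list with elements
#'   `dosage` and `map`.
#' @export
genotype_matrix <- function(dosage, map, participants = NULL) {
  dosage <- as.matrix(dosage)
  map <- as.data.frame(map, stringsAsFactors = FALSE)
  stopifnot(all(c("id", "chrom", "pos", "ref", "alt") %in% names(map)))
  if (ncol(dosage) != nrow(map))
    stop("variant map length (", nrow(map),
         ") does not match dosage width (", ncol(dosage), ")")
  if (anyDuplicated(map$id))
    stop("duplicate variant ids in map")
  rng <- suppressWarnings(range(dosage, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 2))
    stop("dosages must lie in [0, 2]")
  for (ch in unique(map$chrom)) {
    p <- map$pos[map$chrom == ch]
    if (is.unsorted(p)) stop("positions not non-decreasing on ", ch)
  }
  participants <- participants %||% rownames(dosage) %||%
    paste0("P", seq_len(nrow(dosage)))
  rownames(dosage) <- participants
  colnames(dosage) <- map$id
  structure(list(dosage = dosage, map = map), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d participants x %d variants on %d chromosome(s)\n",
              nrow(x$dosage), ncol(x$dosage), length(unique(x$map$chrom))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Alt-allele frequency per variant
#' @param genotypes a [genotype_matrix()].
#' @return numeric vector of alt-allele frequencies.
#' @export
alt_freq <- function(genotypes) {
  colMeans(genotypes$dosage, na.rm = TRUE) / 2
}

#' Summary-statistics constructor / validator
#'
#' One row per variant of a discovery GWAS: identifier, position, effect
#' (A1) and other (A2) allele, signed per-allele effect size, two-tailed
#' p-value, effect-allele frequency and sample size.
#'
#' @param df data.frame with columns `snp`, `chrom`, `pos`, `a1`, `a2`,
#'   `beta`, `p`, `freq`, `n`.
#' @return the validated data.frame with class `sumstats` prepended.
#' @export
sumstats <- function(df) {
  need <- c("snp", "chrom", "pos", "a1", "a2", "beta", "p", "freq", "n")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("sumstats missing column(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(df, stringsAsFactors = FALSE)[need]
  if (anyDuplicated(df$snp)) stop("duplicate variant ids in sumstats")
  ok_allele <- function(a) a %in% c("A", "C", "G", "T")
  if (!all(ok_allele(df$a1)) || !all(ok_allele(df$a2)))
    stop("alleles must be single-character A/C/G/T")
  if (any(df$p <= 0 | df$p > 1)) stop("p-values must lie in (0, 1]")
  class(df) <- c("sumstats", "data.frame")
  df
}
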