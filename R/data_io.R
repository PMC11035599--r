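## On-disk formats: summary-statistics TSV (dialect registry), GT-only VCF,
## dosage text, BED6 gene models, gene-set lists, covariate/phenotype TSVs;
## plus harmonization of summary statistics against target genotypes.

## ---- summary statistics --------------------------------------------------

#' Summary-statistics column dialects
#'
#' A dialect maps the canonical fields to file column names; `beta_transform`
#' optionally transforms the effect column (e.g. `log` for files reporting
#' odds ratios).
#'
#' @param snp,chrom,pos,a1,a2,beta,p,freq,n column names in the file.
#' @param beta_transform function applied to the effect column.
#' @return list of class `sumstats_dialect`.
#' @export
sumstats_dialect <- function(snp = "SNP", chrom = "CHR", pos = "BP",
                             a1 = "A1", a2 = "A2", beta = "BETA", p = "P",
                             freq = "FREQ", n = "N",
                             beta_transform = identity) {
  structure(list(snp = snp, chrom = chrom, pos = pos, a1 = a1, a2 = a2,
                 beta = beta, p = p, freq = freq, n = n,
                 beta_transform = beta_transform),
            class = "sumstats_dialect")
}

#' Built-in dialects: `"default"` (SNP/CHR/BP/A1/A2/BETA/P/FREQ/N) and
#' `"or"` (same but the effect column is `OR`, log-transformed on read).
#' @rdname sumstats_dialect
#' @param name dialect name.
#' @export
get_dialect <- function(name) {
  switch(name,
         default = sumstats_dialect(),
         or = sumstats_dialect(beta = "OR", beta_transform = log),
         stop("unknown sumstats dialect: ", name))
}

#' Read GWAS summary statistics
#'
#' Rows whose required fields fail to parse (non-numeric effect/p, p outside
#' (0,1], missing alleles) are dropped with a message reporting the count.
#'
#' @param path TSV file.
#' @param dialect a [sumstats_dialect()] or the name of a built-in one.
#' @return a [sumstats()] data.frame.
#' @export
read_sumstats <- function(path, dialect = "default") {
  if (is.character(dialect)) dialect <- get_dialect(dialect)
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE,
                          colClasses = list(character = dialect$chrom))
  need <- c("snp", "chrom", "pos", "a1", "a2", "beta", "p", "freq", "n")
  cols <- vapply(dialect[need], identity, "")
  miss <- cols[!cols %in% names(dt)]
  if (length(miss))
    stop("sumstats file missing required column(s): ",
         paste(miss, collapse = ", "))
  df <- data.frame(snp = as.character(dt[[cols["snp"]]]),
                   chrom = as.character(dt[[cols["chrom"]]]),
                   pos = as.numeric(dt[[cols["pos"]]]),
                   a1 = toupper(as.character(dt[[cols["a1"]]])),
                   a2 = toupper(as.character(dt[[cols["a2"]]])),
                   beta = dialect$beta_transform(as.numeric(dt[[cols["beta"]]])),
                   p = as.numeric(dt[[cols["p"]]]),
                   freq = as.numeric(dt[[cols["freq"]]]),
                   n = as.numeric(dt[[cols["n"]]]),
                   stringsAsFactors = FALSE)
  ok <- !is.na(df$pos) & !is.na(df$beta) & !is.na(df$p) & df$p > 0 & df$p <= 1 &
    df$a1 %in% c("A", "C", "G", "T") & df$a2 %in% c("A", "C", "G", "T")
  if (any(!ok))
    message("read_sumstats: dropped ", sum(!ok), " unparseable/invalid row(s)")
  sumstats(df[ok, , drop = FALSE])
}

#' Write summary statistics in the default dialect
#' @param ss a [sumstats()] data.frame.
#' @param path output TSV.
#' @export
write_sumstats <- function(ss, path) {
  out <- data.frame(SNP = ss$snp, CHR = ss$chrom, BP = ss$pos, A1 = ss$a1,
                    A2 = ss$a2, BETA = ss$beta, P = ss$p, FREQ = ss$freq,
                    N = ss$n)
  data.table::fwrite(out, path, sep = "\t")
  invisible(path)
}

## ---- genotypes -----------------------------------------------------------

#' Read target genotypes
#'
#' Supported formats: `"vcf"` (v4.x with GT; parsed via the vcfR package)
#' and `"dosage"` (text dialect written by [write_genotypes()]: header of
#' variant ids, one row per participant, with a sidecar `<path>.map`).
#' Missing genotypes are mean-imputed per variant (count reported);
#' multiallelic VCF records are skipped with a message. Non-diploid GT
#' entries are an error.
#'
#' @param path input file.
#' @param format `"vcf"` or `"dosage"`.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, format = c("vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "vcf") read_genotypes_vcf(path) else read_genotypes_dosage(path)
}

read_genotypes_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- t(fix)  # single-record files drop dimensions
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT, fixed = TRUE)
  if (any(multi))
    message("read_genotypes: skipped ", sum(multi), " multiallelic record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[!multi, , drop = FALSE]
  fix <- fix[!multi, , drop = FALSE]
  gt_chr <- sub("\\|", "/", gt)
  bad_ploidy <- !is.na(gt_chr) & !grepl("^[0-9.]/[0-9.]$", gt_chr)
  if (any(bad_ploidy))
    stop("non-diploid GT entries found (e.g. '",
         gt_chr[which(bad_ploidy)[1]], "')")
  a1 <- substr(gt_chr, 1, 1); a2 <- substr(gt_chr, 3, 3)
  dos <- matrix(NA_real_, nrow(gt_chr), ncol(gt_chr))
  known <- !is.na(gt_chr) & a1 != "." & a2 != "."
  dos[known] <- as.numeric(a1[known]) + as.numeric(a2[known])
  dos <- t(dos)  # participants x variants
  n_missing <- sum(is.na(dos))
  if (n_missing) {
    message("read_genotypes: mean-imputed ", n_missing, " missing genotype(s)")
    for (j in which(colSums(is.na(dos)) > 0)) {
      dos[is.na(dos[, j]), j] <- mean(dos[, j], na.rm = TRUE)
    }
  }
  map <- data.frame(id = fix$ID, chrom = fix$CHROM, pos = as.numeric(fix$POS),
                    ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  gm <- genotype_matrix(dos, map, participants = colnames(gt))
  attr(gm, "n_imputed") <- n_missing
  gm
}

read_genotypes_dosage <- function(path) {
  dt <- data.table::fread(path, sep = "\t", data.table = FALSE)
  ids <- dt[[1]]
  dos <- as.matrix(dt[, -1, drop = FALSE])
  map_path <- paste0(path, ".map")
  if (!file.exists(map_path))
    stop("dosage-text input needs its sidecar variant map: ", map_path)
  map <- data.table::fread(map_path, sep = "\t", data.table = FALSE,
                           colClasses = list(character = "chrom"))
  n_missing <- sum(is.na(dos))
  if (n_missing) {
    message("read_genotypes: mean-imputed ", n_missing, " missing dosage(s)")
    for (j in which(colSums(is.na(dos)) > 0))
      dos[is.na(dos[, j]), j] <- mean(dos[, j], na.rm = TRUE)
  }
  genotype_matrix(dos, map, participants = ids)
}

#' Write target genotypes
#'
#' `"vcf"` emits a minimal VCF v4.2 with GT-only genotype fields (hard calls;
#' fractional imputed dosages cannot be represented and are an error).
#' `"dosage"` writes the text dialect (participant id + one column per
#' variant) with a `<path>.map` sidecar.
#'
#' @param genotypes a [genotype_matrix()].
#' @param path output file.
#' @param format `"vcf"` or `"dosage"`.
#' @export
write_genotypes <- function(genotypes, path, format = c("vcf", "dosage")) {
  format <- match.arg(format)
  if (format == "dosage") {
    df <- data.frame(participant_id = rownames(genotypes$dosage))
    df <- cbind(df, as.data.frame(genotypes$dosage))
    data.table::fwrite(df, path, sep = "\t")
    data.table::fwrite(genotypes$map[c("id", "chrom", "pos", "ref", "alt")],
                       paste0(path, ".map"), sep = "\t")
    return(invisible(path))
  }
  D <- genotypes$dosage
  if (any(D != round(D)))
    stop("VCF output requires hard-call dosages (found fractional values)")
  map <- genotypes$map
  gt_codes <- c("0/0", "0/1", "1/1")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=partprs",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", rownames(D)), collapse = "\t")), con)
  chunk <- 500L
  for (s in seq(1, ncol(D), by = chunk)) {
    j <- s:min(s + chunk - 1L, ncol(D))
    gt <- matrix(gt_codes[t(D[, j, drop = FALSE]) + 1L], length(j),
                 nrow(D))
    lines <- paste(map$chrom[j], map$pos[j], map$id[j], map$ref[j], map$alt[j],
                   ".", "PASS", ".", "GT",
                   apply(gt, 1, paste, collapse = "\t"), sep = "\t")
    writeLines(lines, con)
  }
  invisible(path)
}

## ---- genes, gene sets, tables --------------------------------------------

#' Read/write gene models as BED6
#'
#' BED is 0-based half-open with strand in column 6, matching the internal
#' gene-model convention; IO goes through rtracklayer.
#'
#' @param path BED file.
#' @return data.frame `gene_id`, `chrom`, `start`, `end`, `strand`.
#' @export
read_genes_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  data.frame(gene_id = gr$name,
             chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr) - 1L,
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' @rdname read_genes_bed
#' @param genes gene-model data.frame.
#' @export
write_genes_bed <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    genes$chrom, IRanges::IRanges(genes$start + 1L, genes$end),
    strand = genes$strand)
  gr$name <- genes$gene_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read/write a gene set (one gene id per line)
#' @param path text file.
#' @return character vector of gene ids.
#' @export
read_geneset <- function(path) {
  x <- trimws(readLines(path))
  x[nzchar(x)]
}

#' @rdname read_geneset
#' @param ids character vector of gene ids.
#' @export
write_geneset <- function(ids, path) {
  writeLines(ids, path)
  invisible(path)
}

#' Read/write participant tables (covariates or phenotypes)
#'
#' TSVs keyed by `participant_id`.
#' @param path TSV file.
#' @return data.frame.
#' @export
read_participant_table <- function(path) {
  df <- data.table::fread(path, sep = "\t", data.table = FALSE)
  if (!"participant_id" %in% names(df))
    stop("participant table must have a 'participant_id' column")
  df$participant_id <- as.character(df$participant_id)
  df
}

#' @rdname read_participant_table
#' @param df data.frame with a `participant_id` column.
#' @export
write_participant_table <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t")
  invisible(path)
}

## ---- harmonization -------------------------------------------------------

#' Harmonize summary statistics against target genotypes
#'
#' Variants are matched by (chromosome, position). The oriented weight counts
#' the summary-statistics effect allele on the genotype alt-dosage scale:
#' unchanged when the effect allele is the alt allele, negated when it is the
#' ref allele; rows whose allele pair does not match `{ref, alt}` are
#' dropped. Palindromic pairs (A/T, C/G) are ambiguous between a true match
#' and a strand flip: they are dropped when the effect-allele frequency lies
#' in (0.4, 0.6), otherwise resolved by comparing the frequency with the
#' genotype alt frequency (agreeing sides of 0.5 means the effect allele is
#' the alt allele).
#'
#' @param ss a [sumstats()] data.frame.
#' @param genotypes a [genotype_matrix()].
#' @return data.frame of class `harmonized`: `id` (genotype variant id),
#'   `col_index` (dosage column), `chrom`, `pos`, `weight` (oriented
#'   per-allele effect), `p`.
#' @export
harmonize <- function(ss, genotypes) {
  map <- genotypes$map
  key_g <- paste(map$chrom, map$pos)
  key_s <- paste(ss$chrom, ss$pos)
  gi <- match(key_s, key_g)
  hit <- !is.na(gi)
  if (!any(hit)) stop("no variants overlap between sumstats and genotypes")
  s <- ss[hit, , drop = FALSE]
  gi <- gi[hit]
  ref <- map$ref[gi]; alt <- map$alt[gi]
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  palin <- s$a1 == comp[s$a2]
  direct <- s$a1 == alt & s$a2 == ref
  flipped <- s$a1 == ref & s$a2 == alt
  weight <- rep(NA_real_, nrow(s))
  keep <- rep(FALSE, nrow(s))
  ## non-palindromic: orientation read off the allele labels
  np <- !palin
  keep[np & direct] <- TRUE
  weight[np & direct] <- s$beta[np & direct]
  keep[np & flipped] <- TRUE
  weight[np & flipped] <- -s$beta[np & flipped]
  ## palindromic: labels uninformative; use frequency unless near 0.5
  amb <- palin & (direct | flipped) & s$freq > 0.4 & s$freq < 0.6
  res <- palin & (direct | flipped) & !amb
  if (any(res)) {
    af <- alt_freq(genotypes)[gi[res]]
    same_side <- (s$freq[res] > 0.5) == (af > 0.5)
    keep[res] <- TRUE
    weight[res] <- ifelse(same_side, s$beta[res], -s$beta[res])
  }
  n_drop <- nrow(ss) - sum(keep)
  if (n_drop)
    message("harmonize: dropped ", n_drop,
            " variant(s) (unmatched position, allele mismatch, or ambiguous palindromic)")
  out <- data.frame(id = map$id[gi[keep]], col_index = gi[keep],
                    chrom = map$chrom[gi[keep]], pos = map$pos[gi[keep]],
                    weight = weight[keep], p = s$p[keep],
                    stringsAsFactors = FALSE)
  class(out) <- c("harmonized", "data.frame")
  out
}
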