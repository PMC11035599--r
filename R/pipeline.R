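## One-config orchestration: load -> partition -> clump/score ->
## phenotype prep -> association (-> local rg), with table-shaped outputs
## and a provenance record.

default_config <- function() {
  list(seed = 1L,
       qc = list(maf_min = 0.05, hwe_p_min = 1e-6),
       gene_windows = list(up_kb = 35, down_kb = 10, strand_aware = TRUE),
       clump = list(r2_max = 0.1, window_bp = 1e6),
       thresholds = c(1e-5, 1e-4, 1e-3, 0.01, 0.1),
       phenotype_prep = list(k = 3),
       association = list(covariates = c("sex", "age", "site"),
                          factor_covariates = "site"),
       scan = list(enabled = TRUE, threshold = 1e-4),
       local_rg = list(enabled = FALSE, block_source = "uniform:1000000",
                       nsim = 1000, cum_var = 0.99))
}

merge_config <- function(base, user) {
  for (k in names(user)) {
    base[[k]] <- if (is.list(user[[k]]) && is.list(base[[k]]))
      merge_config(base[[k]], user[[k]]) else user[[k]]
  }
  base
}

#' Load a run configuration
#'
#' Reads a YAML or JSON file (or takes a list), fills defaults, and returns
#' the merged configuration.
#'
#' @param config list, or path to a YAML/JSON file.
#' @return merged configuration list.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  merge_config(default_config(), config)
}

#' Validate a run configuration
#'
#' Collects every problem rather than stopping at the first.
#'
#' @param config configuration list (or path); defaults are filled first.
#' @return character vector of error messages (empty when valid).
#' @export
validate_config <- function(config) {
  config <- load_config(config)
  errs <- character(0)
  add <- function(msg) errs <<- c(errs, msg)
  thr <- config$thresholds
  if (!is.numeric(thr) || !length(thr)) add("thresholds must be numeric")
  else {
    if (is.unsorted(thr, strictly = TRUE))
      add("thresholds must be sorted strictly ascending")
    if (any(thr <= 0 | thr > 1)) add("thresholds must lie in (0, 1]")
  }
  r2 <- config$clump$r2_max
  if (!is.numeric(r2) || r2 <= 0 || r2 > 1)
    add("clump$r2_max must lie in (0, 1]")
  if (!is.numeric(config$clump$window_bp) || config$clump$window_bp <= 0)
    add("clump$window_bp must be positive")
  if (!is.numeric(config$qc$maf_min) || config$qc$maf_min < 0 ||
      config$qc$maf_min >= 0.5)
    add("qc$maf_min must lie in [0, 0.5)")
  for (m in names(config$masks)) {
    ok <- tryCatch({parse_region(config$masks[[m]]); TRUE},
                   error = function(e) FALSE)
    if (!ok) add(paste0("mask '", m, "' is not a valid region"))
  }
  known <- c("genome_wide", "genic", "intergenic", names(config$paths$gene_sets))
  bad <- setdiff(config$compartments %||% character(0), known)
  if (length(bad))
    add(paste0("unknown compartment(s): ", paste(bad, collapse = ", ")))
  for (p in c("sumstats", "genotypes", "genes", "covariates", "phenotypes")) {
    path <- config$paths[[p]]
    if (is.null(path)) add(paste0("paths$", p, " is required"))
    else if (!file.exists(path)) add(paste0("paths$", p, " does not exist: ", path))
  }
  for (s in names(config$paths$gene_sets)) {
    if (!file.exists(config$paths$gene_sets[[s]]))
      add(paste0("gene set '", s, "' file does not exist"))
  }
  errs
}

#' Marginal GWAS of a cohort phenotype
#'
#' Per-variant marginal association of a (covariate-residualized,
#' standardized) phenotype with alt-allele dosage, emitted as a summary-
#' statistics table — the in-cohort GWAS feeding the local genetic
#' correlation analysis.
#'
#' @param genotypes a [genotype_matrix()].
#' @param y phenotype vector (aligned with participants; NAs dropped).
#' @param covariates optional covariate data.frame to residualize on.
#' @return a [sumstats()] data.frame.
#' @export
phenotype_gwas <- function(genotypes, y, covariates = NULL) {
  keep <- !is.na(y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    keep <- keep & stats::complete.cases(covariates)
    X <- stats::model.matrix(~ ., data = covariates[keep, , drop = FALSE])
    y <- stats::lm.fit(X, y[keep])$residuals
  } else y <- y[keep]
  y <- zscore(y, "phenotype")
  D <- genotypes$dosage[keep, , drop = FALSE]
  b_std <- as.vector(stats::cor(y, D))
  n <- length(y)
  z <- b_std * sqrt(n)
  sdj <- col_sds(D); sdj[sdj == 0] <- 1
  sumstats(data.frame(
    snp = genotypes$map$id, chrom = genotypes$map$chrom,
    pos = genotypes$map$pos, a1 = genotypes$map$alt, a2 = genotypes$map$ref,
    beta = b_std / sdj, p = pmax(2 * pnorm(-abs(z)), 1e-320),
    freq = colMeans(D) / 2, n = n,
    stringsAsFactors = FALSE))
}

#' Write a synthetic cohort to disk with a matching run configuration
#'
#' Serializes every piece of a [simulate_cohort()] result through the
#' package's writers and returns a configuration list pointing at the files,
#' with the designated region wired in as the `MHC` mask.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @param genotype_format `"dosage"` (fast) or `"vcf"`.
#' @return configuration list ready for [run_pipeline()].
#' @export
write_cohort <- function(cohort, dir, genotype_format = c("dosage", "vcf")) {
  genotype_format <- match.arg(genotype_format)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(x) file.path(dir, x)
  write_sumstats(cohort$sumstats, fp("sumstats.tsv"))
  gpath <- fp(if (genotype_format == "vcf") "genotypes.vcf" else "genotypes.tsv")
  write_genotypes(cohort$genotypes, gpath, genotype_format)
  write_genes_bed(cohort$annotation$genes, fp("genes.bed"))
  set_paths <- list()
  for (s in names(cohort$annotation$gene_sets)) {
    sp <- fp(paste0("geneset_", s, ".txt"))
    write_geneset(cohort$annotation$gene_sets[[s]], sp)
    set_paths[[s]] <- sp
  }
  write_participant_table(cohort$covariates, fp("covariates.tsv"))
  write_participant_table(cohort$phenotypes, fp("phenotypes.tsv"))
  reg <- cohort$spec$special_region
  list(seed = cohort$spec$seed,
       paths = list(sumstats = fp("sumstats.tsv"),
                    sumstats_dialect = "default",
                    genotypes = gpath, genotype_format = genotype_format,
                    genes = fp("genes.bed"), gene_sets = set_paths,
                    covariates = fp("covariates.tsv"),
                    phenotypes = fp("phenotypes.tsv")),
       masks = setNames(list(format_region(reg)), "MHC"),
       compartments = c("genome_wide", "genic", "intergenic",
                        names(set_paths)),
       score_covariates = c(paste0("PC", 1:15), "array"),
       scan = list(enabled = TRUE, threshold = 1e-4, mask = "MHC"))
}

## "beta (p)" cell layout: rows = score/threshold, columns = outcomes
format_assoc_table <- function(assoc, row_var = "score") {
  rows <- unique(assoc[[row_var]])
  cols <- unique(assoc$outcome)
  tab <- data.frame(row = rows, stringsAsFactors = FALSE)
  names(tab) <- row_var
  for (oc in cols) {
    cell <- vapply(rows, function(r) {
      hit <- assoc[[row_var]] == r & assoc$outcome == oc
      if (!any(hit)) return("")
      sprintf("%.3f (%.2g)", assoc$beta[hit][1], assoc$p[hit][1])
    }, "")
    tab[[oc]] <- cell
  }
  tab
}

#' Run the full pipeline from one configuration
#'
#' Stages: load -> variant partition -> clump + score series -> phenotype
#' preparation -> per-score associations with Bonferroni families ->
#' per-chromosome intergenic scan (-> local genetic correlation when
#' enabled). Writes machine-readable results plus "beta (p)" tables shaped
#' like the study's, and a provenance record.
#'
#' @param config configuration list or YAML/JSON path (see
#'   [validate_config()]).
#' @param out_dir output directory.
#' @return invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  config <- load_config(config)
  errs <- validate_config(config)
  if (length(errs))
    stop("invalid configuration:\n  ", paste(errs, collapse = "\n  "))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  t0 <- proc.time()[3]
  stage <- function(name) message(sprintf("[partprs %6.1fs] %s",
                                          proc.time()[3] - t0, name))

  stage("load data")
  ss <- read_sumstats(config$paths$sumstats,
                      config$paths$sumstats_dialect %||% "default")
  geno <- read_genotypes(config$paths$genotypes,
                         config$paths$genotype_format %||% "vcf")
  genes <- read_genes_bed(config$paths$genes)
  gene_sets <- lapply(config$paths$gene_sets, read_geneset)
  covar <- read_participant_table(config$paths$covariates)
  phen_raw <- read_participant_table(config$paths$phenotypes)

  stage("partition variants")
  gw <- config$gene_windows
  part <- partition_variants(geno, genes, gene_sets, config$masks,
                             maf_min = config$qc$maf_min,
                             hwe_p_min = config$qc$hwe_p_min,
                             up_kb = gw$up_kb, down_kb = gw$down_kb,
                             strand_aware = gw$strand_aware)
  harm <- harmonize(ss, geno)

  stage("clump and score")
  cp <- clump_params(config$clump$r2_max, config$clump$window_bp)
  sc_covar <- if (length(config$score_covariates))
    covar[match(rownames(geno$dosage), covar$participant_id),
          config$score_covariates, drop = FALSE]
  scores <- build_score_series(geno, harm, part,
                               compartments = config$compartments,
                               masks = config$masks,
                               thresholds = config$thresholds,
                               score_covariates = sc_covar, params = cp)
  write_score_matrix(scores, file.path(out_dir, "scores.tsv"))

  stage("prepare phenotypes")
  phen <- prepare_phenotypes(phen_raw, k = config$phenotype_prep$k)
  outcomes <- setdiff(names(phen), "participant_id")
  data <- merge(phen, covar, by = "participant_id")
  adj <- as.data.frame(scores$adjusted)
  adj$participant_id <- rownames(scores$adjusted)
  data <- merge(data, adj, by = "participant_id")

  stage("associations")
  ac <- config$association
  assoc <- list()
  for (col in scores$info$column) {
    if (all(is.na(data[[col]]))) next
    for (oc in outcomes) {
      r <- fit_association(data, oc, col, ac$covariates,
                           ac$factor_covariates)
      r <- cbind(r, scores$info[scores$info$column == col,
                                c("compartment", "mask", "threshold",
                                  "n_snps")])
      assoc[[paste(col, oc)]] <- r
    }
  }
  assoc <- do.call(rbind, assoc)
  rownames(assoc) <- NULL
  ## families mirror the per-table footnotes: one family per
  ## (table, measure): genome-wide; unmasked compartments; masked compartments
  measure_of <- sub("^[^_]+_", "", assoc$outcome)
  fam <- ifelse(assoc$compartment == "genome_wide", "genome_wide",
                ifelse(assoc$mask == "all", "compartments",
                       "compartments_masked"))
  fam <- paste(fam, measure_of, sep = ".")
  sp <- split(assoc, fam)
  assoc <- do.call(rbind, Map(function(g, nm) apply_bonferroni(g, family = nm),
                              sp, names(sp)))
  rownames(assoc) <- NULL
  data.table::fwrite(assoc, file.path(out_dir, "associations.tsv"),
                     sep = "\t")
  jsonlite::write_json(assoc, file.path(out_dir, "associations.json"),
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  for (ms in unique(assoc$mask)) {
    sub <- assoc[assoc$mask == ms & grepl("axonal_density", assoc$outcome), ]
    sub$row_label <- sprintf("%s p<%g", sub$compartment, sub$threshold)
    tab <- format_assoc_table(sub, "row_label")
    data.table::fwrite(tab, file.path(out_dir, sprintf(
      "table_axonal_density_%s.tsv", ms)), sep = "\t")
  }

  scan <- NULL
  if (isTRUE(config$scan$enabled)) {
    stage("per-chromosome intergenic scan")
    scan <- per_chromosome_scan(geno, harm, part, data,
                                outcomes = grep("axonal_density", outcomes,
                                                value = TRUE),
                                mask = config$scan$mask %||%
                                  names(config$masks)[1],
                                threshold = config$scan$threshold,
                                covariates = ac$covariates,
                                factor_covariates = ac$factor_covariates,
                                score_covariates = sc_covar, params = cp)
    data.table::fwrite(scan, file.path(out_dir, "scan_intergenic.tsv"),
                       sep = "\t")
    data.table::fwrite(format_assoc_table(scan, "score"),
                       file.path(out_dir, "table_scan.tsv"), sep = "\t")
  }

  localrg <- NULL
  if (isTRUE(config$local_rg$enabled)) {
    stage("local genetic correlation")
    oc1 <- grep("axonal_density", outcomes, value = TRUE)[1]
    y <- data[[oc1]][match(rownames(geno$dosage), data$participant_id)]
    cv <- data[match(rownames(geno$dosage), data$participant_id),
               ac$covariates, drop = FALSE]
    ss_b <- phenotype_gwas(geno, y, cv)
    harm_b <- harmonize(ss_b, geno)
    blocks <- define_blocks(geno$map, config$local_rg$block_source)
    localrg <- local_rg_scan(blocks, harm, harm_b, geno,
                             n_a = stats::median(ss$n), n_b = sum(!is.na(y)),
                             cum_var = config$local_rg$cum_var,
                             nsim = config$local_rg$nsim)
    data.table::fwrite(localrg, file.path(out_dir, "local_rg.tsv"),
                       sep = "\t")
  }

  stage("provenance")
  canon <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  cfg_path <- file.path(out_dir, "config.json")
  writeLines(canon, cfg_path)
  prov <- list(package = "partprs",
               version = as.character(utils::packageVersion("partprs")),
               r_version = paste(R.version$major, R.version$minor, sep = "."),
               seed = config$seed,
               parameter_hash = unname(tools::md5sum(cfg_path)))
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE)
  stage("done")
  invisible(list(config = config, partition = part, harmonized = harm,
                 scores = scores, phenotypes = phen, associations = assoc,
                 scan = scan, local_rg = localrg))
}
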