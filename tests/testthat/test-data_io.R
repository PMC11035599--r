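test_that("sumstats TSV round-trips and invalid rows are rejected", {
  f <- withr::local_tempfile(fileext = ".tsv")
  write_sumstats(tiny_cohort$sumstats, f)
  back <- read_sumstats(f)
  expect_equal(nrow(back), nrow(tiny_cohort$sumstats))
  expect_equal(back$beta, tiny_cohort$sumstats$beta, tolerance = 1e-12)

  # a p = 0 row must be dropped (p in (0, 1])
  txt <- c("SNP\tCHR\tBP\tA1\tA2\tBETA\tP\tFREQ\tN",
           "rs1\tchr1\t100\tA\tG\t0.1\t0.5\t0.3\t1000",
           "rs2\tchr1\t200\tC\tG\t0.2\t0\t0.4\t1000")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(txt, f2)
  expect_message(ss <- read_sumstats(f2), "dropped 1")
  expect_equal(ss$snp, "rs1")

  # a missing required column is an error naming it
  writeLines(sub("\tP\t", "\tPP\t", txt[1]) |> c(txt[-1]), f2)
  expect_error(read_sumstats(f2), "P")
})

test_that("an odds-ratio dialect log-transforms the effect column", {
  txt <- c("SNP\tCHR\tBP\tA1\tA2\tOR\tP\tFREQ\tN",
           "rs1\tchr1\t100\tA\tG\t1.5\t0.5\t0.3\t1000",
           "rs2\tchr1\t200\tC\tG\t0.8\t0.1\t0.4\t1000",
           "rs3\tchr1\t300\tT\tG\t1.0\t0.9\t0.2\t1000")
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(txt, f)
  ss <- read_sumstats(f, "or")
  expect_equal(ss$beta, log(c(1.5, 0.8, 1.0)))
})

test_that("VCF and dosage-text genotypes round-trip the in-memory matrix", {
  g <- tiny_cohort$genotypes
  vcf <- withr::local_tempfile(fileext = ".vcf")
  write_genotypes(g, vcf, "vcf")
  back <- read_genotypes(vcf, "vcf")
  expect_equal(unname(back$dosage), unname(g$dosage * 1.0))
  expect_equal(back$map$pos, g$map$pos)
  expect_equal(back$map$ref, g$map$ref)
  expect_identical(rownames(back$dosage), rownames(g$dosage))

  dtxt <- withr::local_tempfile(fileext = ".tsv")
  write_genotypes(g, dtxt, "dosage")
  back2 <- read_genotypes(dtxt, "dosage")
  expect_equal(unname(back2$dosage), unname(g$dosage * 1.0))
  expect_equal(back2$map$id, g$map$id)
})

test_that("VCF reader imputes missing calls, skips multiallelics, rejects bad ploidy", {
  hdr <- c("##fileformat=VCFv4.2",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                 "INFO", "FORMAT", "S1", "S2", "S3", "S4", sep = "\t"))
  body <- c(
    "chr1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t./.",
    "chr1\t200\tv2\tA\tG,T\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1\t0/0",
    "chr1\t300\tv3\tC\tT\t.\tPASS\t.\tGT\t0|0\t0|1\t1|1\t0|0")
  f <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(hdr, body), f)
  msgs <- capture_messages(g <- read_genotypes(f, "vcf"))
  expect_match(paste(msgs, collapse = " "), "multiallelic")
  expect_match(paste(msgs, collapse = " "), "imputed")
  expect_equal(g$map$id, c("v1", "v3"))          # multiallelic skipped
  expect_equal(unname(g$dosage[4, "v1"]), 1)     # mean of 0,1,2
  expect_equal(unname(g$dosage[, "v3"]), c(0, 1, 2, 0))

  writeLines(c(hdr, "chr1\t100\tv1\tA\tG\t.\tPASS\t.\tGT\t0/0/0\t0/1\t1/1\t0/0"),
             f)
  expect_error(read_genotypes(f, "vcf"), "ploidy|diploid")
})

test_that("harmonization orients, flips, and drops by the allele rules", {
  dos <- matrix(rep(c(0, 1, 2, 1), 10), nrow = 4)
  g <- make_genotypes(dos, pos = (1:10) * 1000,
                      ref = rep("A", 10), alt = rep("G", 10))
  ss <- sumstats(data.frame(
    snp = paste0("s", 1:10), chrom = "chr1", pos = (1:10) * 1000,
    a1 = c("G", "A", rep("G", 6), "C", "T"),
    a2 = c("A", "G", rep("A", 6), "A", "C"),
    beta = rep(0.3, 10), p = rep(0.01, 10),
    freq = rep(0.25, 10), n = 1000))
  expect_message(h <- harmonize(ss, g), "dropped 2")
  expect_equal(nrow(h), 8)                       # 2 mismatched pairs dropped
  expect_equal(h$weight[h$pos == 1000], 0.3)     # effect allele == alt
  expect_equal(h$weight[h$pos == 2000], -0.3)    # effect allele == ref
})

test_that("palindromic variants are dropped near 0.5 and resolved by frequency otherwise", {
  dos <- cbind(c(0, 0, 1, 2, 0, 0, 1, 0, 0, 0),   # alt freq 0.2
               c(2, 2, 1, 0, 2, 2, 1, 2, 2, 2),   # alt freq 0.8
               c(0, 1, 1, 1, 1, 1, 1, 1, 1, 2))   # alt freq 0.5
  g <- make_genotypes(dos, pos = c(1000, 2000, 3000),
                      ref = c("A", "A", "C"), alt = c("T", "T", "G"))
  ss <- sumstats(data.frame(
    snp = c("s1", "s2", "s3"), chrom = "chr1", pos = c(1000, 2000, 3000),
    a1 = c("A", "T", "C"), a2 = c("T", "A", "G"),
    beta = c(0.5, 0.5, 0.5), p = 0.01,
    freq = c(0.21, 0.79, 0.5), n = 1000))
  expect_message(h <- harmonize(ss, g), "dropped 1")
  # s1: effect allele A has freq 0.21, genotype alt freq 0.2 -> A is alt
  expect_equal(h$weight[h$pos == 1000], 0.5)
  # s2: effect allele T freq 0.79, alt freq 0.8 -> T is alt, keep sign
  expect_equal(h$weight[h$pos == 2000], 0.5)
  # s3: ambiguous (freq in (0.4, 0.6)) -> dropped
  expect_false(3000 %in% h$pos)
})

test_that("harmonization is idempotent", {
  h1 <- tiny_harm
  g <- tiny_cohort$genotypes
  ss2 <- sumstats(data.frame(
    snp = h1$id, chrom = h1$chrom, pos = h1$pos,
    a1 = g$map$alt[h1$col_index], a2 = g$map$ref[h1$col_index],
    beta = h1$weight, p = h1$p,
    freq = alt_freq(g)[h1$col_index], n = 1000))
  h2 <- suppressMessages(harmonize(ss2, g))
  expect_equal(h2$weight[match(h1$id, h2$id)], h1$weight)
})

test_that("standardized scores are invariant under ref/alt relabeling with dosage recoding", {
  g <- tiny_cohort$genotypes
  keep_palin <- g$map$ref != c(A = "T", T = "A", C = "G", G = "C")[g$map$alt]
  h <- tiny_harm[keep_palin[tiny_harm$col_index], ]
  # relabel: swap ref/alt, recode dosage 2 - g
  g2 <- genotype_matrix(2 - g$dosage,
                        transform(g$map, ref = alt, alt = ref),
                        rownames(g$dosage))
  ss <- tiny_cohort$sumstats
  h2 <- suppressMessages(harmonize(ss, g2))
  common <- intersect(h$id, h2$id)
  s1 <- compute_prs(h[h$id %in% common, ], g, p_threshold = 1)
  s2 <- compute_prs(h2[h2$id %in% common, ], g2, p_threshold = 1)
  expect_equal(adjust_and_standardize(s1), adjust_and_standardize(s2),
               tolerance = 1e-10)
})
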