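# reference panel for block estimators: one high-LD block of 30 SNPs
lrg_ref <- simulate_genotypes(genome_spec(
  n_chromosomes = 1, chrom_length_bp = 1e6, snps_per_block = 30,
  special_region = "chr1:1-1000000", r2_special = 0.5,
  n_participants = 2000, seed = 55))

# harmonized table from standardized marginal effects (alt-allele oriented)
lrg_harm <- function(b_std, genotypes = lrg_ref, n = 1e5) {
  sds <- apply(genotypes$dosage, 2, sd)
  make_harmonized(genotypes, weight = b_std / sds,
                  p = pmax(2 * pnorm(-abs(b_std) * sqrt(n)), 1e-320))
}

# marginal standardized effects: R beta + correlated noise at sample size n
lrg_marginal <- function(beta, R, n) {
  as.vector(R %*% beta) +
    as.vector(t(chol(R + diag(1e-6, nrow(R)))) %*% rnorm(nrow(R))) / sqrt(n)
}

test_that("uniform blocks tile the chromosome and assignments are exhaustive", {
  map <- data.frame(id = paste0("v", 1:20), chrom = "chr1",
                    pos = seq(5e5, 9.6e6, length.out = 20))
  bl <- define_blocks(map, "uniform:1000000")
  expect_equal(nrow(bl$blocks), 10)
  expect_true(all(!is.na(bl$assignment)))
  expect_length(bl$assignment, 20)
  # each variant lands in the tile containing its position
  expect_equal(unname(bl$assignment[1]), "chr1_b1")
  expect_equal(unname(bl$assignment[20]), "chr1_b10")
})

test_that("explicit block tables assign outside variants to the nearest block", {
  map <- data.frame(id = c("a", "b", "c"), chrom = "chr1",
                    pos = c(5e5, 15e5, 9e6))
  src <- data.frame(chrom = "chr1", start = c(1, 1e6), end = c(1e6, 2e6))
  expect_message(bl <- define_blocks(map, src), "nearest")
  expect_equal(unname(bl$assignment), c("chr1_b1", "chr1_b2", "chr1_b2"))
})

test_that("merging blocks spans their union and reassigns variants", {
  map <- data.frame(id = paste0("v", 1:10), chrom = "chr1",
                    pos = seq(1e5, 4.9e6, length.out = 10))
  bl <- define_blocks(map, "uniform:1000000")
  merged <- merge_blocks(bl, c("chr1_b3", "chr1_b4", "chr1_b5"), "big")
  expect_equal(nrow(merged$blocks), 3)
  big <- merged$blocks[merged$blocks$block_id == "big", ]
  expect_equal(big$start, 2e6 + 1)
  expect_equal(big$end, 5e6 + 1)
  expect_true(all(merged$assignment[map$pos > 2e6] == "big"))
  expect_error(merge_blocks(bl, "chr1_b1"), "at least two")
})

test_that("block tables round-trip through TSV", {
  map <- data.frame(id = paste0("v", 1:5), chrom = "chr2",
                    pos = (1:5) * 8e5)
  bl <- define_blocks(map, "uniform:1000000")
  f <- withr::local_tempfile(fileext = ".tsv")
  write_blocks(bl, f)
  expect_equal(read_blocks_tsv(f), bl$blocks, ignore_attr = TRUE)
  bl2 <- define_blocks(map, read_blocks_tsv(f))
  expect_identical(bl2$assignment, bl$assignment)
})

test_that("local h2 recovers a planted effect and vanishes under the null at large n", {
  R <- cor(lrg_ref$dosage)
  ids <- lrg_ref$map$id
  v <- 0.1
  beta <- rep(0, 30); beta[12] <- sqrt(v / R[12, 12])
  withr::with_seed(56, {
    est <- replicate(20, {
      h <- lrg_harm(lrg_marginal(beta, R, 5e5))
      local_h2(ids, h, lrg_ref, 5e5, nsim = 200)$h2
    })
  })
  expect_lt(abs(mean(est) - v), 0.02)
  # zero effects, effectively infinite n: estimate collapses to zero
  withr::with_seed(57, {
    h0 <- lrg_harm(lrg_marginal(rep(0, 30), R, 1e12), n = 1e12)
    r0 <- local_h2(ids, h0, lrg_ref, 1e12, nsim = 200)
  })
  expect_lt(abs(r0$h2), 1e-5)
  expect_error(local_h2(ids[1], lrg_harm(rep(0, 30)), lrg_ref, 100), "< 2")
})

test_that("self-correlation returns exactly 1 and degenerate h2 yields missing rg", {
  R <- cor(lrg_ref$dosage)
  withr::with_seed(58, {
    beta <- rnorm(30, sd = sqrt(0.05 / 30))
    h <- lrg_harm(lrg_marginal(beta, R, 2e5), n = 2e5)
  })
  res <- local_rg_bivariate(lrg_ref$map$id, h, h, lrg_ref, 2e5, 2e5,
                            nsim = 200)
  expect_identical(res$rg, 1)
  # pure noise at modest n: heritability estimates can go non-positive
  withr::with_seed(59, {
    hn <- lrg_harm(lrg_marginal(rep(0, 30), R, 500), n = 500)
    hn2 <- lrg_harm(lrg_marginal(rep(0, 30), R, 500), n = 500)
  })
  res2 <- local_rg_bivariate(lrg_ref$map$id, hn, hn2, lrg_ref, 500, 500,
                             nsim = 100)
  if (res2$h2_a <= 0 || res2$h2_b <= 0) expect_true(is.na(res2$rg))
  expect_error(local_rg_bivariate(lrg_ref$map$id, hn, hn2, lrg_ref, 500, 500,
                                  sample_overlap = TRUE), "overlap")
})

test_that("estimates are invariant to variant order within the block", {
  R <- cor(lrg_ref$dosage)
  withr::with_seed(60, {
    beta <- rnorm(30, sd = sqrt(0.03 / 30))
    h <- lrg_harm(lrg_marginal(beta, R, 1e5))
  })
  ids <- lrg_ref$map$id
  r1 <- local_h2(ids, h, lrg_ref, 1e5, nsim = 100)
  r2 <- local_h2(rev(ids), h, lrg_ref, 1e5, nsim = 100)
  expect_equal(r1$h2, r2$h2, tolerance = 1e-10)
})

test_that("the scan filters on univariate significance before testing rg", {
  # two blocks: one with strong shared signal, one null
  ref2 <- simulate_genotypes(genome_spec(
    n_chromosomes = 1, chrom_length_bp = 2e6, snps_per_block = 20,
    special_region = "chr1:1-1000000", r2_special = 0.4, r2_within = 0.4,
    n_participants = 1500, seed = 61))
  withr::with_seed(62, {
    m <- 40
    beta_a <- beta_b <- rep(0, m)
    beta_a[1:20] <- rnorm(20, sd = sqrt(0.05 / 20))
    beta_b[1:20] <- beta_a[1:20]            # perfectly shared in block 1
    R1 <- cor(ref2$dosage[, 1:20]); R2 <- cor(ref2$dosage[, 21:40])
    ma <- c(lrg_marginal(beta_a[1:20], R1, 2e5),
            lrg_marginal(beta_a[21:40], R2, 2e5))
    mb <- c(lrg_marginal(beta_b[1:20], R1, 2e5),
            lrg_marginal(beta_b[21:40], R2, 2e5))
    sds <- apply(ref2$dosage, 2, sd)
    ha <- make_harmonized(ref2, weight = ma / sds)
    hb <- make_harmonized(ref2, weight = mb / sds)
    blocks <- define_blocks(ref2$map, "uniform:1000000")
    scan <- local_rg_scan(blocks, ha, hb, ref2, 2e5, 2e5, nsim = 500)
  })
  expect_equal(attr(scan, "univariate_threshold"), 0.05 / 2)
  b1 <- scan[scan$block_id == "chr1_b1", ]
  b2 <- scan[scan$block_id == "chr1_b2", ]
  expect_true(b1$tested)
  expect_false(b2$tested)      # null block fails the univariate filter
  expect_true(is.na(b2$rg))
  expect_gt(b1$rg, 0.8)        # shared effects: rg near 1
  expect_true(b1$rg_significant)
})

test_that("the univariate filter threshold follows 0.05 over the block count", {
  expect_equal(bonferroni_threshold(2495), 0.05 / 2495)
  expect_equal(bonferroni_threshold(2495), 2.004008e-05, tolerance = 1e-4)
})
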