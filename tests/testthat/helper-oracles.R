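# Independent oracles, written from first principles and kept separate from
# the implementation they check.

# plain-loop greedy clumping trace over a precomputed r2 matrix
clump_oracle <- function(ids, p, chrom, pos, r2mat, r2_max = 0.1,
                         window_bp = 1e6) {
  ord <- order(p, chrom, pos)
  status <- rep("open", length(ids))  # open / index / removed
  absorbed <- rep(NA_character_, length(ids))
  for (v in ord) {
    if (status[v] != "open") next
    status[v] <- "index"
    for (u in ord) {
      if (status[u] != "open") next
      if (chrom[u] != chrom[v]) next
      if (abs(pos[u] - pos[v]) > window_bp) next
      if (r2mat[u, v] > r2_max) {
        status[u] <- "removed"
        absorbed[u] <- ids[v]
      }
    }
  }
  list(retained = ids[ord][status[ord] == "index"],
       absorbed = data.frame(variant = ids[status == "removed"],
                             index = absorbed[status == "removed"],
                             stringsAsFactors = FALSE))
}

# HWE exact test by direct factorial enumeration of all heterozygote counts
# compatible with the observed allele counts
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nm <- 2 * n_aa + n_Aa          # minor-allele count (orient below)
  if (nm > n) nm <- 2 * n - nm
  if (nm == 0) return(1)
  hets <- seq(nm %% 2, nm, by = 2)
  prob <- vapply(hets, function(x) {
    hom_minor <- (nm - x) / 2
    hom_major <- n - x - hom_minor
    2^x * factorial(n) /
      (factorial(hom_minor) * factorial(x) * factorial(hom_major)) *
      factorial(nm) * factorial(2 * n - nm) / factorial(2 * n)
  }, 0)
  obs <- prob[hets == n_Aa]
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

# OLS by normal equations with t-based two-tailed p-values
ols_oracle <- function(y, X) {
  XtX <- crossprod(X)
  beta <- solve(XtX, crossprod(X, y))
  res <- y - X %*% beta
  df <- length(y) - ncol(X)
  sigma2 <- sum(res^2) / df
  se <- sqrt(diag(solve(XtX)) * sigma2)
  tval <- beta / se
  list(beta = as.vector(beta), se = as.vector(se),
       p = as.vector(2 * pt(-abs(tval), df)), residuals = as.vector(res),
       df = df)
}
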