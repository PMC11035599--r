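#' Parse a region string
#'
#' Regions are written `"chrom:start-end"` (e.g. `"chr6:25000000-35000000"`).
#' Coordinates are interpreted as a half-open interval `[start, end)` on the
#' 1-based position scale: a variant at `pos` is inside the region iff
#' `start <= pos < end`.
#'
#' @param x region string, or a list with `chrom`, `start`, `end`.
#' @return list with `chrom` (character), `start`, `end` (numeric, bp).
#' @export
parse_region <- function(x) {
  if (is.list(x)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(x)))
    reg <- list(chrom = as.character(x$chrom),
                start = as.numeric(x$start), end = as.numeric(x$end))
  } else {
    m <- regmatches(x, regexec("^([^:]+):([0-9eE.+]+)-([0-9eE.+]+)$", x))[[1]]
    if (length(m) != 4L)
      stop("malformed region string (expected 'chrom:start-end'): ", x)
    reg <- list(chrom = m[2], start = as.numeric(m[3]), end = as.numeric(m[4]))
  }
  if (!is.finite(reg$start) || !is.finite(reg$end) || reg$start >= reg$end)
    stop("region start must be < end: ", format_region(reg))
  reg
}

format_region <- function(reg) {
  sprintf("%s:%s-%s", reg$chrom, format(reg$start, scientific = FALSE),
          format(reg$end, scientific = FALSE))
}

#' @keywords internal
in_region <- function(chrom, pos, region) {
  region <- parse_region(region)
  chrom == region$chrom & pos >= region$start & pos < region$end
}

## z-score with a guard for degenerate columns; sd uses the n-1 denominator.
zscore <- function(x, what = "vector") {
  s <- stats::sd(x, na.rm = TRUE)
  if (!is.finite(s) || s == 0)
    stop("cannot standardize ", what, ": zero variance")
  (x - mean(x, na.rm = TRUE)) / s
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## column standard deviations without materializing a full double copy per call
col_sds <- function(X) {
  n <- nrow(X)
  cm <- colMeans(X)
  css <- colSums(X * X)
  v <- (css - n * cm^2) / (n - 1)
  sqrt(pmax(v, 0))
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}
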