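## Phenotype cleaning: per-column +/- k SD outlier trimming (single pass,
## strict inequality) and bilateral (left/right hemisphere) averaging.

#' Flag outliers beyond k standard deviations
#'
#' Single-pass rule: a value is flagged when `|v - mean| > k * SD`, with mean
#' and SD computed once on the full column (missing values ignored). A value
#' at exactly `mean + k * SD` is not flagged. Zero-variance columns produce
#' no exclusions.
#'
#' @param values numeric vector (>= 3 non-missing values).
#' @param k SD multiplier (default 3).
#' @return logical exclusion mask (same length; `FALSE` for missing values).
#' @export
trim_outliers <- function(values, k = 3) {
  if (sum(!is.na(values)) < 3)
    stop("need at least 3 non-missing values to trim")
  m <- mean(values, na.rm = TRUE)
  s <- stats::sd(values, na.rm = TRUE)
  if (!is.finite(s) || s == 0) return(rep(FALSE, length(values)))
  out <- abs(values - m) > k * s
  out[is.na(out)] <- FALSE
  out
}

#' Average left and right hemisphere values
#'
#' Arithmetic mean; missing whenever either side is missing (or excluded
#' upstream, which is encoded as missing).
#'
#' @param left,right numeric vectors.
#' @return numeric vector of bilateral means.
#' @export
bilateral_average <- function(left, right) {
  (left + right) / 2
}

#' Clean a wide phenotype table
#'
#' Expects columns named `<tract>_<measure>_<L|R>`. Each column is trimmed at
#' `k` SD; a participant flagged in any hemisphere or measure of a tract is
#' excluded for that whole tract (all its measures set missing). Surviving
#' left/right pairs are averaged into `<tract>_<measure>` columns.
#'
#' @param phen data.frame with `participant_id` and hemisphere columns.
#' @param k SD multiplier for [trim_outliers()].
#' @return data.frame `participant_id` + one bilateral column per
#'   (tract, measure); attribute `excluded` is a logical participant x tract
#'   matrix.
#' @export
prepare_phenotypes <- function(phen, k = 3) {
  cols <- setdiff(names(phen), "participant_id")
  parsed <- regmatches(cols, regexec("^(.*)_([^_]+_[^_]+)_(L|R)$", cols))
  ok <- lengths(parsed) == 4
  if (!all(ok))
    stop("unrecognized phenotype column name(s): ",
         paste(cols[!ok], collapse = ", "))
  tract <- vapply(parsed, `[`, "", 2)
  measure <- vapply(parsed, `[`, "", 3)
  side <- vapply(parsed, `[`, "", 4)
  tracts <- unique(tract)
  excl <- matrix(FALSE, nrow(phen), length(tracts),
                 dimnames = list(phen$participant_id, tracts))
  for (i in seq_along(cols)) {
    excl[, tract[i]] <- excl[, tract[i]] | trim_outliers(phen[[cols[i]]], k)
  }
  out <- data.frame(participant_id = phen$participant_id,
                    stringsAsFactors = FALSE)
  for (tr in tracts) {
    for (ms in unique(measure[tract == tr])) {
      lc <- cols[tract == tr & measure == ms & side == "L"]
      rc <- cols[tract == tr & measure == ms & side == "R"]
      if (length(lc) != 1 || length(rc) != 1)
        stop("tract ", tr, " measure ", ms, " needs exactly one L and one R column")
      v <- bilateral_average(phen[[lc]], phen[[rc]])
      v[excl[, tr]] <- NA_real_
      out[[paste0(tr, "_", ms)]] <- v
    }
  }
  attr(out, "excluded") <- excl
  out
}
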