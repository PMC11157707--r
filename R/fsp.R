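## Fragment size pattern: GC/library-size adjusted short (100-150 bp) and
## long (151-220 bp) fragment counts per 5-Mb bin, standardized to mean 0 /
## unit sd across bins within each sample.

#' GC- and library-size-adjusted per-bin short/long fragment counts
#'
#' Each fragment with length inside `shortRange` or `longRange` contributes
#' its reciprocal GC-bias weight to the short or long tally of the bin
#' holding its midpoint. Tallies are then rescaled so the sample's weighted
#' total equals `targetTotal` (the library-size adjustment). Fragments whose
#' midpoints fall outside retained bins are ignored.
#'
#' @param sample A [FragmentSample-class].
#' @param scheme A [GenomicBinScheme-class] (conventionally 5-Mb bins).
#' @param bias A [GCBiasCurve-class].
#' @param targetTotal Common weighted total after rescaling (default 1e6).
#' @param shortRange,longRange Inclusive bp ranges for short and long
#'   fragments. Defaults 100-150 / 151-220.
#' @return `data.frame(chrom, start, end, short, long)`, one row per bin.
#' @export
adjustedBinCounts <- function(sample, scheme, bias, targetTotal = 1e6,
                              shortRange = c(100L, 150L),
                              longRange = c(151L, 220L)) {
  if (nBins(scheme) == 0L) stop("empty bin scheme")
  fr <- fragments(sample)
  isShort <- fr$length >= shortRange[1] & fr$length <= shortRange[2]
  isLong  <- fr$length >= longRange[1] & fr$length <= longRange[2]
  use <- isShort | isLong
  fr <- fr[use, , drop = FALSE]
  isShort <- isShort[use]
  idx <- binIndexOf(scheme, fr$chrom, .midpoints(fr))
  ok <- !is.na(idx)
  w <- 1 / biasAt(bias, fr$gc)
  nb <- nBins(scheme)
  short <- numeric(nb); long <- numeric(nb)
  if (any(ok & isShort)) {
    a <- tapply(w[ok & isShort], idx[ok & isShort], sum)
    short[as.integer(names(a))] <- a
  }
  if (any(ok & !isShort)) {
    a <- tapply(w[ok & !isShort], idx[ok & !isShort], sum)
    long[as.integer(names(a))] <- a
  }
  tot <- sum(short) + sum(long)
  if (tot > 0) {
    short <- short * targetTotal / tot
    long  <- long  * targetTotal / tot
  }
  cbind(bins(scheme), short = short, long = long)
}

## population-sd z-scores; constant input maps to all zeros
.zscore <- function(x) {
  s <- stats::sd(x) * sqrt((length(x) - 1) / length(x))
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Standardized fragment-size-pattern feature vector
#'
#' Z-scores the short and long per-bin counts separately across bins
#' (population sd). A degenerate sd of 0 yields all-zero scores for that
#' track. The result is invariant to any positive rescaling of the raw
#' counts.
#'
#' @param counts Output of [adjustedBinCounts()] (at least 2 bins).
#' @return Named numeric vector `fsp_short_z_<chrom>_<start>` /
#'   `fsp_long_z_<chrom>_<start>`.
#' @export
fspVector <- function(counts) {
  if (nrow(counts) < 2L) stop("need at least 2 bins to standardize")
  sz <- .zscore(counts$short)
  lz <- .zscore(counts$long)
  tag <- paste0(counts$chrom, "_",
                format(counts$start, scientific = FALSE, trim = TRUE))
  stats::setNames(c(sz, lz),
                  c(paste0("fsp_short_z_", tag), paste0("fsp_long_z_", tag)))
}
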