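## Copy number features: per-1-Mb-bin log2 depth ratios against a healthy
## baseline. Only the log2-ratio stage is modeled; segmentation and
## tumor-fraction estimation are downstream concerns the classifier does not
## consume.

#' Per-bin normalized, GC-corrected depth
#'
#' Depth of a bin is the sum of reciprocal GC-bias weights over fragments
#' whose midpoint falls inside it, divided by the sample's mean per-bin
#' value (sample-level normalization to mean 1).
#'
#' @param sample A [FragmentSample-class].
#' @param scheme A [GenomicBinScheme-class] (conventionally 1-Mb bins).
#' @param bias A [GCBiasCurve-class].
#' @return Numeric vector of normalized depths, one per bin.
#' @export
binDepth <- function(sample, scheme, bias) {
  if (nBins(scheme) == 0L) stop("empty bin scheme")
  fr <- fragments(sample)
  if (!nrow(fr)) {
    warning("sample has zero fragments; all depths are 0")
    return(numeric(nBins(scheme)))
  }
  idx <- binIndexOf(scheme, fr$chrom, .midpoints(fr))
  ok <- !is.na(idx)
  w <- 1 / biasAt(bias, fr$gc)
  depth <- numeric(nBins(scheme))
  if (any(ok)) {
    a <- tapply(w[ok], idx[ok], sum)
    depth[as.integer(names(a))] <- a
  }
  m <- mean(depth)
  if (m > 0) depth <- depth / m
  depth
}

#' Build a healthy depth baseline
#'
#' Per-bin median of normalized depths across a pool of healthy samples;
#' zero medians are floored at `eps` so ratios stay finite.
#'
#' @param pool List of per-bin depth vectors (at least 3), all on the same
#'   scheme.
#' @param scheme The [GenomicBinScheme-class] the depths were computed on.
#' @param eps Floor applied to zero medians.
#' @return A [DepthBaseline-class].
#' @export
buildDepthBaseline <- function(pool, scheme, eps = 1e-3) {
  if (length(pool) < 3L) stop("depth baseline pool must have >= 3 samples")
  nb <- nBins(scheme)
  if (any(vapply(pool, length, 1L) != nb))
    stop("pool depth vectors must match the scheme")
  m <- do.call(cbind, pool)
  med <- apply(m, 1L, stats::median)
  methods::new("DepthBaseline", bins = bins(scheme), depth = pmax(med, eps),
               poolSize = length(pool))
}

#' Per-bin log2 depth ratios against a baseline
#'
#' `log2(max(depth, eps) / baseline)` per bin; finite everywhere thanks to
#' the floors. Swapping depth and baseline negates every ratio.
#'
#' @param depth Per-bin normalized depth from [binDepth()].
#' @param baseline A [DepthBaseline-class] on the same scheme.
#' @param eps Floor applied to the sample depth.
#' @return Named numeric vector `cnv_log2_<chrom>_<start>`.
#' @export
cnvVector <- function(depth, baseline, eps = 1e-3) {
  if (length(depth) != length(baseline@depth))
    stop("depth and baseline are on different schemes")
  lr <- log2(pmax(depth, eps) / baseline@depth)
  tag <- paste0(baseline@bins$chrom, "_",
                format(baseline@bins$start, scientific = FALSE, trim = TRUE))
  stats::setNames(lr, paste0("cnv_log2_", tag))
}
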