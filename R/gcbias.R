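#' GC stratum grid used throughout
#' @return `seq(0, 1, by = 0.02)` (51 strata).
#' @export
gcStrata <- function() seq(0, 1, by = 0.02)

.strataIndex <- function(gc) pmin(pmax(as.integer(round(gc / 0.02)) + 1L, 1L), 51L)

#' Estimate the per-sample GC bias curve
#'
#' Compares the sample's fragment GC representation with the genome's
#' reference GC distribution (one value per genome window, all windows equal
#' weight) on a 51-stratum grid at 0.02 resolution. The per-stratum ratio is
#' the median, over the genome windows of that stratum, of each window's
#' observed fragment count divided by the genome-wide expectation per
#' window; the median makes the curve robust to localized coverage changes
#' (e.g. focal copy gains), which must not be absorbed into the GC model.
#' The ratio curve is smoothed by local linear regression (LOESS, span 0.3
#' over the strata with reference mass) and clamped below at `floor`, so
#' reciprocal weights `1/bias` used by all feature extractors stay bounded
#' by `1/floor`. Strata with no reference mass carry bias 1; strata with
#' reference mass but no observed fragments carry bias `floor`.
#'
#' @param sample A [FragmentSample-class]; fewer than 1000 fragments triggers
#'   a warning (the curve is still computed).
#' @param genome A [GenomeSpec-class].
#' @param span LOESS span over the occupied strata.
#' @param floor Lower clamp for the bias.
#' @return A [GCBiasCurve-class].
#' @export
estimateGCBias <- function(sample, genome, span = 0.3, floor = 0.05) {
  fr <- fragments(sample)
  if (nrow(fr) < 1000L)
    warning("GC bias estimated from only ", nrow(fr), " fragments")
  g <- gcStrata()
  w <- genome@windows
  ws <- genome@windowSize
  refCnt <- tabulate(.strataIndex(w$gc), nbins = 51L)
  ## per-window observed fragment (midpoint) counts
  winKey <- paste0(w$chrom, ":", floor(w$window_start / ws))
  mid <- .midpoints(fr)
  winIdx <- match(paste0(fr$chrom, ":", floor(mid / ws)), winKey)
  winCnt <- tabulate(winIdx[!is.na(winIdx)], nbins = nrow(w))
  expPerWin <- nrow(fr) / nrow(w)
  winStratum <- .strataIndex(w$gc)
  obsCnt <- tabulate(.strataIndex(fr$gc), nbins = 51L)  # fragment GC mass
  bias <- rep(1, 51L)
  occ <- refCnt > 0L
  ratio <- vapply(which(occ), function(k)
    stats::median(winCnt[winStratum == k]) / expPerWin, numeric(1))
  if (sum(occ) >= 7L) {
    sp <- max(span, 7 / sum(occ))  # local linear fit needs a few points
    fit <- stats::loess(ratio ~ gg, data = data.frame(ratio = ratio, gg = g[occ]),
                        span = sp, degree = 1,
                        control = stats::loess.control(surface = "direct"))
    sm <- stats::predict(fit, data.frame(gg = g[occ]))
    bias[occ] <- sm
  } else {
    bias[occ] <- ratio
  }
  bias[occ] <- pmax(bias[occ], floor)
  bias[occ & obsCnt == 0L] <- floor   # no observed mass: clamp, don't trust fit
  methods::new("GCBiasCurve", strata = g, bias = bias, floor = floor)
}

#' Look up bias values for fragment GC fractions
#'
#' @param curve A [GCBiasCurve-class].
#' @param gc Numeric vector of GC fractions.
#' @return Bias at the nearest stratum of each value.
#' @export
biasAt <- function(curve, gc) curve@bias[.strataIndex(gc)]

#' Identity bias curve (bias 1 everywhere)
#'
#' Convenience for tests and for running extractors without GC correction.
#'
#' @param floor Lower clamp recorded on the curve.
#' @return A [GCBiasCurve-class] with bias 1 in every stratum.
#' @export
flatBiasCurve <- function(floor = 0.05) {
  methods::new("GCBiasCurve", strata = gcStrata(), bias = rep(1, 51L),
               floor = floor)
}
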