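## Nucleosome coverage pattern: GC-corrected fragment-midpoint coverage
## profiles around TF binding sites, summarized into three scalars per TF
## (flanking mean, central coverage, nucleosome-periodicity amplitude).

.NCP_NBINS <- 667L           # 15-bp bins spanning centre +/- 5002.5 bp
.NCP_BINW <- 15
.NCP_CENTER <- 334L          # 1-based centre bin index
.NCP_FFT_K <- 53L            # harmonic nearest the ~190-bp nucleosome repeat

## central symmetric SG coefficients (window 11 bins = 165 bp, order 3)
.sgCoef <- function() signal::sgolay(p = 3, n = 11)[6L, ]

## smooth with reflect padding so edges keep the window mean
.sgSmooth <- function(x) {
  co <- .sgCoef()
  h <- 5L
  xp <- c(x[(h + 1L):2L], x, x[(length(x) - 1L):(length(x) - h)])
  stats::filter(xp, co, sides = 2)[(h + 1L):(h + length(x))]
}

#' Midpoint coverage profile around one TF's binding sites
#'
#' Fragments of 100-220 bp contribute their reciprocal GC-bias weight to the
#' 15-bp bin holding their midpoint's offset from the nearest site centre;
#' the 667-bin histograms of all sites are averaged, normalized to a window
#' mean of 1, and Savitzky-Golay smoothed (window 11 bins, order 3).
#'
#' @param sample A [FragmentSample-class].
#' @param sites `data.frame(chrom, center)` of this TF's binding sites (at
#'   least 1 site).
#' @param bias A [GCBiasCurve-class].
#' @param tfName TF name recorded on the profile.
#' @param lenRange Inclusive fragment-length window, default 100-220 bp.
#' @return A [CoverageProfile-class]. With zero in-window fragments the
#'   profile is all zeros (normalization skipped) and a warning is issued.
#' @export
siteCoverageProfile <- function(sample, sites, bias, tfName = "TF",
                                lenRange = c(100L, 220L)) {
  if (!nrow(sites)) stop("need at least one binding site")
  fr <- fragments(sample)
  if (!nrow(fr)) stop("sample has no fragments")
  fr <- fr[fr$length >= lenRange[1] & fr$length <= lenRange[2], , drop = FALSE]
  acc <- numeric(.NCP_NBINS)
  half <- (.NCP_NBINS * .NCP_BINW) / 2      # 5002.5
  for (ch in unique(sites$chrom)) {
    cen <- sort(sites$center[sites$chrom == ch])
    mid <- .midpoints(fr[fr$chrom == ch, , drop = FALSE])
    gc <- fr$gc[fr$chrom == ch]
    if (!length(mid)) next
    j <- findInterval(mid, cen)
    jlo <- pmax(j, 1L); jhi <- pmin(j + 1L, length(cen))
    nearest <- ifelse(abs(mid - cen[jlo]) <= abs(mid - cen[jhi]), jlo, jhi)
    off <- mid - cen[nearest]
    keep <- abs(off) <= half
    if (!any(keep)) next
    binIdx <- as.integer(round(off[keep] / .NCP_BINW)) + .NCP_CENTER
    binIdx <- pmin(pmax(binIdx, 1L), .NCP_NBINS)
    w <- 1 / biasAt(bias, gc[keep])
    a <- tapply(w, binIdx, sum)
    acc[as.integer(names(a))] <- acc[as.integer(names(a))] + a
  }
  nSites <- nrow(sites)
  raw <- acc / nSites
  if (sum(raw) == 0) {
    warning("no fragments in any site window for ", tfName,
            "; returning all-zero profile")
    return(methods::new("CoverageProfile", tfName = tfName,
                        values = raw, raw = raw, nSites = nSites))
  }
  raw <- raw / mean(raw)
  methods::new("CoverageProfile", tfName = tfName,
               values = as.numeric(.sgSmooth(raw)), raw = raw,
               nSites = nSites)
}

#' Three scalar features per coverage profile
#'
#' For each TF profile: `flank` = mean coverage over centre +/- 1 kb (the
#' centre bin and 66 bins on each side), `central` = coverage at the centre
#' bin — both read from the smoothed profile — and `amp` = amplitude of the
#' nucleosome-periodicity component, `2/M * |DFT_k|` of the mean-subtracted
#' 667-bin window at harmonic k = 53 (period 10005/53 ~ 188.8 bp). The
#' amplitude is computed on the raw normalized profile: the single-harmonic
#' projection is already noise-robust, whereas the smoothing filter
#' attenuates the ~190-bp component itself. For a raw profile
#' `1 + a*cos(2*pi*53*i/667)` the amplitude is exactly `a`.
#'
#' @param profiles List of [CoverageProfile-class], one per TF.
#' @param smoothed Use the smoothed (`TRUE`, default) or raw profile for the
#'   flank and central features.
#' @return Named numeric vector `ncp_<tf>_{flank,central,amp}`.
#' @export
ncpVector <- function(profiles, smoothed = TRUE) {
  feats <- lapply(profiles, function(p) {
    v <- if (smoothed) p@values else p@raw
    if (length(v) != .NCP_NBINS || length(p@raw) != .NCP_NBINS)
      stop("profile for ", p@tfName, " does not have 667 bins")
    flankIdx <- (.NCP_CENTER - 66L):(.NCP_CENTER + 66L)
    amp <- 2 / .NCP_NBINS *
      Mod(stats::fft(p@raw - mean(p@raw))[.NCP_FFT_K + 1L])
    stats::setNames(c(mean(v[flankIdx]), v[.NCP_CENTER], amp),
                    paste0("ncp_", p@tfName, "_", c("flank", "central", "amp")))
  })
  do.call(c, feats)
}
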