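#' Assemble the four feature blocks for a cohort
#'
#' Runs the full extraction pipeline on a list of samples: per-sample GC-bias
#' curves, fragment-size-pattern z-scores on 5-Mb bins, per-1-Mb-bin log2
#' depth ratios against a control-pool median baseline, the three
#' nucleosome-coverage scalars per panel TF, and baseline-adjusted
#' substitution spectra (baseline = mean over the control samples,
#' mirroring an external healthy pool).
#'
#' @param samples List of [FragmentSample-class]; controls are the samples
#'   labeled `"non_cancer"` (needed for the depth and spectrum baselines).
#' @param genome A [GenomeSpec-class].
#' @param panel TF-site panel `data.frame(tf, chrom, center)`.
#' @param fspBinSize,cnvBinSize Bin widths of the two schemes (bp).
#' @param snpBlacklist,chipBlacklist Optional position blacklists for the
#'   spectra.
#' @param targetTotal Library-size target for the FSP adjustment.
#' @return List with `features` (named list of four sample x variable
#'   matrices: `FSP`, `CNV`, `NCP`, `SNS`), `labels` (0/1 numeric, 1 =
#'   cancer, names = sample ids), and the two bin schemes.
#' @export
cohortFeatures <- function(samples, genome, panel,
                           fspBinSize = 5e6, cnvBinSize = 1e6,
                           snpBlacklist = NULL, chipBlacklist = NULL,
                           targetTotal = 1e6) {
  ids <- vapply(samples, sampleId, character(1))
  labels <- vapply(samples, sampleLabel, character(1))
  isCtrl <- labels == "non_cancer"
  if (!any(isCtrl)) stop("need control samples to build baselines")
  fspScheme <- makeBinScheme(genome, fspBinSize)
  cnvScheme <- makeBinScheme(genome, cnvBinSize)
  gLen <- genomeLength(genome)
  tfs <- unique(panel$tf)

  biasList <- lapply(samples, estimateGCBias, genome = genome)
  fspMat <- t(vapply(seq_along(samples), function(i)
    fspVector(adjustedBinCounts(samples[[i]], fspScheme, biasList[[i]],
                                targetTotal = targetTotal)),
    numeric(2L * nBins(fspScheme))))
  depths <- lapply(seq_along(samples), function(i)
    binDepth(samples[[i]], cnvScheme, biasList[[i]]))
  depthBase <- buildDepthBaseline(depths[isCtrl], cnvScheme)
  cnvMat <- t(vapply(depths, cnvVector, baseline = depthBase,
                     numeric(nBins(cnvScheme))))
  ncpMat <- t(vapply(seq_along(samples), function(i) {
    profs <- lapply(tfs, function(tf)
      siteCoverageProfile(samples[[i]],
                          panel[panel$tf == tf, c("chrom", "center")],
                          biasList[[i]], tfName = tf))
    ncpVector(profs)
  }, numeric(3L * length(tfs))))
  spectra <- lapply(seq_along(samples), function(i)
    snsSpectrum(samples[[i]], biasList[[i]], gLen,
                snpBlacklist = snpBlacklist, chipBlacklist = chipBlacklist))
  snsBase <- buildSNSBaseline(spectra[isCtrl])
  snsMat <- t(vapply(spectra, function(s)
    subtractBaseline(s, snsBase)@adjusted, numeric(96)))
  colnames(snsMat) <- paste0("sns_", snsClasses())

  feats <- list(FSP = fspMat, CNV = cnvMat, NCP = ncpMat, SNS = snsMat)
  for (k in names(feats)) rownames(feats[[k]]) <- ids
  list(features = feats,
       labels = stats::setNames(as.numeric(labels == "cancer"), ids),
       fspScheme = fspScheme, cnvScheme = cnvScheme)
}
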