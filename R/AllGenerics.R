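#' @include AllClasses.R
NULL

#' Sample identifier
#' @param x A [FragmentSample-class] or [SNSSpectrum-class].
#' @return Character scalar.
#' @export
setGeneric("sampleId", function(x) standardGeneric("sampleId"))

#' @rdname sampleId
#' @export
setMethod("sampleId", "FragmentSample", function(x) x@sampleId)

#' @rdname sampleId
#' @export
setMethod("sampleId", "SNSSpectrum", function(x) x@sampleId)

#' Sample class label
#' @param x A [FragmentSample-class].
#' @return `"cancer"`, `"non_cancer"` or `"unknown"`.
#' @export
setGeneric("sampleLabel", function(x) standardGeneric("sampleLabel"))

#' @rdname sampleLabel
#' @export
setMethod("sampleLabel", "FragmentSample", function(x) x@label)

#' Fragment table of a sample
#' @param x A [FragmentSample-class].
#' @return `data.frame` of fragments (0-based half-open coordinates).
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @rdname fragments
#' @export
setMethod("fragments", "FragmentSample", function(x) x@fragments)

#' Mismatch table of a sample
#' @param x A [FragmentSample-class].
#' @return `data.frame` of per-base reference mismatches.
#' @export
setGeneric("mismatchTable", function(x) standardGeneric("mismatchTable"))

#' @rdname mismatchTable
#' @export
setMethod("mismatchTable", "FragmentSample", function(x) x@mismatches)

#' Number of fragments in a sample
#' @param x A [FragmentSample-class].
#' @return Integer.
#' @export
setGeneric("nFragments", function(x) standardGeneric("nFragments"))

#' @rdname nFragments
#' @export
setMethod("nFragments", "FragmentSample", function(x) nrow(x@fragments))

#' Bin table of a bin scheme or depth baseline
#' @param x A [GenomicBinScheme-class] or [DepthBaseline-class].
#' @return `data.frame(chrom, start, end)`.
#' @export
setGeneric("bins", function(x) standardGeneric("bins"))

#' @rdname bins
#' @export
setMethod("bins", "GenomicBinScheme", function(x) x@bins)

#' @rdname bins
#' @export
setMethod("bins", "DepthBaseline", function(x) x@bins)

#' Number of bins in a scheme
#' @param x A [GenomicBinScheme-class].
#' @return Integer.
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname nBins
#' @export
setMethod("nBins", "GenomicBinScheme", function(x) nrow(x@bins))

#' Total genome length of a GenomeSpec
#' @param x A [GenomeSpec-class].
#' @return Total bp across chromosomes.
#' @export
setGeneric("genomeLength", function(x) standardGeneric("genomeLength"))

#' @rdname genomeLength
#' @export
setMethod("genomeLength", "GenomeSpec", function(x) sum(x@chromosomes$length))

setMethod("show", "FragmentSample", function(object) {
  cat("FragmentSample:", object@sampleId,
      sprintf("(%s)\n", object@label))
  cat(" ", nrow(object@fragments), "fragments,",
      nrow(object@mismatches), "recorded mismatches\n")
  if (nrow(object@fragments))
    cat("  median length:", stats::median(object@fragments$length), "bp\n")
})

setMethod("show", "GenomeSpec", function(object) {
  cat("GenomeSpec:", nrow(object@chromosomes), "chromosome(s),",
      format(genomeLength(object), big.mark = ","), "bp,",
      format(object@windowSize, big.mark = ","), "bp windows\n")
})

setMethod("show", "GenomicBinScheme", function(object) {
  cat("GenomicBinScheme:", nrow(object@bins), "bins of",
      format(object@binSize, big.mark = ","), "bp",
      sprintf("(gc >= %g, mappability >= %g)\n", object@gcMin, object@mapMin))
})

setMethod("show", "GCBiasCurve", function(object) {
  occ <- object@bias != 1
  cat("GCBiasCurve: 51 strata (step 0.02), floor", object@floor, "\n")
  if (any(occ))
    cat("  bias range over fitted strata:",
        sprintf("[%.3f, %.3f]\n", min(object@bias[occ]), max(object@bias[occ])))
})

setMethod("show", "CoverageProfile", function(object) {
  cat("CoverageProfile:", object@tfName, "-", object@nSites, "sites,",
      "667 x 15-bp bins\n")
  cat(sprintf("  central coverage %.3f, window mean %.3f\n",
              object@values[334], mean(object@raw)))
})

setMethod("show", "SNSSpectrum", function(object) {
  cat("SNSSpectrum:", object@sampleId, "- total weighted count",
      sprintf("%.1f", sum(object@counts)),
      "| mean depth", sprintf("%.4g", object@meanDepth), "\n")
  cat("  adjusted:", if (all(is.na(object@adjusted))) "not yet baseline-subtracted"
      else "baseline-subtracted", "\n")
})

setMethod("show", "CohortConfig", function(object) {
  cat("CohortConfig:", object@nCancer, "cancer +", object@nControl,
      "control samples,", object@fragmentsPerSample, "fragments each\n")
  cat(sprintf("  tumor fraction ~ U[%g, %g]; %d CNV segment(s); %d TF(s); %d elevated SNS class(es)\n",
              object@tfLaw[1], object@tfLaw[2], nrow(object@cnvTruth),
              nrow(object@tssTruth), sum(object@snsTruth > 0)))
})

setMethod("show", "ScreeningPriors", function(object) {
  cat("ScreeningPriors: population", format(object@population, big.mark = ","),
      "- prevalence", object@prevalence, "\n")
  for (m in names(object@modalities)) {
    pr <- object@modalities[[m]]
    fmt <- function(v) if (length(v) == 2L)
      sprintf("Beta(%g, %g)", v[1], v[2]) else sprintf("point %g", v)
    cat(sprintf("  %s: compliance %s, sensitivity %s, specificity %s\n",
                m, fmt(pr$compliance), fmt(pr$sensitivity), fmt(pr$specificity)))
  }
})

setMethod("show", "ScreeningDraws", function(object) {
  cat("ScreeningDraws:", object@nIter, "iterations x",
      length(unique(object@draws$modality)), "modalities (seed",
      object@seed, ")\n")
})

setMethod("show", "CfdnaEnsemble", function(object) {
  cat("CfdnaEnsemble: 20 base models (4 types x 5) + 5 stacked models\n")
  cat(sprintf("  cross-validated AUROC %.3f, Youden threshold %.3f\n",
              object@cvAuroc, object@threshold))
})
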