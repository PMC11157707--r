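#' @import methods
NULL

## Central S4 containers. Coordinates are 0-based half-open (BED convention)
## throughout; fragments are strandless after read pairing.

#' FragmentSample: one sample's cfDNA fragments
#'
#' Holds every sequenced cfDNA fragment of one plasma sample together with its
#' per-fragment annotations (GC fraction, mapping quality, mismatch count) and
#' a companion table of individual reference mismatches used by the
#' substitution-spectrum extractor.
#'
#' @slot sampleId Non-empty sample identifier.
#' @slot label One of `"cancer"`, `"non_cancer"`, `"unknown"`.
#' @slot fragments `data.frame` with columns `chrom`, `start`, `end`,
#'   `length`, `gc`, `mapq`, `n_mismatch`. `start`/`end` are 0-based
#'   half-open; `length = end - start`; `gc` in \[0, 1\]; `mapq` is a
#'   Phred-scaled mapping quality.
#' @slot mismatches `data.frame` with columns `frag` (row index into
#'   `fragments`), `pos` (0-based position of the mismatched base),
#'   `ref_tri` (3-letter reference trinucleotide centred on the mismatched
#'   base), `alt` (single substituted base), `baseq` (Phred base quality).
#' @slot metadata Free-form list (stage, tumor location, Lauren subtype, ...).
#'
#' @seealso [readFragmentTable()], [writeFragmentTable()], [simulateSample()]
#' @export
setClass("FragmentSample",
  slots = c(
    sampleId   = "character",
    label      = "character",
    fragments  = "data.frame",
    mismatches = "data.frame",
    metadata   = "list"
  )
)

.fragmentCols <- c("chrom", "start", "end", "length", "gc", "mapq", "n_mismatch")
.mismatchCols <- c("frag", "pos", "ref_tri", "alt", "baseq")

setValidity("FragmentSample", function(object) {
  fr <- object@fragments
  mm <- object@mismatches
  msg <- character()
  if (length(object@sampleId) != 1L || !nzchar(object@sampleId))
    msg <- c(msg, "sampleId must be a single non-empty string")
  if (!(object@label %in% c("cancer", "non_cancer", "unknown")))
    msg <- c(msg, "label must be one of cancer/non_cancer/unknown")
  if (!all(.fragmentCols %in% names(fr)))
    msg <- c(msg, paste("fragments must have columns:",
                        paste(.fragmentCols, collapse = ", ")))
  if (!all(.mismatchCols %in% names(mm)))
    msg <- c(msg, paste("mismatches must have columns:",
                        paste(.mismatchCols, collapse = ", ")))
  if (length(msg)) return(msg)
  if (nrow(fr)) {
    bad <- which(fr$end <= fr$start)
    if (length(bad))
      msg <- c(msg, sprintf("end <= start at fragment row(s) %s",
                            paste(utils::head(bad, 5L), collapse = ", ")))
    if (!all(fr$length == fr$end - fr$start))
      msg <- c(msg, "length must equal end - start")
    if (any(fr$gc < 0 | fr$gc > 1))
      msg <- c(msg, "gc must lie in [0, 1]")
    if (any(fr$mapq < 0))
      msg <- c(msg, "mapq must be >= 0")
    cnt <- tabulate(mm$frag, nbins = nrow(fr))
    if (!all(cnt == fr$n_mismatch))
      msg <- c(msg, "n_mismatch must equal the number of recorded mismatches")
  } else if (nrow(mm)) {
    msg <- c(msg, "mismatches present but no fragments")
  }
  if (nrow(mm)) {
    if (any(mm$frag < 1L | mm$frag > nrow(fr)))
      msg <- c(msg, "mismatch frag index out of range")
    else {
      inside <- mm$pos >= fr$start[mm$frag] & mm$pos < fr$end[mm$frag]
      if (!all(inside))
        msg <- c(msg, "each mismatch position must lie within its fragment")
    }
  }
  if (length(msg)) msg else TRUE
})

#' GenomeSpec: chromosome sizes plus per-window reference GC/mappability
#'
#' @slot chromosomes `data.frame` with columns `chrom`, `length` (bp).
#' @slot windows `data.frame` with columns `chrom`, `window_start`, `gc`,
#'   `mappability`; fixed-width windows tiling each chromosome exactly.
#' @slot windowSize Window width in bp.
#' @export
setClass("GenomeSpec",
  slots = c(
    chromosomes = "data.frame",
    windows     = "data.frame",
    windowSize  = "integer"
  )
)

setValidity("GenomeSpec", function(object) {
  ch <- object@chromosomes
  w  <- object@windows
  ws <- object@windowSize
  msg <- character()
  if (length(ws) != 1L || is.na(ws) || ws <= 0L)
    msg <- c(msg, "windowSize must be a single positive integer")
  if (!all(c("chrom", "length") %in% names(ch)))
    msg <- c(msg, "chromosomes needs columns chrom, length")
  if (!all(c("chrom", "window_start", "gc", "mappability") %in% names(w)))
    msg <- c(msg, "windows needs columns chrom, window_start, gc, mappability")
  if (length(msg)) return(msg)
  if (any(ch$length <= 0)) msg <- c(msg, "chromosome lengths must be > 0")
  if (any(w$gc < 0 | w$gc > 1)) msg <- c(msg, "window gc must lie in [0, 1]")
  if (any(w$mappability < 0 | w$mappability > 1))
    msg <- c(msg, "window mappability must lie in [0, 1]")
  if (any(ch$length %% ws != 0))
    msg <- c(msg, "chromosome lengths must be multiples of windowSize (windows tile exactly)")
  for (i in seq_len(nrow(ch))) {
    ws_i <- w$window_start[w$chrom == ch$chrom[i]]
    want <- seq(0, ch$length[i] - ws, by = ws)
    if (length(ws_i) != length(want) || !all(sort(ws_i) == want)) {
      msg <- c(msg, sprintf("windows do not tile chromosome %s", ch$chrom[i]))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' GenomicBinScheme: filtered fixed-width genome tiling
#'
#' Non-overlapping, sorted bins of a single width whose window-averaged GC and
#' mappability pass the stated filters. Partial terminal tiles are dropped, so
#' every retained bin has exactly `binSize` bp.
#'
#' @slot bins `data.frame` with columns `chrom`, `start`, `end` (0-based
#'   half-open).
#' @slot binSize Bin width in bp.
#' @slot gcMin Minimum window-averaged GC fraction.
#' @slot mapMin Minimum window-averaged mappability.
#' @seealso [makeBinScheme()]
#' @export
setClass("GenomicBinScheme",
  slots = c(
    bins    = "data.frame",
    binSize = "numeric",
    gcMin   = "numeric",
    mapMin  = "numeric"
  )
)

setValidity("GenomicBinScheme", function(object) {
  b <- object@bins
  msg <- character()
  if (!all(c("chrom", "start", "end") %in% names(b)))
    return("bins needs columns chrom, start, end")
  if (nrow(b)) {
    if (!all(b$end - b$start == object@binSize))
      msg <- c(msg, "every bin must have width binSize")
    o <- order(b$chrom, b$start)
    bo <- b[o, , drop = FALSE]
    same <- bo$chrom[-1L] == bo$chrom[-nrow(bo)]
    if (any(same & bo$start[-1L] < bo$end[-nrow(bo)]))
      msg <- c(msg, "bins must be non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' GCBiasCurve: per-GC-stratum fragment representation bias
#'
#' Ratio of the observed fragment GC distribution to the genome reference GC
#' distribution over a fixed 51-point stratum grid (step 0.02), LOESS-smoothed
#' and clamped below at `floor` so reciprocal weights `1/bias` stay bounded.
#' Strata with zero reference mass carry bias 1.
#'
#' @slot strata GC grid, `seq(0, 1, by = 0.02)`.
#' @slot bias Positive bias value per stratum, `>= floor`.
#' @slot floor Lower clamp (default 0.05), so weights are `<= 1/floor`.
#' @seealso [estimateGCBias()], [biasAt()]
#' @export
setClass("GCBiasCurve",
  slots = c(strata = "numeric", bias = "numeric", floor = "numeric")
)

setValidity("GCBiasCurve", function(object) {
  msg <- character()
  if (length(object@strata) != length(object@bias))
    msg <- c(msg, "strata and bias must have equal length")
  if (object@floor <= 0) msg <- c(msg, "floor must be > 0")
  if (any(object@bias < object@floor - 1e-12))
    msg <- c(msg, "bias must be >= floor everywhere")
  if (length(msg)) msg else TRUE
})

#' CoverageProfile: averaged midpoint coverage around TF binding sites
#'
#' 667 bins of 15 bp spanning site centre +/- 5002.5 bp (centre bin index 334,
#' 1-based). `raw` is the site-averaged, GC-corrected midpoint histogram
#' normalized to window mean 1; `values` is `raw` after Savitzky-Golay
#' smoothing (window 11 bins = 165 bp, polynomial order 3, reflect padding).
#'
#' @slot tfName Transcription factor name.
#' @slot values Smoothed profile (length 667).
#' @slot raw Normalized unsmoothed profile (length 667).
#' @slot nSites Number of binding sites averaged.
#' @seealso [siteCoverageProfile()], [ncpVector()]
#' @export
setClass("CoverageProfile",
  slots = c(tfName = "character", values = "numeric", raw = "numeric",
            nSites = "integer")
)

setValidity("CoverageProfile", function(object) {
  msg <- character()
  if (length(object@values) != 667L || length(object@raw) != 667L)
    msg <- c(msg, "profiles must have exactly 667 bins")
  if (any(object@raw != 0) && abs(mean(object@raw) - 1) > 1e-6)
    msg <- c(msg, "raw profile must be normalized to mean 1")
  if (length(msg)) msg else TRUE
})

#' SNSSpectrum: 96-class single-nucleotide-substitution spectrum
#'
#' GC-weighted mismatch counts over the 96 canonical pyrimidine-centred
#' trinucleotide substitution classes, with depth normalization and optional
#' healthy-baseline adjustment. Filters applied during extraction are recorded
#' in `filters`.
#'
#' @slot sampleId Sample identifier.
#' @slot counts Named numeric (96), GC-weighted class counts, `>= 0`.
#' @slot normalized `counts / meanDepth`.
#' @slot adjusted `normalized - baseline`, filled by [subtractBaseline()]
#'   (`NA` until then; may be negative).
#' @slot meanDepth Mean sequencing depth (total fragment bases / genome bp).
#' @slot filters List recording `baseq_min`, `mapq_min`, `n_mismatch`,
#'   `tlen_max`.
#' @seealso [snsSpectrum()], [snsClasses()]
#' @export
setClass("SNSSpectrum",
  slots = c(sampleId = "character", counts = "numeric", normalized = "numeric",
            adjusted = "numeric", meanDepth = "numeric", filters = "list")
)

setValidity("SNSSpectrum", function(object) {
  msg <- character()
  for (sl in c("counts", "normalized", "adjusted")) {
    v <- slot(object, sl)
    if (length(v) != 96L || !identical(names(v), snsClasses()))
      msg <- c(msg, sprintf("%s must be named with the 96 canonical classes", sl))
  }
  if (length(msg)) return(msg)
  if (any(object@counts < 0)) msg <- c(msg, "counts must be >= 0")
  if (length(msg)) msg else TRUE
})

#' SNSBaseline: healthy-pool mean of normalized substitution spectra
#'
#' @slot values Per-class mean normalized value (named, 96).
#' @slot poolSize Number of pooled healthy samples.
#' @seealso [buildSNSBaseline()]
#' @export
setClass("SNSBaseline",
  slots = c(values = "numeric", poolSize = "integer")
)

setValidity("SNSBaseline", function(object) {
  if (length(object@values) != 96L || !identical(names(object@values), snsClasses()))
    return("values must be named with the 96 canonical classes")
  TRUE
})

#' DepthBaseline: per-bin median normalized depth across a healthy pool
#'
#' @slot bins Bin table of the scheme the baseline was built on.
#' @slot depth Per-bin median normalized depth (floored at 1e-3, so > 0).
#' @slot poolSize Number of pooled samples.
#' @seealso [buildDepthBaseline()], [cnvVector()]
#' @export
setClass("DepthBaseline",
  slots = c(bins = "data.frame", depth = "numeric", poolSize = "integer")
)

setValidity("DepthBaseline", function(object) {
  msg <- character()
  if (nrow(object@bins) != length(object@depth))
    msg <- c(msg, "depth must have one value per bin")
  if (any(object@depth <= 0))
    msg <- c(msg, "baseline depths must be > 0 (flooring failed?)")
  if (length(msg)) msg else TRUE
})

#' CohortConfig: parameters of the synthetic cfDNA cohort generator
#'
#' Encodes the generative model: per-sample tumor fraction law, healthy and
#' tumor fragment-length laws, copy-number truth, TF-site depletion /
#' periodicity truth, substitution-excess truth, and the toy genome + TF panel
#' everything is placed on. Control samples have tumor fraction 0; every
#' cancer effect channel scales linearly with tumor fraction and can be
#' switched off independently.
#'
#' @slot nCancer,nControl Sample counts.
#' @slot fragmentsPerSample Fragments simulated per sample.
#' @slot tfLaw `c(min, max)` of the uniform tumor-fraction law for cancer
#'   samples.
#' @slot lengthSupport Integer bp support shared by both length laws.
#' @slot healthyLengthLaw,tumorLengthLaw Probability vectors over
#'   `lengthSupport` (modes ~166 and ~145 bp).
#' @slot cnvTruth `data.frame(chrom, start, end, cn)` of copy-number segments
#'   (background is diploid, cn = 2).
#' @slot tssTruth `data.frame(tf, depletion, amplitude)`: central coverage
#'   depletion depth d in \[0,1\] and periodic amplitude a >= 0 per TF
#'   (realized effects are `tf * d`, `tf * a`).
#' @slot snsTruth Named numeric: per-class excess mismatch rate per fragment
#'   at tumor fraction 1 (names from [snsClasses()]).
#' @slot mismatchNoiseRate Baseline mismatches per fragment (all samples).
#' @slot dipSigma Gaussian half-width (bp) of the central coverage dip.
#' @slot periodBp Period (bp) of the nucleosome oscillation injected around
#'   active TF sites.
#' @slot genome [GenomeSpec-class] the cohort lives on.
#' @slot panel `data.frame(tf, chrom, center)` TF-site panel.
#' @slot seed Cohort-level RNG seed.
#' @seealso [cohortConfig()], [simulateCohort()]
#' @export
setClass("CohortConfig",
  slots = c(
    nCancer = "integer", nControl = "integer",
    fragmentsPerSample = "integer",
    tfLaw = "numeric",
    lengthSupport = "integer",
    healthyLengthLaw = "numeric", tumorLengthLaw = "numeric",
    cnvTruth = "data.frame", tssTruth = "data.frame", snsTruth = "numeric",
    mismatchNoiseRate = "numeric",
    dipSigma = "numeric", periodBp = "numeric",
    genome = "GenomeSpec", panel = "data.frame",
    seed = "integer"
  )
)

setValidity("CohortConfig", function(object) {
  msg <- character()
  if (object@nCancer <= 0L || object@nControl <= 0L)
    msg <- c(msg, "sample counts must be > 0")
  if (object@fragmentsPerSample <= 0L)
    msg <- c(msg, "fragmentsPerSample must be > 0")
  if (length(object@tfLaw) != 2L || any(object@tfLaw < 0) ||
      any(object@tfLaw > 1) || object@tfLaw[1] > object@tfLaw[2])
    msg <- c(msg, "tfLaw must be c(min, max) within [0, 1]")
  for (sl in c("healthyLengthLaw", "tumorLengthLaw")) {
    p <- slot(object, sl)
    if (length(p) != length(object@lengthSupport) || any(p < 0) ||
        abs(sum(p) - 1) > 1e-8)
      msg <- c(msg, sprintf("%s must be a normalized law over lengthSupport", sl))
  }
  if (nrow(object@cnvTruth) && any(object@cnvTruth$cn < 0))
    msg <- c(msg, "copy numbers must be >= 0")
  if (nrow(object@tssTruth) &&
      (any(object@tssTruth$depletion < 0 | object@tssTruth$depletion > 1) ||
       any(object@tssTruth$amplitude < 0)))
    msg <- c(msg, "tssTruth depletion must be in [0,1], amplitude >= 0")
  if (any(object@snsTruth < 0)) msg <- c(msg, "snsTruth rates must be >= 0")
  if (object@mismatchNoiseRate < 0) msg <- c(msg, "mismatchNoiseRate must be >= 0")
  if (length(msg)) msg else TRUE
})

#' CohortTruth: realized parameters of a simulated cohort
#'
#' One row per generated sample plus the realized effect parameters, kept for
#' parameter-recovery tests.
#'
#' @slot table `data.frame(sample_id, label, tumor_fraction, seed)`.
#' @slot params List of the realized effect truths (cnv, tss, sns, laws).
#' @export
setClass("CohortTruth", slots = c(table = "data.frame", params = "list"))

#' ScreeningPriors: Beta/Binomial prior set for the screening simulator
#'
#' Per modality (`endo` = gastroscopy, `ctDNA` = the cfDNA assay): compliance,
#' sensitivity and specificity priors, each either `c(a, b)` shape parameters
#' of a Beta distribution or a single number for a point mass. Plus the
#' population size and cancer prevalence.
#'
#' @slot modalities Named list; each element a list with `compliance`,
#'   `sensitivity`, `specificity`.
#' @slot prevalence Population cancer prevalence in (0, 1).
#' @slot population Screening population size.
#' @seealso [screeningPriors()], [runScreeningSimulation()]
#' @export
setClass("ScreeningPriors",
  slots = c(modalities = "list", prevalence = "numeric", population = "numeric")
)

setValidity("ScreeningPriors", function(object) {
  msg <- character()
  if (!length(object@modalities) || is.null(names(object@modalities)))
    msg <- c(msg, "modalities must be a named list")
  for (m in names(object@modalities)) {
    pr <- object@modalities[[m]]
    for (p in c("compliance", "sensitivity", "specificity")) {
      v <- pr[[p]]
      if (is.null(v) || !(length(v) %in% 1:2))
        msg <- c(msg, sprintf("%s/%s must be Beta c(a,b) or a point mass", m, p))
      else if (length(v) == 2L && any(v <= 0))
        msg <- c(msg, sprintf("%s/%s Beta parameters must be > 0", m, p))
      else if (length(v) == 1L && (v < 0 || v > 1))
        msg <- c(msg, sprintf("%s/%s point mass must lie in [0, 1]", m, p))
    }
  }
  if (object@prevalence <= 0 || object@prevalence >= 1)
    msg <- c(msg, "prevalence must lie in (0, 1)")
  if (object@population <= 0) msg <- c(msg, "population must be > 0")
  if (length(msg)) msg else TRUE
})

#' ScreeningDraws: per-iteration draws of the screening simulation
#'
#' @slot draws `data.frame` with columns `modality`, `iter`, `C`, `N`, `S`,
#'   `SE`, `SP`, `TP`, `TN`, `NPV`, `FNR`.
#' @slot nIter Iterations per modality.
#' @slot seed RNG seed used.
#' @seealso [runScreeningSimulation()], [summarizeDraws()]
#' @export
setClass("ScreeningDraws",
  slots = c(draws = "data.frame", nIter = "integer", seed = "integer")
)

setValidity("ScreeningDraws", function(object) {
  d <- object@draws
  msg <- character()
  need <- c("modality", "iter", "C", "N", "S", "SE", "SP", "TP", "TN", "NPV", "FNR")
  if (!all(need %in% names(d)))
    return(paste("draws needs columns:", paste(need, collapse = ", ")))
  if (nrow(d)) {
    if (any(d$TP > d$S) || any(d$S > d$N)) msg <- c(msg, "need TP <= S <= N")
    if (any(d$TN > d$N - d$S)) msg <- c(msg, "need TN <= N - S")
    if (any(d$NPV < 0 | d$NPV > 1)) msg <- c(msg, "NPV must lie in [0, 1]")
    if (any(d$FNR < 0 | d$FNR > 1)) msg <- c(msg, "FNR must lie in [0, 1]")
  }
  if (length(msg)) msg else TRUE
})

#' CfdnaEnsemble: trained two-layer stacked ensemble
#'
#' First layer: 20 base models (4 feature types x 5 best algorithm/
#' hyperparameter combinations, selected by cross-validated AUROC from a
#' random search over elastic-net logistic regression, gradient boosting,
#' random forest and a single-hidden-layer neural network). Second layer: 5
#' stacked models (elastic-net / boosting / forest) trained on the base
#' models' out-of-fold scores; their predictions are averaged into the final
#' score in \[0, 1\].
#'
#' @slot baseModels List of 20 base model specs (type, algorithm,
#'   hyperparameters, cv AUROC, full-data fit, default variable importance).
#' @slot stackModels List of 5 stacked model specs.
#' @slot foldIds Integer fold assignment used throughout.
#' @slot oof n x 20 matrix of base out-of-fold scores.
#' @slot cvScores Fold-honest cross-validated ensemble scores per sample.
#' @slot cvAuroc AUROC of `cvScores`.
#' @slot threshold Youden-index decision threshold chosen on `cvScores`.
#' @slot labels Binary training labels (1 = cancer).
#' @slot featureNames Named list of column names per feature type.
#' @slot seed Global training seed.
#' @seealso [trainEnsemble()], [predictEnsemble()], [rankImportance()]
#' @export
setClass("CfdnaEnsemble",
  slots = c(
    baseModels = "list", stackModels = "list",
    foldIds = "integer", oof = "matrix",
    cvScores = "numeric", cvAuroc = "numeric", threshold = "numeric",
    labels = "numeric", featureNames = "list", seed = "integer"
  )
)

setValidity("CfdnaEnsemble", function(object) {
  msg <- character()
  if (length(object@baseModels) != 20L)
    msg <- c(msg, "exactly 20 base models required (4 types x 5)")
  if (length(object@stackModels) != 5L)
    msg <- c(msg, "exactly 5 stacked models required")
  if (ncol(object@oof) != 20L)
    msg <- c(msg, "out-of-fold matrix must have 20 columns")
  if (length(msg)) msg else TRUE
})
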