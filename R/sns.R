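## 96-class single-nucleotide-substitution spectra. Classes follow the
## standard pyrimidine-centred convention: substitutions C>A, C>G, C>T, T>A,
## T>C, T>G with one flanking base on each side, 6 x 4 x 4 = 96 classes;
## purine-centred raw contexts are reverse-complemented onto them.

.BASES <- c("A", "C", "G", "T")
.SUBS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' The 96 canonical substitution classes
#'
#' Names of the form `X[R>A]Y` with `R` a pyrimidine (C or T), ordered by
#' substitution type, then 5' base, then 3' base.
#' @return Character vector of length 96.
#' @export
snsClasses <- function() {
  as.vector(vapply(.SUBS, function(s)
    as.vector(vapply(.BASES, function(x)
      paste0(x, "[", s, "]", .BASES), character(4))), character(16)))
}

.complementBase <- function(b) chartr("ACGT", "TGCA", b)

.revcompTri <- function(tri) {
  sp <- strsplit(chartr("ACGT", "TGCA", tri), "")
  vapply(sp, function(x) paste(rev(x), collapse = ""), character(1))
}

## pyrimidine-strand trinucleotide + alt for each canonical class name
.classContext <- function(cls) {
  tri <- paste0(substr(cls, 1, 1), substr(cls, 3, 3), substr(cls, 7, 7))
  list(tri = tri, alt = substr(cls, 5, 5))
}

#' Classify a substitution into its canonical 96-class name
#'
#' Takes the reference trinucleotide centred on the mismatched base and the
#' substituted base; purine-centred contexts (centre A or G) are
#' reverse-complemented onto the pyrimidine-centred canonical class, so all
#' 192 raw (trinucleotide, alt) combinations map 2-to-1 onto the 96 classes.
#'
#' @param refTri Character vector of 3-letter reference trinucleotides.
#' @param alt Character vector of substituted bases (must differ from the
#'   centre base).
#' @return Character vector of class names from [snsClasses()].
#' @examples
#' classifySubstitution("ACA", "T")  # "A[C>T]A"
#' classifySubstitution("AGT", "C")  # "A[C>G]T"
#' @export
classifySubstitution <- function(refTri, alt) {
  refTri <- toupper(refTri); alt <- toupper(alt)
  chars <- c(strsplit(paste(refTri, collapse = ""), "")[[1]], alt)
  if (length(refTri) && !all(chars %in% .BASES))
    stop("non-ACGT base in refTri/alt")
  if (any(nchar(refTri) != 3L))
    stop("refTri must be 3-letter trinucleotides")
  center <- substr(refTri, 2, 2)
  if (any(center == alt))
    stop("alt must differ from the centre reference base")
  purine <- center %in% c("A", "G")
  tri <- ifelse(purine, .revcompTri(refTri), refTri)
  a <- ifelse(purine, .complementBase(alt), alt)
  paste0(substr(tri, 1, 1), "[", substr(tri, 2, 2), ">", a, "]",
         substr(tri, 3, 3))
}

#' Extract the substitution spectrum of a sample
#'
#' Fragments are kept iff mapping quality >= `mapqMin`, length <= `tlenMax`
#' and exactly `nMismatch` recorded mismatch(es); a kept fragment's mismatch
#' enters the spectrum iff its base quality >= `baseqMin` and its
#' `(chrom, pos, ref, alt)` appears in neither blacklist. Each passing
#' mismatch adds the reciprocal GC-bias weight of its fragment to its
#' canonical class. Normalization divides by the mean sequencing depth,
#' total fragment bases / genome length.
#'
#' @param sample A [FragmentSample-class].
#' @param bias A [GCBiasCurve-class].
#' @param genomeLength Genome length in bp (see [genomeLength()]).
#' @param snpBlacklist,chipBlacklist Optional `data.frame(chrom, pos, ref,
#'   alt)` of positions to exclude (germline SNPs; clonal-hematopoiesis
#'   mutations).
#' @param baseqMin,mapqMin,tlenMax,nMismatch Filter thresholds; defaults are
#'   base quality >= 30, mapping quality >= 60, template length <= 300 bp,
#'   exactly 1 mismatch.
#' @return An [SNSSpectrum-class] with `counts` and `normalized` filled
#'   (`adjusted` is `NA` until [subtractBaseline()]).
#' @export
snsSpectrum <- function(sample, bias, genomeLength,
                        snpBlacklist = NULL, chipBlacklist = NULL,
                        baseqMin = 30L, mapqMin = 60L, tlenMax = 300L,
                        nMismatch = 1L) {
  fr <- fragments(sample)
  mm <- mismatchTable(sample)
  keepFrag <- fr$mapq >= mapqMin & fr$length <= tlenMax &
    fr$n_mismatch == nMismatch
  mm <- mm[keepFrag[mm$frag] & mm$baseq >= baseqMin, , drop = FALSE]
  if (nrow(mm)) {
    key <- paste(fr$chrom[mm$frag], mm$pos, substr(mm$ref_tri, 2, 2), mm$alt)
    for (bl in list(snpBlacklist, chipBlacklist)) {
      if (!is.null(bl) && nrow(bl))
        mm <- mm[!(key %in% paste(bl$chrom, bl$pos, bl$ref, bl$alt)), ,
                 drop = FALSE]
      key <- paste(fr$chrom[mm$frag], mm$pos, substr(mm$ref_tri, 2, 2), mm$alt)
    }
  }
  counts <- stats::setNames(rep(0, 96), snsClasses())
  if (nrow(mm)) {
    cls <- classifySubstitution(mm$ref_tri, mm$alt)
    w <- 1 / biasAt(bias, fr$gc[mm$frag])
    agg <- tapply(w, cls, sum)
    counts[names(agg)] <- agg
  }
  meanDepth <- sum(fr$length) / genomeLength
  normalized <- if (meanDepth > 0) counts / meanDepth else counts
  methods::new("SNSSpectrum", sampleId = sample@sampleId, counts = counts,
               normalized = normalized,
               adjusted = stats::setNames(rep(NA_real_, 96), snsClasses()),
               meanDepth = meanDepth,
               filters = list(baseq_min = baseqMin, mapq_min = mapqMin,
                              n_mismatch = nMismatch, tlen_max = tlenMax))
}

#' Build a healthy-pool substitution baseline
#'
#' Per-class arithmetic mean of the normalized values over a pool of healthy
#' spectra.
#'
#' @param pool List of [SNSSpectrum-class] (at least 2).
#' @return An [SNSBaseline-class].
#' @export
buildSNSBaseline <- function(pool) {
  if (length(pool) < 2L) stop("SNS baseline pool must have >= 2 spectra")
  m <- vapply(pool, function(s) s@normalized, numeric(96))
  methods::new("SNSBaseline", values = rowMeans(m),
               poolSize = length(pool))
}

#' Subtract the healthy baseline from a spectrum
#'
#' Fills the `adjusted` slot with `normalized - baseline`, class-wise
#' (adjusted values may be negative).
#'
#' @param spectrum An [SNSSpectrum-class].
#' @param baseline An [SNSBaseline-class].
#' @return The spectrum with `adjusted` filled.
#' @export
subtractBaseline <- function(spectrum, baseline) {
  spectrum@adjusted <- spectrum@normalized - baseline@values
  spectrum
}
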