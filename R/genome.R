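#' Construct a GenomeSpec
#'
#' @param chromosomes `data.frame(chrom, length)`.
#' @param windows `data.frame(chrom, window_start, gc, mappability)` tiling
#'   each chromosome at `windowSize`.
#' @param windowSize Window width (bp).
#' @return A [GenomeSpec-class].
#' @export
GenomeSpec <- function(chromosomes, windows, windowSize) {
  windows <- windows[order(windows$chrom, windows$window_start), , drop = FALSE]
  rownames(windows) <- NULL
  methods::new("GenomeSpec", chromosomes = as.data.frame(chromosomes),
               windows = as.data.frame(windows),
               windowSize = as.integer(windowSize))
}

#' Read / write a genome specification
#'
#' Two TSVs: a chromosome-sizes file (`chrom length`) and a window file
#' (`chrom window_start gc mappability`).
#'
#' @param sizesPath,windowsPath Paths to the two TSV files.
#' @param windowSize Window width (bp).
#' @return [readGenomeSpec()] returns a [GenomeSpec-class];
#'   [writeGenomeSpec()] invisibly returns the two paths.
#' @export
readGenomeSpec <- function(sizesPath, windowsPath, windowSize) {
  ch <- data.table::fread(sizesPath, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  w  <- data.table::fread(windowsPath, sep = "\t", header = TRUE,
                          data.table = FALSE, showProgress = FALSE)
  GenomeSpec(ch, w, windowSize)
}

#' @rdname readGenomeSpec
#' @param genome A [GenomeSpec-class].
#' @export
writeGenomeSpec <- function(genome, sizesPath, windowsPath) {
  data.table::fwrite(genome@chromosomes, sizesPath, sep = "\t", quote = FALSE)
  data.table::fwrite(genome@windows, windowsPath, sep = "\t", quote = FALSE)
  invisible(c(sizesPath, windowsPath))
}

#' Toy genome for desk-scale simulation
#'
#' A small diploid genome with a smoothly varying reference GC landscape
#' (sinusoidal mix, range `gcRange`) and mappability 1 everywhere except
#' optional dropout tiles. Defaults give 2 chromosomes x 50 Mb with 100-kb
#' windows: large enough for 5-Mb and 1-Mb bin schemes, small enough for
#' minutes-scale cohort simulation.
#'
#' @param nChrom Number of chromosomes.
#' @param chromLength Chromosome length (bp), a multiple of `windowSize`.
#' @param windowSize Genome-spec window width (bp).
#' @param gcRange Range of the smooth reference GC landscape.
#' @param dropout Optional `data.frame(chrom, start, end, mappability)` of
#'   low-mappability tiles.
#' @return A [GenomeSpec-class].
#' @export
toyGenome <- function(nChrom = 2L, chromLength = 5e7, windowSize = 1e5,
                      gcRange = c(0.3, 0.6), dropout = NULL) {
  stopifnot(chromLength %% windowSize == 0)
  chroms <- paste0("chr", seq_len(nChrom))
  nw <- chromLength / windowSize
  mid <- mean(gcRange); amp <- diff(gcRange) / 2
  win <- do.call(rbind, lapply(seq_len(nChrom), function(i) {
    starts <- seq(0, chromLength - windowSize, by = windowSize)
    x <- (starts + windowSize / 2) / chromLength
    ## two incommensurate harmonics -> smooth, non-repeating GC landscape
    gc <- mid + amp * (0.7 * sin(2 * pi * (3 * x + 0.13 * i)) +
                       0.3 * sin(2 * pi * (7 * x + 0.41 * i)))
    data.frame(chrom = chroms[i], window_start = starts,
               gc = round(pmin(pmax(gc, gcRange[1]), gcRange[2]), 4),
               mappability = 1)
  }))
  if (!is.null(dropout)) {
    for (k in seq_len(nrow(dropout))) {
      hit <- win$chrom == dropout$chrom[k] &
        win$window_start >= dropout$start[k] &
        win$window_start < dropout$end[k]
      win$mappability[hit] <- dropout$mappability[k]
    }
  }
  GenomeSpec(data.frame(chrom = chroms, length = chromLength), win, windowSize)
}

#' Build a filtered fixed-width bin scheme
#'
#' Tiles each chromosome into consecutive non-overlapping bins of `binSize`
#' bp and keeps those whose window-averaged GC and mappability pass the
#' filters (the 5-Mb fragment-size bins use GC >= 0.3 and mappability >= 0.9).
#' Partial terminal tiles are dropped, never truncated. The result is a
#' deterministic function of its arguments.
#'
#' @param genome A [GenomeSpec-class].
#' @param binSize Bin width (bp); must be a multiple of the genome's window
#'   size.
#' @param gcMin Minimum window-averaged GC.
#' @param mapMin Minimum window-averaged mappability.
#' @return A [GenomicBinScheme-class].
#' @examples
#' g <- toyGenome(nChrom = 1L, chromLength = 2e7)
#' makeBinScheme(g, 5e6)  # 4 bins
#' @export
makeBinScheme <- function(genome, binSize, gcMin = 0.3, mapMin = 0.9) {
  ws <- genome@windowSize
  if (binSize %% ws != 0)
    stop("binSize (", binSize, ") must be a multiple of the genome windowSize (",
         ws, ")")
  out <- lapply(seq_len(nrow(genome@chromosomes)), function(i) {
    chrom <- genome@chromosomes$chrom[i]
    len <- genome@chromosomes$length[i]
    nb <- floor(len / binSize)
    if (nb == 0L) return(NULL)
    w <- genome@windows[genome@windows$chrom == chrom, ]
    tile <- floor(w$window_start / binSize)
    keepw <- tile < nb
    gcBar  <- tapply(w$gc[keepw], tile[keepw], mean)
    mapBar <- tapply(w$mappability[keepw], tile[keepw], mean)
    ok <- gcBar >= gcMin & mapBar >= mapMin
    idx <- as.integer(names(gcBar))[ok]
    if (!length(idx)) return(NULL)
    data.frame(chrom = chrom, start = idx * binSize, end = (idx + 1) * binSize)
  })
  b <- do.call(rbind, out)
  if (is.null(b)) b <- data.frame(chrom = character(), start = numeric(),
                                  end = numeric())
  rownames(b) <- NULL
  methods::new("GenomicBinScheme", bins = b, binSize = binSize,
               gcMin = gcMin, mapMin = mapMin)
}

#' Map fragment midpoints to bins of a scheme
#'
#' Midpoint assignment under half-open bins (no ties possible). Fragments
#' whose midpoint tile was filtered out of the scheme get `NA`.
#'
#' @param scheme A [GenomicBinScheme-class].
#' @param chrom,mid Parallel vectors of chromosome and midpoint position.
#' @return Integer index into `bins(scheme)` or `NA`.
#' @export
binIndexOf <- function(scheme, chrom, mid) {
  key <- paste0(scheme@bins$chrom, ":", floor(scheme@bins$start / scheme@binSize))
  match(paste0(chrom, ":", floor(mid / scheme@binSize)), key)
}

## fragment midpoints (integer floor of the centre)
.midpoints <- function(fragments) (fragments$start + fragments$end) %/% 2L

## reference GC value of the genome window containing each position
.windowGC <- function(genome, chrom, pos) {
  ws <- genome@windowSize
  key <- paste0(genome@windows$chrom, ":",
                floor(genome@windows$window_start / ws))
  genome@windows$gc[match(paste0(chrom, ":", floor(pos / ws)), key)]
}
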