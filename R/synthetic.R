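## Synthetic cfDNA cohort generator. Every cancer effect channel (fragment
## size shift, copy gains, TF-site coverage depletion/periodicity, elevated
## substitution classes) scales linearly with the per-sample tumor fraction
## and can be switched off independently, so each feature extractor has a
## clean parameter-recovery oracle.

## run expr under a temporary RNG seed, restoring the caller's stream
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

#' Discretized log-normal fragment-length law
#'
#' @param support Integer bp support.
#' @param mode Modal fragment length (bp).
#' @param sigma Log-scale spread.
#' @return Probability vector over `support`.
#' @export
lengthLaw <- function(support = 80:260, mode = 166, sigma = 0.14) {
  mu <- log(mode) + sigma^2
  p <- stats::dlnorm(support, meanlog = mu, sdlog = sigma)
  p / sum(p)
}

#' Default synthetic TF-site panel
#'
#' Places `sitesPerTF` binding sites per factor on the genome, at least
#' `minGap` bp apart and away from chromosome ends, assigned to TFs at
#' random. Desk-scale stand-in for a curated panel of 10,000 sites per TF.
#'
#' @param genome A [GenomeSpec-class].
#' @param tfs Character vector of TF names.
#' @param sitesPerTF Sites per factor.
#' @param minGap Minimum distance between site centres (bp); keep above the
#'   10-kb profiling window to avoid overlapping windows.
#' @param seed RNG seed.
#' @return `data.frame(tf, chrom, center)`.
#' @export
defaultTFPanel <- function(genome, tfs = c("TF1", "TF2", "TF3"),
                           sitesPerTF = 200L, minGap = 12000L, seed = 99L) {
  nSites <- length(tfs) * sitesPerTF
  .withSeed(seed, {
    cand <- do.call(rbind, lapply(seq_len(nrow(genome@chromosomes)), function(i) {
      L <- genome@chromosomes$length[i]
      centers <- seq(minGap, L - minGap, by = minGap)
      centers <- centers + sample(seq(-minGap %/% 4, minGap %/% 4), length(centers),
                                  replace = TRUE)
      data.frame(chrom = genome@chromosomes$chrom[i], center = as.integer(centers))
    }))
    if (nrow(cand) < nSites)
      stop("genome too small for ", nSites, " sites at minGap ", minGap)
    pick <- cand[sort(sample.int(nrow(cand), nSites)), ]
    pick$tf <- sample(rep(tfs, sitesPerTF))
    rownames(pick) <- NULL
    pick[, c("tf", "chrom", "center")]
  })
}

#' Default elevated substitution classes
#'
#' The 16 `X[C>A]Y` classes plus 12 `X[T>C]Y` classes (28 of 96, echoing the
#' roughly-30% of classes elevated in cancer cfDNA).
#' @return Character vector of 28 class names.
#' @export
elevatedSNSClasses <- function() {
  cls <- snsClasses()
  c(grep("\\[C>A\\]", cls, value = TRUE),
    grep("^[ACG]\\[T>C\\]", cls, value = TRUE))
}

#' Build a cohort generator configuration
#'
#' Defaults encode the study conditions the pipeline is exercised under: a
#' 2 x 50 Mb toy genome, fragment-length laws with modes 166 bp (healthy) and
#' 145 bp (tumor), tumor fractions uniform on \[0.01, 0.10\], two copy-gain
#' segments (CN 3 and 4), two cancer-active TFs with central coverage
#' depletion and ~190-bp periodicity, and 28 elevated substitution classes.
#' `channels` switches effect channels off for per-extractor recovery tests.
#'
#' @param nCancer,nControl Sample counts.
#' @param fragmentsPerSample Fragments per sample.
#' @param tfLaw `c(min, max)` of the uniform tumor-fraction law.
#' @param lengthSupport Shared length support (bp).
#' @param healthyLengthLaw,tumorLengthLaw Probability vectors over
#'   `lengthSupport`.
#' @param cnvTruth `data.frame(chrom, start, end, cn)`.
#' @param tssTruth `data.frame(tf, depletion, amplitude)`.
#' @param snsTruth Named numeric excess rate per class at tumor fraction 1.
#' @param mismatchNoiseRate Baseline mismatches per fragment.
#' @param dipSigma Gaussian half-width of the central coverage dip (bp).
#' @param periodBp Injected nucleosome periodicity (bp). Default 10005/53
#'   (~188.8 bp), the exact harmonic of the 667 x 15-bp profiling window
#'   closest to the canonical ~190-bp nucleosome repeat.
#' @param genome A [GenomeSpec-class].
#' @param panel TF-site panel `data.frame(tf, chrom, center)`.
#' @param channels Subset of `c("size", "cnv", "tss", "sns")`; omitted
#'   channels are disabled.
#' @param seed Cohort seed.
#' @return A [CohortConfig-class].
#' @export
cohortConfig <- function(nCancer = 30L, nControl = 30L,
                         fragmentsPerSample = 50000L,
                         tfLaw = c(0.01, 0.10),
                         lengthSupport = 80:260,
                         healthyLengthLaw = lengthLaw(lengthSupport, 166, 0.14),
                         tumorLengthLaw = lengthLaw(lengthSupport, 145, 0.20),
                         cnvTruth = data.frame(
                           chrom = c("chr1", "chr2"),
                           start = c(20e6, 35e6), end = c(23e6, 38e6),
                           cn = c(3, 4)),
                         tssTruth = data.frame(
                           tf = c("TF1", "TF2", "TF3"),
                           depletion = c(0.5, 0.25, 0),
                           amplitude = c(0.25, 0.1, 0)),
                         snsTruth = NULL,
                         mismatchNoiseRate = 0.02,
                         dipSigma = 80, periodBp = 10005 / 53,
                         genome = toyGenome(),
                         panel = defaultTFPanel(genome),
                         channels = c("size", "cnv", "tss", "sns"),
                         seed = 20240607L) {
  if (is.null(snsTruth)) {
    snsTruth <- stats::setNames(rep(0, 96), snsClasses())
    snsTruth[elevatedSNSClasses()] <- 0.004
  }
  if (!("size" %in% channels)) tumorLengthLaw <- healthyLengthLaw
  if (!("cnv" %in% channels)) cnvTruth <- cnvTruth[0, , drop = FALSE]
  if (!("tss" %in% channels)) {
    tssTruth$depletion <- 0; tssTruth$amplitude <- 0
  }
  if (!("sns" %in% channels)) snsTruth[] <- 0
  methods::new("CohortConfig",
    nCancer = as.integer(nCancer), nControl = as.integer(nControl),
    fragmentsPerSample = as.integer(fragmentsPerSample),
    tfLaw = tfLaw, lengthSupport = as.integer(lengthSupport),
    healthyLengthLaw = healthyLengthLaw, tumorLengthLaw = tumorLengthLaw,
    cnvTruth = cnvTruth, tssTruth = tssTruth, snsTruth = snsTruth,
    mismatchNoiseRate = mismatchNoiseRate,
    dipSigma = dipSigma, periodBp = periodBp,
    genome = genome, panel = panel, seed = as.integer(seed))
}

## partition the genome into constant-copy-number segments
.cnSegments <- function(genome, cnvTruth) {
  out <- lapply(seq_len(nrow(genome@chromosomes)), function(i) {
    chrom <- genome@chromosomes$chrom[i]
    L <- genome@chromosomes$length[i]
    tr <- cnvTruth[cnvTruth$chrom == chrom, , drop = FALSE]
    cuts <- sort(unique(c(0, L, tr$start, tr$end)))
    seg <- data.frame(chrom = chrom, start = cuts[-length(cuts)],
                      end = cuts[-1], cn = 2)
    for (k in seq_len(nrow(tr)))
      seg$cn[seg$start >= tr$start[k] & seg$end <= tr$end[k]] <- tr$cn[k]
    seg
  })
  do.call(rbind, out)
}

## active TF sites with their effect sizes, sorted per chromosome
.activeSites <- function(panel, tssTruth) {
  act <- tssTruth[tssTruth$depletion > 0 | tssTruth$amplitude > 0, , drop = FALSE]
  if (!nrow(act)) return(NULL)
  s <- merge(panel, act, by = "tf")
  s <- s[order(s$chrom, s$center), ]
  rownames(s) <- NULL
  s
}

## multiplicative thinning rate at distance off from an active site
.tssRate <- function(off, tf, d, a, sigma, period) {
  inWin <- abs(off) <= 5002.5
  1 - tf * d * exp(-off^2 / (2 * sigma^2)) -
    tf * a * cos(2 * pi * off / period) * inWin
}

#' Simulate one cfDNA sample
#'
#' Generates exactly `fragmentsPerSample` fragments. Lengths come from the
#' mixture `(1 - tf) * healthy + tf * tumor`; genomic placement follows
#' per-segment rates proportional to the copy-number mixture
#' `(2 (1 - tf) + tf * CN) / 2`; fragments near cancer-active TF sites are
#' thinned by a Gaussian central dip of depth `tf * d` plus a `tf * a`
#' nucleosome oscillation; per-fragment GC equals the reference GC of the
#' window holding the midpoint (so control samples reproduce the reference
#' GC distribution); mismatches are injected at the baseline noise rate plus
#' the tumor-fraction-scaled class excesses, with ~5% of base qualities
#' below 30 and ~5% of mapping qualities below 60 to exercise the
#' substitution filters. Deterministic given `seed`; the caller's RNG stream
#' is left untouched.
#'
#' @param config A [CohortConfig-class].
#' @param label `"cancer"` or `"non_cancer"`.
#' @param tumorFraction Tumor fraction in \[0, 1\] (controls use 0).
#' @param seed Per-sample seed.
#' @param sampleId Sample identifier.
#' @return A [FragmentSample-class].
#' @export
simulateSample <- function(config, label, tumorFraction, seed,
                           sampleId = paste0(label, "_", seed)) {
  if (!is.numeric(tumorFraction) || tumorFraction < 0 || tumorFraction > 1)
    stop("tumorFraction must lie in [0, 1]")
  genome <- config@genome
  chromLen <- stats::setNames(genome@chromosomes$length,
                              genome@chromosomes$chrom)
  segs <- .cnSegments(genome, config@cnvTruth)
  segW <- ((2 * (1 - tumorFraction) + tumorFraction * segs$cn) / 2) *
    (segs$end - segs$start)
  sites <- .activeSites(config@panel, config@tssTruth)
  aMax <- if (is.null(sites)) 0 else max(sites$amplitude)
  pMax <- 1 + tumorFraction * aMax
  n <- config@fragmentsPerSample
  .withSeed(seed, {
    chromAcc <- character(0); startAcc <- integer(0); lenAcc <- integer(0)
    while (length(lenAcc) < n) {
      m <- ceiling((n - length(lenAcc)) * pMax * 1.15) + 100L
      isTum <- stats::runif(m) < tumorFraction
      len <- integer(m)
      if (any(isTum))
        len[isTum] <- sample(config@lengthSupport, sum(isTum), replace = TRUE,
                             prob = config@tumorLengthLaw)
      if (any(!isTum))
        len[!isTum] <- sample(config@lengthSupport, sum(!isTum), replace = TRUE,
                              prob = config@healthyLengthLaw)
      si <- sample.int(nrow(segs), m, replace = TRUE, prob = segW)
      chrom <- segs$chrom[si]
      pos <- segs$start[si] +
        floor(stats::runif(m) * (segs$end[si] - segs$start[si]))
      start <- pmin(pmax(pos - len %/% 2L, 0L), chromLen[chrom] - len)
      mid <- start + len %/% 2L
      keepP <- rep(1, m)
      if (!is.null(sites) && tumorFraction > 0) {
        for (ch in unique(sites$chrom)) {
          sc <- sites[sites$chrom == ch, ]
          onCh <- which(chrom == ch)
          if (!length(onCh)) next
          j <- findInterval(mid[onCh], sc$center)
          jlo <- pmax(j, 1L); jhi <- pmin(j + 1L, nrow(sc))
          nearest <- ifelse(abs(mid[onCh] - sc$center[jlo]) <=
                              abs(mid[onCh] - sc$center[jhi]), jlo, jhi)
          off <- mid[onCh] - sc$center[nearest]
          keepP[onCh] <- .tssRate(off, tumorFraction,
                                  sc$depletion[nearest], sc$amplitude[nearest],
                                  config@dipSigma, config@periodBp)
        }
      }
      keep <- stats::runif(m) < keepP / pMax
      chromAcc <- c(chromAcc, chrom[keep])
      startAcc <- c(startAcc, as.integer(start[keep]))
      lenAcc <- c(lenAcc, len[keep])
    }
    chrom <- chromAcc[seq_len(n)]; start <- startAcc[seq_len(n)]
    len <- lenAcc[seq_len(n)]
    mid <- start + len %/% 2L
    gc <- .windowGC(genome, chrom, mid)
    mapq <- ifelse(stats::runif(n) < 0.05, 30L, 60L)
    ## mismatch injection: baseline noise + tumor-fraction-scaled class excess
    classRate <- config@mismatchNoiseRate / 96 + tumorFraction * config@snsTruth
    lam <- sum(classRate)
    k <- stats::rpois(n, lam)
    fragIdx <- rep(which(k > 0L), k[k > 0L])
    M <- length(fragIdx)
    mm <- emptyMismatches()
    if (M) {
      cls <- sample(snsClasses(), M, replace = TRUE, prob = classRate / lam)
      ctx <- .classContext(cls)                   # pyrimidine-strand tri + alt
      flip <- stats::runif(M) < 0.5               # random reported strand
      refTri <- ifelse(flip, .revcompTri(ctx$tri), ctx$tri)
      alt <- ifelse(flip, .complementBase(ctx$alt), ctx$alt)
      pos <- start[fragIdx] +
        floor(stats::runif(M) * len[fragIdx])
      baseq <- ifelse(stats::runif(M) < 0.05, 25L, 37L)
      mm <- data.frame(frag = fragIdx, pos = as.integer(pos), ref_tri = refTri,
                       alt = alt, baseq = baseq)
      mm <- mm[order(mm$frag), ]; rownames(mm) <- NULL
    }
    FragmentSample(sampleId,
      fragments = data.frame(chrom = chrom, start = start, end = start + len,
                             gc = gc, mapq = mapq,
                             n_mismatch = tabulate(mm$frag, nbins = n)),
      mismatches = mm, label = label,
      metadata = list(tumor_fraction = tumorFraction, seed = seed))
  })
}

#' Simulate a labeled cohort
#'
#' `nCancer` cancer samples with tumor fractions drawn from the configured
#' uniform law, plus `nControl` controls at tumor fraction 0. Per-sample
#' seeds are drawn from the cohort seed, so the whole cohort is reproducible.
#'
#' @param config A [CohortConfig-class].
#' @return List with elements `samples` (list of [FragmentSample-class]) and
#'   `truth` (a [CohortTruth-class]).
#' @export
simulateCohort <- function(config) {
  methods::validObject(config)
  nC <- config@nCancer; nH <- config@nControl
  .withSeed(config@seed, {
    tf <- stats::runif(nC, config@tfLaw[1], config@tfLaw[2])
    seeds <- sample.int(.Machine$integer.max - 1L, nC + nH)
    ids <- c(sprintf("cancer_%02d", seq_len(nC)),
             sprintf("control_%02d", seq_len(nH)))
    labels <- rep(c("cancer", "non_cancer"), c(nC, nH))
    tfAll <- c(tf, rep(0, nH))
    samples <- lapply(seq_along(ids), function(i)
      simulateSample(config, labels[i], tfAll[i], seeds[i], ids[i]))
    truth <- methods::new("CohortTruth",
      table = data.frame(sample_id = ids, label = labels,
                         tumor_fraction = tfAll, seed = seeds),
      params = list(cnv = config@cnvTruth, tss = config@tssTruth,
                    sns = config@snsTruth, tfLaw = config@tfLaw,
                    panel = config@panel))
    list(samples = samples, truth = truth)
  })
}

#' Plant a synthetic SNP/CHIP blacklist and inject its mismatches
#'
#' `plantBlacklist()` draws random genomic positions with random substitution
#' identities; `injectBlacklistMismatches()` adds the corresponding mismatch
#' to every fragment overlapping a blacklisted position (simulating germline
#' SNP / clonal-hematopoiesis contamination that the spectrum extractor must
#' filter out).
#'
#' @param genome A [GenomeSpec-class].
#' @param n Number of blacklist positions.
#' @param seed RNG seed.
#' @return `plantBlacklist()`: `data.frame(chrom, pos, ref, alt, ref_tri)`;
#'   `injectBlacklistMismatches()`: a new [FragmentSample-class].
#' @export
plantBlacklist <- function(genome, n = 50L, seed = 7L) {
  .withSeed(seed, {
    i <- sample.int(nrow(genome@chromosomes), n, replace = TRUE)
    chrom <- genome@chromosomes$chrom[i]
    pos <- as.integer(floor(stats::runif(n) * (genome@chromosomes$length[i] - 2L)) + 1L)
    bases <- c("A", "C", "G", "T")
    tri <- paste0(sample(bases, n, TRUE), sample(bases, n, TRUE),
                  sample(bases, n, TRUE))
    ref <- substr(tri, 2, 2)
    alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
    data.frame(chrom = chrom, pos = pos, ref = ref, alt = unname(alt),
               ref_tri = tri)
  })
}

#' @rdname plantBlacklist
#' @param sample A [FragmentSample-class].
#' @param blacklist Output of [plantBlacklist()].
#' @param baseq Base quality assigned to injected mismatches.
#' @export
injectBlacklistMismatches <- function(sample, blacklist, baseq = 37L) {
  fr <- fragments(sample)
  mm <- mismatchTable(sample)
  add <- list()
  for (k in seq_len(nrow(blacklist))) {
    hit <- which(fr$chrom == blacklist$chrom[k] &
                   fr$start <= blacklist$pos[k] & fr$end > blacklist$pos[k])
    if (length(hit))
      add[[length(add) + 1L]] <- data.frame(
        frag = hit, pos = blacklist$pos[k], ref_tri = blacklist$ref_tri[k],
        alt = blacklist$alt[k], baseq = baseq)
  }
  if (length(add)) {
    mm <- rbind(mm, do.call(rbind, add))
    mm <- mm[order(mm$frag), ]; rownames(mm) <- NULL
  }
  fr$n_mismatch <- tabulate(mm$frag, nbins = nrow(fr))
  FragmentSample(sample@sampleId, fr, mm, sample@label, sample@metadata)
}
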