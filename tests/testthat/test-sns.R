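test_that("substitution classification matches the strand-collapse oracle on
           all 192 raw contexts", {
  expect_equal(classifySubstitution("ACA", "T"), "A[C>T]A")
  expect_equal(classifySubstitution("AGT", "C"), "A[C>G]T")
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(x = bases, r = bases, y = bases, alt = bases,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$r != grid$alt, ]
  tri <- paste0(grid$x, grid$r, grid$y)
  got <- classifySubstitution(tri, grid$alt)
  ## exactly the canonical 96, each hit exactly twice (both strands)
  expect_setequal(got, snsClasses())
  expect_true(all(table(got) == 2L))
  ## independent reverse-complement oracle (Biostrings)
  skip_if_not_installed("Biostrings")
  rc <- function(x) as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(x)))
  oracle <- ifelse(grid$r %in% c("A", "G"),
                   paste0(substr(rc(tri), 1, 1), "[", substr(rc(tri), 2, 2),
                          ">", rc(grid$alt), "]", substr(rc(tri), 3, 3)),
                   paste0(grid$x, "[", grid$r, ">", grid$alt, "]", grid$y))
  expect_equal(got, oracle)
  expect_error(classifySubstitution("ACA", "C"), "differ")
  expect_error(classifySubstitution("ANA", "T"), "non-ACGT")
})

## one fragment per row, each carrying one mismatch of the given class
spectrumFixture <- function(n = 10L, tri = "ACG", alt = "T", baseq = 37L,
                            mapq = 60L, len = 166L, nExtra = 0L) {
  start <- seq(0L, by = 1000L, length.out = n)
  fr <- data.frame(chrom = "chr1", start = start, end = start + len,
                   gc = 0.4, mapq = mapq, n_mismatch = 1L + nExtra)
  mm <- data.frame(frag = seq_len(n), pos = start + 10L, ref_tri = tri,
                   alt = alt, baseq = baseq)
  if (nExtra > 0L) {
    extra <- do.call(rbind, replicate(nExtra, mm, simplify = FALSE))
    extra$pos <- extra$pos + 5L
    mm <- rbind(mm, extra)
  }
  FragmentSample("fix", fr, mm[order(mm$frag), ])
}

test_that("passing mismatches count into their class; filters exclude
           boundary violations one by one", {
  gLen <- 1e6
  s <- spectrumFixture(10L)
  sp <- snsSpectrum(s, flatBiasCurve(), gLen)
  expect_equal(unname(sp@counts["A[C>T]G"]), 10)
  expect_equal(sum(sp@counts), 10)
  ## normalization: counts / (total bases / genome length)
  expect_equal(unname(sp@normalized["A[C>T]G"]), 10 / (10 * 166 / gLen))
  ## each filter drops everything when violated at the boundary
  expect_equal(sum(snsSpectrum(spectrumFixture(baseq = 29L),
                               flatBiasCurve(), gLen)@counts), 0)
  expect_equal(sum(snsSpectrum(spectrumFixture(mapq = 59L),
                               flatBiasCurve(), gLen)@counts), 0)
  expect_equal(sum(snsSpectrum(spectrumFixture(len = 301L),
                               flatBiasCurve(), gLen)@counts), 0)
  expect_equal(sum(snsSpectrum(spectrumFixture(nExtra = 1L),
                               flatBiasCurve(), gLen)@counts), 0)
  ## boundary values pass
  expect_equal(sum(snsSpectrum(spectrumFixture(baseq = 30L, len = 300L),
                               flatBiasCurve(), gLen)@counts), 10)
  ## no mismatches at all: zero spectrum
  s0 <- uniformSample(100L, seed = 2L)
  expect_equal(sum(snsSpectrum(s0, flatBiasCurve(), gLen)@counts), 0)
})

test_that("relaxing any threshold never decreases any class count", {
  cfg <- smallConfig(fragmentsPerSample = 20000L)
  s <- simulateSample(cfg, "cancer", 0.5, seed = 44L)
  gLen <- genomeLength(cfg@genome)
  strict <- snsSpectrum(s, flatBiasCurve(), gLen)@counts
  for (relaxed in list(
    snsSpectrum(s, flatBiasCurve(), gLen, baseqMin = 0L)@counts,
    snsSpectrum(s, flatBiasCurve(), gLen, mapqMin = 0L)@counts,
    snsSpectrum(s, flatBiasCurve(), gLen, tlenMax = 10000L)@counts))
    expect_true(all(relaxed >= strict - 1e-12))
})

test_that("blacklisted positions are excluded from the spectrum", {
  cfg <- smallConfig()
  s <- simulateSample(cfg, "non_cancer", 0, seed = 30L)
  bl <- plantBlacklist(cfg@genome, n = 300L, seed = 31L)
  s2 <- injectBlacklistMismatches(s, bl)
  gLen <- genomeLength(cfg@genome)
  with_bl <- snsSpectrum(s2, flatBiasCurve(), gLen, snpBlacklist = bl)
  without <- snsSpectrum(s2, flatBiasCurve(), gLen)
  expect_lt(sum(with_bl@counts), sum(without@counts))
  ## filtering recovers the spectrum of the uncontaminated sample for
  ## fragments that remain single-mismatch
  clean <- snsSpectrum(s, flatBiasCurve(), gLen)
  expect_lte(abs(sum(with_bl@counts) - sum(clean@counts)),
             0.1 * sum(clean@counts) + 5)
})

test_that("baselines average normalized spectra and subtract class-wise", {
  gLen <- 1e6
  pool <- lapply(1:20, function(i)
    snsSpectrum(spectrumFixture(i), flatBiasCurve(), gLen))
  base <- buildSNSBaseline(pool)
  ## brute-force per-class mean oracle
  oracle <- rowMeans(vapply(pool, function(s) s@normalized, numeric(96)))
  expect_equal(base@values, oracle)
  ## identical pool members reproduce the member
  base2 <- buildSNSBaseline(pool[c(3, 3)])
  expect_equal(base2@values, pool[[3]]@normalized)
  ## {0, 2} -> 1
  two <- pool[[1]]; two@normalized["A[C>T]G"] <- 2
  zero <- pool[[1]]; zero@normalized["A[C>T]G"] <- 0
  expect_equal(unname(buildSNSBaseline(list(two, zero))@values["A[C>T]G"]), 1)
  expect_error(buildSNSBaseline(pool[1]), ">= 2")
  ## subtraction identities
  sp <- pool[[5]]
  adj <- subtractBaseline(sp, base)
  expect_equal(adj@adjusted, sp@normalized - base@values)
  selfbase <- buildSNSBaseline(list(sp, sp))
  expect_equal(unname(subtractBaseline(sp, selfbase)@adjusted), rep(0, 96))
})

test_that("elevated classes separate cancer from control on an SNS-only
           cohort (rank-sum)", {
  sns <- stats::setNames(rep(0, 96), snsClasses())
  sns[elevatedSNSClasses()] <- 0.02            # strong-effect configuration
  cfg <- smallConfig(nCancer = 20L, nControl = 20L,
                     fragmentsPerSample = 20000L, channels = "sns",
                     snsTruth = sns, tfLaw = c(0.2, 0.5), seed = 202L)
  co <- simulateCohort(cfg)
  gLen <- genomeLength(cfg@genome)
  spectra <- lapply(co$samples, function(s)
    snsSpectrum(s, flatBiasCurve(), gLen))
  isCtrl <- co$truth@table$label == "non_cancer"
  base <- buildSNSBaseline(spectra[isCtrl])
  elevSum <- vapply(spectra, function(s)
    sum(subtractBaseline(s, base)@adjusted[elevatedSNSClasses()]), numeric(1))
  p <- stats::wilcox.test(elevSum[!isCtrl], elevSum[isCtrl],
                          alternative = "greater")$p.value
  expect_lt(p, 0.01)
})
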