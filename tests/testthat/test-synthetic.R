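test_that("simulation is deterministic given the seed and exact in count", {
  cfg <- smallConfig()
  a <- simulateSample(cfg, "cancer", 0.1, seed = 5L)
  b <- simulateSample(cfg, "cancer", 0.1, seed = 5L)
  expect_identical(fragments(a), fragments(b))
  expect_identical(mismatchTable(a), mismatchTable(b))
  expect_equal(nFragments(a), cfg@fragmentsPerSample)
  c <- simulateSample(cfg, "cancer", 0.1, seed = 6L)
  expect_false(identical(fragments(a), fragments(c)))
  expect_identical(names(fragments(a)), names(fragments(c)))
  expect_error(simulateSample(cfg, "cancer", 1.5, seed = 1L), "\\[0, 1\\]")
})

test_that("tumor-fraction-0 fragment lengths follow the healthy law (KS)", {
  cfg <- smallConfig(fragmentsPerSample = 50000L)
  s <- simulateSample(cfg, "non_cancer", 0, seed = 3L)
  lens <- fragments(s)$length
  empCdf <- cumsum(tabulate(lens - 79L, nbins = 181L)) / length(lens)
  lawCdf <- cumsum(cfg@healthyLengthLaw)
  expect_lt(max(abs(empCdf - lawCdf)), 0.02)
})

test_that("mean fragment length strictly decreases with tumor fraction", {
  cfg <- smallConfig(fragmentsPerSample = 50000L)
  means <- vapply(c(0, 0.05, 0.2, 1), function(tf)
    mean(fragments(simulateSample(cfg, "cancer", tf, seed = 9L))$length),
    numeric(1))
  expect_true(all(diff(means) < 0))
})

test_that("copy-number placement follows the analytic mixture rate", {
  ## at tf = 1 a CN-4 region is covered twice as densely as CN-2 background
  cfg <- smallConfig(fragmentsPerSample = 50000L,
                     cnvTruth = data.frame(chrom = "chr1", start = 10e6,
                                           end = 20e6, cn = 4),
                     channels = "cnv")
  s <- simulateSample(cfg, "cancer", 1, seed = 13L)
  fr <- fragments(s)
  mid <- (fr$start + fr$end) %/% 2L
  inGain <- fr$chrom == "chr1" & mid >= 10e6 & mid < 20e6
  ## expected fraction: 2*10 / (2*10 + 90) of all fragments
  pGain <- 20 / 110
  phat <- mean(inGain)
  se <- sqrt(pGain * (1 - pGain) / nFragments(s))
  expect_lt(abs(phat - pGain), 4 * se)
})

test_that("control fragment GC matches the genome reference distribution", {
  cfg <- smallConfig(fragmentsPerSample = 50000L)
  s <- simulateSample(cfg, "non_cancer", 0, seed = 17L)
  g <- testGenome()
  obs <- tabulate(cfgastro:::.strataIndex(fragments(s)$gc), nbins = 51L)
  ref <- tabulate(cfgastro:::.strataIndex(g@windows$gc), nbins = 51L)
  expect_lt(max(abs(obs / sum(obs) - ref / sum(ref))), 0.01)
})

test_that("cohorts have exact sizes, labeled tumor fractions and truth", {
  cfg <- smallConfig(nCancer = 5L, nControl = 5L,
                     fragmentsPerSample = 2000L, seed = 42L)
  co <- simulateCohort(cfg)
  expect_length(co$samples, 10L)
  tt <- co$truth@table
  expect_equal(sum(tt$tumor_fraction > 0), 5L)
  expect_true(all(tt$tumor_fraction[tt$label == "non_cancer"] == 0))
  expect_true(all(tt$tumor_fraction >= cfg@tfLaw[1] - 1e-12 |
                    tt$tumor_fraction == 0))
  ## reproducible from the cohort seed
  co2 <- simulateCohort(cfg)
  expect_identical(fragments(co$samples[[3]]), fragments(co2$samples[[3]]))
})

test_that("realized tumor fractions match the configured law's moments", {
  cfg <- smallConfig(nCancer = 200L, nControl = 1L, fragmentsPerSample = 50L,
                     seed = 8L)
  co <- simulateCohort(cfg)
  tf <- co$truth@table$tumor_fraction
  tf <- tf[tf > 0]
  m <- mean(cfg@tfLaw); v <- diff(cfg@tfLaw)^2 / 12
  expect_lt(abs(mean(tf) - m), 3 * sqrt(v / 200))
})

test_that("effect channels are independently switchable", {
  base <- smallConfig(channels = character(0))
  expect_equal(base@tumorLengthLaw, base@healthyLengthLaw)
  expect_equal(nrow(base@cnvTruth), 0L)
  expect_true(all(base@tssTruth$depletion == 0))
  expect_true(all(base@snsTruth == 0))
  only_sns <- smallConfig(channels = "sns")
  expect_gt(sum(only_sns@snsTruth), 0)
  expect_equal(only_sns@tumorLengthLaw, only_sns@healthyLengthLaw)
})

test_that("planted blacklist mismatches are injected into overlapping fragments", {
  cfg <- smallConfig()
  s <- simulateSample(cfg, "non_cancer", 0, seed = 30L)
  bl <- plantBlacklist(cfg@genome, n = 200L, seed = 31L)
  s2 <- injectBlacklistMismatches(s, bl)
  expect_gt(nrow(mismatchTable(s2)), nrow(mismatchTable(s)))
  expect_true(methods::validObject(s2))
})
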