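test_that("uniform samples give per-bin depth ~ 1 within Poisson error", {
  g <- testGenome()
  sc <- makeBinScheme(g, 1e6)
  s <- uniformSample(100000L, g, seed = 12L)
  d <- binDepth(s, sc, flatBiasCurve())
  expect_equal(mean(d), 1)
  perBin <- 100000L / nBins(sc)
  expect_lt(max(abs(d - 1)), 4 / sqrt(perBin))   # ~4 sigma
})

test_that("bin depth matches a counting oracle and empty bins give 0", {
  g <- toyGenome(nChrom = 1L, chromLength = 1e7)
  sc <- makeBinScheme(g, 1e6)
  ## all fragments concentrated in bin 3
  n <- 2000L
  set.seed(8)
  start <- as.integer(2e6 + floor(runif(n) * (1e6 - 166)))
  s <- FragmentSample("conc", data.frame(
    chrom = "chr1", start = start, end = start + 166L, gc = 0.4,
    mapq = 60L, n_mismatch = 0L))
  d <- binDepth(s, sc, flatBiasCurve())
  expect_equal(d[3], 10)           # all mass in 1 of 10 bins, mean-normalized
  expect_true(all(d[-3] == 0))
  ## a bin holding 2x the fragments of the others sits at ~2x depth
  start2 <- as.integer(c(floor(runif(n) * (1e7 - 166)),
                         4e6 + floor(runif(n / 10) * (1e6 - 166))))
  s2 <- FragmentSample("double", data.frame(
    chrom = "chr1", start = start2, end = start2 + 166L, gc = 0.4,
    mapq = 60L, n_mismatch = 0L))
  d2 <- binDepth(s2, sc, flatBiasCurve())
  expect_equal(d2[5] / mean(d2[-5]), 2, tolerance = 0.15)
  expect_warning(
    binDepth(FragmentSample("none", fragments(s)[0, ]), sc, flatBiasCurve()),
    "zero fragments")
})

test_that("depth baselines are per-bin medians, robust and floored", {
  g <- toyGenome(nChrom = 1L, chromLength = 5e6)
  sc <- makeBinScheme(g, 1e6)
  pool <- list(rep(1, 5), rep(1, 5), rep(1, 5), rep(1, 5), c(9, 1, 1, 1, 1))
  b <- buildDepthBaseline(pool, sc)
  expect_equal(b@depth, rep(1, 5))          # outlier sample has no effect
  expect_equal(buildDepthBaseline(pool[c(1, 2, 5)], sc)@depth[1], 1)
  ## identical members reproduce any member
  expect_equal(buildDepthBaseline(pool[1:3], sc)@depth, pool[[1]])
  ## zero medians floored
  z <- list(rep(0, 5), rep(0, 5), rep(0, 5))
  expect_equal(buildDepthBaseline(z, sc)@depth, rep(1e-3, 5))
  expect_error(buildDepthBaseline(pool[1:2], sc), ">= 3")
})

test_that("log2 ratios are exact, antisymmetric and scheme-checked", {
  g <- toyGenome(nChrom = 1L, chromLength = 5e6)
  sc <- makeBinScheme(g, 1e6)
  base <- buildDepthBaseline(list(rep(1, 5), rep(1, 5), rep(1, 5)), sc)
  expect_equal(unname(cnvVector(rep(1, 5), base)), rep(0, 5))
  expect_equal(unname(cnvVector(c(2, 1, 1, 1, 1), base))[1], 1)
  ## antisymmetry: swapping depth and baseline negates the ratios
  d <- c(0.5, 1, 2, 1.2, 0.8)
  baseD <- buildDepthBaseline(list(d, d, d), sc)
  expect_equal(unname(cnvVector(rep(1, 5), baseD)),
               -unname(cnvVector(d, base)))
  expect_error(cnvVector(rep(1, 4), base), "different schemes")
})

test_that("a control scored against its own cohort baseline stays near 0", {
  g <- testGenome()
  sc <- makeBinScheme(g, 1e6)
  pool <- lapply(1:4, function(i)
    binDepth(uniformSample(100000L, g, seed = 40L + i), sc, flatBiasCurve()))
  base <- buildDepthBaseline(pool, sc)
  lr <- cnvVector(pool[[1]], base)
  expect_lt(median(abs(lr)), 0.05)
})

test_that("copy-gain log2 ratios recover the analytic mixture value", {
  ## focused spot check (the full tf x CN grid runs in the acceptance suite)
  g <- testGenome()
  sc <- makeBinScheme(g, 1e6)
  cfg <- smallConfig(fragmentsPerSample = 100000L,
                     cnvTruth = data.frame(chrom = "chr1", start = 20e6,
                                           end = 25e6, cn = 3),
                     channels = "cnv")
  ctrl <- lapply(1:3, function(i)
    simulateSample(cfg, "non_cancer", 0, seed = 50L + i))
  pool <- lapply(ctrl, function(x) binDepth(x, sc, estimateGCBias(x, g)))
  base <- buildDepthBaseline(pool, sc)
  can <- simulateSample(cfg, "cancer", 0.2, seed = 60L)
  lr <- cnvVector(binDepth(can, sc, estimateGCBias(can, g)), base)
  gained <- grepl("chr1_2[01234]000000", names(lr))
  expect_equal(sum(gained), 5L)
  recovered <- mean(lr[gained]) - median(lr[!gained])
  expect_equal(recovered, log2(1 + 0.2 / 2), tolerance = 0.03 / 0.1375)
})
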