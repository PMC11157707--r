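## helper to wrap a numeric profile into a CoverageProfile (raw = values)
mkProfile <- function(v, tf = "TF") {
  raw <- v / mean(v)
  methods::new("CoverageProfile", tfName = tf, values = raw, raw = raw,
               nSites = 1L)
}

test_that("flat profiles map to (flank, central, amp) = (1, 1, 0)", {
  v <- ncpVector(list(mkProfile(rep(1, 667))))
  expect_equal(unname(v), c(1, 1, 0))
  expect_error(ncpVector(list(methods::new("CoverageProfile", tfName = "x",
                                           values = rep(1, 10),
                                           raw = rep(1, 10), nSites = 1L))),
               "667")
})

test_that("the FFT amplitude of a pure k = 53 cosine is exact", {
  i <- 0:666
  for (a in c(0.05, 0.2)) {
    prof <- mkProfile(1 + a * cos(2 * pi * 53 * i / 667))
    v <- ncpVector(list(prof), smoothed = FALSE)
    expect_equal(unname(v[3]), a, tolerance = 1e-6)
  }
  ## phase does not matter
  prof <- mkProfile(1 + 0.2 * cos(2 * pi * 53 * i / 667 + 1.1))
  expect_equal(unname(ncpVector(list(prof))[3]), 0.2, tolerance = 1e-6)
})

test_that("a single fragment lands its weight in the centre bin", {
  g <- toyGenome(nChrom = 1L, chromLength = 1e6)
  center <- 500000L
  s <- FragmentSample("one", data.frame(
    chrom = "chr1", start = center - 75L, end = center + 75L, gc = 0.4,
    mapq = 60L, n_mismatch = 0L))
  pr <- siteCoverageProfile(s, data.frame(chrom = "chr1", center = center),
                            flatBiasCurve(), "T1")
  expect_equal(which(pr@raw > 0), 334L)
})

test_that("profiles are mean-1 normalized and smoothing preserves the mean", {
  g <- toyGenome(nChrom = 1L, chromLength = 1e7)
  pan <- defaultTFPanel(g, tfs = "TF1", sitesPerTF = 100L, seed = 5L)
  cfg <- smallConfig(fragmentsPerSample = 200000L, genome = g, panel = pan,
                     tssTruth = data.frame(tf = "TF1", depletion = 0,
                                           amplitude = 0))
  s <- simulateSample(cfg, "non_cancer", 0, seed = 19L)
  pr <- siteCoverageProfile(s, pan[, c("chrom", "center")],
                            flatBiasCurve(), "TF1")
  expect_equal(mean(pr@raw), 1, tolerance = 1e-9)
  expect_equal(mean(pr@values), 1, tolerance = 1e-3)
  ## uniform coverage: every bin ~ 1, amplitude ~ 0
  expect_lt(max(abs(pr@values - 1)), 0.5)
  expect_lt(unname(ncpVector(list(pr))[3]), 0.05)
})

test_that("N identical sites give the same profile as a single site", {
  g <- toyGenome(nChrom = 1L, chromLength = 1e6)
  s <- uniformSample(20000L, g, seed = 23L)
  one <- data.frame(chrom = "chr1", center = 500000L)
  many <- one[rep(1L, 7L), ]
  p1 <- siteCoverageProfile(s, one, flatBiasCurve(), "T")
  p7 <- siteCoverageProfile(s, many, flatBiasCurve(), "T")
  expect_equal(p7@raw, p1@raw)
  expect_equal(p7@values, p1@values)
})

test_that("zero in-window fragments yield an all-zero profile with warning", {
  g <- toyGenome(nChrom = 1L, chromLength = 1e6)
  s <- FragmentSample("far", data.frame(
    chrom = "chr1", start = 1000L, end = 1166L, gc = 0.4, mapq = 60L,
    n_mismatch = 0L))
  expect_warning(
    pr <- siteCoverageProfile(s, data.frame(chrom = "chr1", center = 900000L),
                              flatBiasCurve(), "T"),
    "all-zero")
  expect_true(all(pr@values == 0))
})

test_that("central coverage decreases monotonically with injected depletion", {
  g <- toyGenome(nChrom = 1L, chromLength = 1e7)
  pan <- defaultTFPanel(g, tfs = "TFX", sitesPerTF = 300L, seed = 5L)
  centrals <- vapply(c(0, 0.25, 0.5, 0.75), function(d) {
    cfg <- cohortConfig(nCancer = 1L, nControl = 1L,
                        fragmentsPerSample = 150000L, genome = g, panel = pan,
                        tssTruth = data.frame(tf = "TFX", depletion = d,
                                              amplitude = 0),
                        channels = "tss")
    s <- simulateSample(cfg, "cancer", 1, seed = 91L)
    pr <- siteCoverageProfile(s, pan[, c("chrom", "center")],
                              flatBiasCurve(), "TFX")
    unname(ncpVector(list(pr))[2])
  }, numeric(1))
  expect_true(all(diff(centrals) < 0))
  ## depth of the d = 0.75 dip is near truth
  expect_equal(1 - centrals[4], 0.75, tolerance = 0.12)
})
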