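## Shared fixtures, built in code. Heavier objects are cached per test run.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cache)) assign(key, force(expr), envir = .cache)
  get(key, envir = .cache)
}

## default 2 x 50 Mb toy genome (deterministic)
testGenome <- function() cached("genome", toyGenome())

## tiny hand-made sample: explicit fragments, no randomness
tinySample <- function(id = "tiny") {
  fr <- data.frame(
    chrom = c("chr1", "chr1", "chr2"),
    start = c(1000L, 5000L, 2000L),
    end   = c(1160L, 5120L, 2220L),
    gc    = c(0.45, 0.50, 0.40),
    mapq  = c(60L, 60L, 30L),
    n_mismatch = c(1L, 0L, 0L))
  mm <- data.frame(frag = 1L, pos = 1050L, ref_tri = "ACA", alt = "T",
                   baseq = 37L)
  FragmentSample(id, fr, mm, label = "unknown")
}

## uniform random fragments over a genome, no cancer effects, bias-neutral GC
uniformSample <- function(n, genome = testGenome(), len = 166L, seed = 1L,
                          id = "unif") {
  chroms <- genome@chromosomes
  set.seed(seed)
  i <- sample.int(nrow(chroms), n, replace = TRUE)
  start <- floor(runif(n) * (chroms$length[i] - len))
  fr <- data.frame(chrom = chroms$chrom[i], start = as.integer(start),
                   end = as.integer(start + len), mapq = 60L, n_mismatch = 0L)
  fr$gc <- cfgastro:::.windowGC(genome, fr$chrom, (fr$start + fr$end) %/% 2L)
  FragmentSample(id, fr, label = "non_cancer")
}

## small cohort config used across module tests
smallConfig <- function(...) {
  args <- list(nCancer = 3L, nControl = 3L, fragmentsPerSample = 10000L)
  over <- list(...)
  args[names(over)] <- over
  do.call(cohortConfig, args)
}

## planted-signal feature blocks for importance-recovery tests:
## 5 variables (2 FSP, 1 CNV, 1 NCP, 1 SNS) carry all the signal
plantedFeatures <- function(n = 60L, delta = 3, seed = 1L) {
  set.seed(seed)
  y <- rep(c(1, 0), each = n / 2)
  mk <- function(p, prefix, planted) {
    x <- matrix(rnorm(n * p), n, p)
    colnames(x) <- paste0(prefix, "_v", seq_len(p))
    for (j in planted) x[, j] <- x[, j] + delta * y
    x
  }
  list(
    features = list(FSP = mk(12L, "fsp", 1:2), CNV = mk(12L, "cnv", 1L),
                    NCP = mk(9L, "ncp", 1L), SNS = mk(20L, "sns", 1L)),
    labels = y,
    planted = c("fsp_v1", "fsp_v2", "cnv_v1", "ncp_v1", "sns_v1"),
    plantedPerType = list(FSP = c("fsp_v1", "fsp_v2"), CNV = "cnv_v1",
                          NCP = "ncp_v1", SNS = "sns_v1"))
}
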