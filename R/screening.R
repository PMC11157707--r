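## Monte Carlo simulation of screening performance in a hypothetical
## population: compliance, sensitivity and specificity are drawn from Beta
## priors; compliers, cases, true positives and true negatives from the
## corresponding Binomials; NPV and FNR are computed per iteration.

#' Construct the screening prior set
#'
#' Defaults are the published prior distributions for gastroscopy (`endo`)
#' and the cfDNA assay (`ctDNA`): compliance Beta(43.8, 56.2) and
#' Beta(80, 20); sensitivity Beta(22, 3.7) and Beta(67, 6); specificity
#' Beta(6000, 1051) and Beta(86, 8); gastric cancer prevalence 0.8% in a
#' population of 100,000. A prior given as a single number is treated as a
#' point mass.
#'
#' @param endo,ctDNA Named lists with `compliance`, `sensitivity`,
#'   `specificity`, each `c(a, b)` Beta shapes or a scalar point mass.
#' @param prevalence Cancer prevalence in (0, 1).
#' @param population Screening population size.
#' @return A [ScreeningPriors-class].
#' @export
screeningPriors <- function(endo = list(compliance = c(43.8, 56.2),
                                        sensitivity = c(22, 3.7),
                                        specificity = c(6000, 1051)),
                            ctDNA = list(compliance = c(80, 20),
                                         sensitivity = c(67, 6),
                                         specificity = c(86, 8)),
                            prevalence = 0.008, population = 1e5) {
  methods::new("ScreeningPriors",
               modalities = list(endo = endo, ctDNA = ctDNA),
               prevalence = prevalence, population = population)
}

.drawProb <- function(n, prior) {
  if (length(prior) == 1L) rep(prior, n) else stats::rbeta(n, prior[1], prior[2])
}

#' Run the screening Monte Carlo simulation
#'
#' Per iteration and modality: compliance `C` ~ Beta; compliers
#' `N` ~ Binomial(population, C); cases among compliers
#' `S` ~ Binomial(N, prevalence); sensitivity `SE` and specificity `SP`
#' ~ Beta; true positives `TP` ~ Binomial(S, SE); true negatives
#' `TN` ~ Binomial(N - S, SP). Then `NPV = TN / (TN + S - TP)` and
#' `FNR = (S - TP) / N`. Degenerate denominators resolve to NPV 1 and FNR 0.
#' Deterministic given `seed`; the caller's RNG stream is untouched.
#'
#' @param priors A [ScreeningPriors-class].
#' @param nIter Iterations per modality (default 10,000).
#' @param seed RNG seed.
#' @return A [ScreeningDraws-class].
#' @export
runScreeningSimulation <- function(priors, nIter = 10000L, seed = 1L) {
  methods::validObject(priors)
  if (nIter < 1L) stop("nIter must be >= 1")
  pop <- priors@population
  prev <- priors@prevalence
  .withSeed(seed, {
    perMod <- lapply(names(priors@modalities), function(m) {
      pr <- priors@modalities[[m]]
      C  <- .drawProb(nIter, pr$compliance)
      N  <- stats::rbinom(nIter, pop, C)
      S  <- stats::rbinom(nIter, N, prev)
      SE <- .drawProb(nIter, pr$sensitivity)
      SP <- .drawProb(nIter, pr$specificity)
      TP <- stats::rbinom(nIter, S, SE)
      TN <- stats::rbinom(nIter, N - S, SP)
      FN <- S - TP
      NPV <- ifelse(TN + FN > 0, TN / (TN + FN), 1)
      FNR <- ifelse(N > 0, FN / N, 0)
      data.frame(modality = m, iter = seq_len(nIter), C = C, N = N, S = S,
                 SE = SE, SP = SP, TP = TP, TN = TN, NPV = NPV, FNR = FNR)
    })
    methods::new("ScreeningDraws", draws = do.call(rbind, perMod),
                 nIter = as.integer(nIter), seed = as.integer(seed))
  })
}

#' Summarize simulation draws
#'
#' Mean and empirical central percentile interval per metric and modality.
#'
#' @param draws A [ScreeningDraws-class].
#' @param ciLevel Central interval mass (default 0.95, i.e. the 2.5 and 97.5
#'   percentiles).
#' @return `data.frame(modality, metric, mean, lo, hi)` over TP, TN, NPV,
#'   FNR.
#' @export
summarizeDraws <- function(draws, ciLevel = 0.95) {
  d <- draws@draws
  if (!nrow(d)) stop("no draws to summarize")
  a <- (1 - ciLevel) / 2
  out <- list()
  for (m in unique(d$modality)) {
    dm <- d[d$modality == m, ]
    for (metric in c("TP", "TN", "NPV", "FNR")) {
      v <- dm[[metric]]
      q <- stats::quantile(v, c(a, 1 - a), names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        modality = m, metric = metric, mean = mean(v), lo = q[1], hi = q[2])
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Closed-form expectations for the screening simulation
#'
#' Independent oracle for the Monte Carlo draws:
#' `E[TP] = population * E[C] * prevalence * E[SE]`,
#' `E[FNR] = prevalence * E[1 - SE]` (exact by conditioning on N > 0), and
#' NPV approximated by plugging prior means into `TN / (TN + FN)`. Beta
#' means are `a / (a + b)`; point masses are their own mean.
#'
#' @param priors A [ScreeningPriors-class].
#' @return `data.frame(modality, expected_tp, expected_fnr, approx_npv)`.
#' @export
analyticExpectations <- function(priors) {
  pm <- function(v) if (length(v) == 1L) v else v[1] / (v[1] + v[2])
  out <- lapply(names(priors@modalities), function(m) {
    pr <- priors@modalities[[m]]
    EC <- pm(pr$compliance); ESE <- pm(pr$sensitivity); ESP <- pm(pr$specificity)
    pop <- priors@population; prev <- priors@prevalence
    TN <- pop * EC * (1 - prev) * ESP
    FN <- pop * EC * prev * (1 - ESE)
    data.frame(modality = m,
               expected_tp = pop * EC * prev * ESE,
               expected_fnr = prev * (1 - ESE),
               approx_npv = TN / (TN + FN))
  })
  do.call(rbind, out)
}
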