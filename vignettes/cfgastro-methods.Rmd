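---
title: "Multi-dimensional cfDNA analysis: models, parameters and design choices"
author: "cfgastro"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-dimensional cfDNA analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfgastro)
```

## Overview

Plasma cell-free DNA (cfDNA) of a cancer patient carries a small admixture of
tumor-derived fragments (the tumor fraction, *tf*). Several orthogonal signals
betray that admixture in low-pass whole-genome sequencing: tumor-derived
fragments are shorter; somatic copy gains tilt per-region coverage; open
chromatin at tumor-active regulatory sites depletes nucleosome-protected
coverage around transcription-factor (TF) binding sites; and somatic mutational
processes shift the spectrum of single-nucleotide substitutions (SNS).
`cfgastro` implements the four corresponding feature extractors, a two-layer
stacked ensemble that combines them into a per-sample cancer score, a
rank-based variable importance scheme, and a Monte Carlo projection of
screening performance at population scale. A synthetic cohort generator with
known ground truth makes every stage testable on a desk.

## The data model

Fragments are the atomic observation: 0-based half-open coordinates, fragment
GC fraction, Phred mapping quality, and per-base reference mismatches
(position, reference trinucleotide, substituted base, base quality). Fragments
are strandless — the strand is meaningless after read pairing. The canonical
interchange format is a plain TSV (`chrom start end gc mapq n_mismatch
mismatches`) that round-trips losslessly, so no alignment infrastructure is
needed to exercise the pipeline.

## GC bias and reciprocal weighting

All extractors weight each fragment by the reciprocal of its GC bias. The bias
curve lives on a fixed 51-point GC grid (step 0.02). Per stratum, the bias is
the median over the genome windows of that stratum of the window's observed
fragment count divided by the genome-wide expectation per window. The median
matters: a focal copy gain concentrates extra coverage in the GC strata of the
gained region, and a mean-based estimator would absorb part of the copy-number
signal into the GC model; a median over hundreds of windows is insensitive to
a minority of copy-altered windows. The raw curve is smoothed by local linear
regression (LOESS, span 0.3 over the occupied strata) and clamped below at
`floor = 0.05`, bounding every reciprocal weight by 20. Strata without
reference mass carry bias 1; strata with reference mass but no observed
fragments are set to the floor rather than trusting an extrapolated fit.
Samples with fewer than 1000 fragments trigger a warning but still return a
curve.

## The four feature families

**Fragment size pattern (FSP).** Short (100–150 bp) and long (151–220 bp)
fragment tallies per 5-Mb bin, GC-weighted, rescaled to a common library-size
target (default 10^6^), then z-scored across bins separately for the two
tracks. Two conventions were left open by the problem statement and are fixed
here: the population (n-denominator) standard deviation is used, and short and
long tracks are standardized separately; both are arguments, not hard-coded.
A degenerate sd of 0 yields all-zero scores instead of an error. Bins come
from a deterministic tiling filtered at window-averaged GC ≥ 0.3 and
mappability ≥ 0.9, with partial terminal tiles dropped (never truncated) so
every bin has identical width.

**Copy number (CNV).** Per-1-Mb-bin GC-weighted midpoint depth, normalized to
sample mean 1, expressed as log2 ratio against a healthy-pool baseline (the
per-bin median over at least three controls, floored at 10^-3^). Only the
log2-ratio stage is modeled: segmentation, subclonality and tumor-fraction
estimation are deliberately out of scope because the classifier consumes the
per-bin ratios directly. Midpoint assignment decides bin membership; under
half-open bins ties cannot occur. A heterozygous-diploid background with a
gain to copy number CN at tumor fraction *tf* has expected ratio
(2(1 − *tf*) + CN·*tf*)/2, which is the recovery target of the tests. Because
sample-level mean normalization shifts all bins by a factor that depends on
the gained fraction, recovery is measured relative to the neutral-background
median — the standard log2-ratio centering.

**Nucleosome coverage pattern (NCP).** For each TF, fragment midpoints
(fragments 100–220 bp) are histogrammed around each binding-site centre into
667 bins of 15 bp (the site sits in the centre bin, index 334; a literal
10-kb/15-bp split is non-integral, so the symmetric centre-bin tiling spanning
±5002.5 bp is used). Site histograms are averaged, normalized to window mean
1, and smoothed with a Savitzky–Golay filter of polynomial order 3. The
nominal 150-bp window is 10 bins — even, which a Savitzky–Golay filter cannot
use — so the window is 11 bins (165 bp), with reflect padding at the edges.
Three scalars summarize each profile: the flanking mean (centre ± 1 kb), the
centre-bin coverage, and the amplitude 2/M·|DFT~k~| of the mean-subtracted
window at harmonic k = 53, whose period 10005/53 ≈ 188.8 bp is the window
harmonic closest to the canonical ~190-bp nucleosome repeat. The amplitude is
computed on the *raw* normalized profile: the single-harmonic projection is
already an average over the full window and thus noise-robust, while the
smoothing filter attenuates the ~190-bp component itself by roughly 17%, which
would bias the feature. Centre coverage is read from a single bin (not a small
central window); TF strand orientation is ignored since the profile summaries
used here are symmetric.

**Substitution spectra (SNS).** Fragments pass if mapping quality ≥ 60,
length ≤ 300 bp and exactly one recorded mismatch; the mismatch passes if its
base quality ≥ 30 and its position is on neither the SNP nor the CHIP
(clonal hematopoiesis) blacklist. Each passing mismatch contributes its
fragment's reciprocal GC weight to one of the 96 canonical classes
(pyrimidine-centred trinucleotide contexts; purine-centred raw contexts are
reverse-complemented, a 192→2→1 collapse that the tests verify exhaustively).
Counts are normalized by mean depth (total fragment bases / genome length) and
adjusted by subtracting a healthy-pool baseline (per-class mean over the
pool). Depth-normalized counts, not proportions, are subtracted; a proportion
mode would change the scale of every adjusted value and is intentionally not
the default. Variant calling itself is out of scope: the fragment table's
mismatch annotations together with the two positional blacklists reproduce
the same downstream arithmetic at desk scale.

## The synthetic cohort generator

The generator is first-class, tested code: it defines the study conditions
under which everything else is validated. Defaults: a 2 × 50 Mb toy genome
with 100-kb windows, smooth reference GC in [0.3, 0.6] and mappability 1;
fragment-length laws are discretized log-normals with modes 166 bp (healthy)
and 145 bp (tumor) — the field's canonical mono-nucleosomal peak and the
left-shift of tumor-derived fragments; tumor fractions uniform on
[0.01, 0.10], the realistic early-stage ctDNA range; two copy-gain segments
(CN 3 and CN 4, 3 Mb each); three TFs of which two are cancer-active
(central depletion 0.5 and 0.25, oscillation amplitude 0.25 and 0.1); and 28
of 96 SNS classes elevated (all C>A contexts plus twelve T>C contexts,
echoing the roughly 30% of classes elevated in cancer plasma), each with
excess rate 0.004 per fragment at *tf* = 1 over a 0.02 baseline noise rate.
Every channel scales linearly with *tf* and is independently switchable, so
each extractor has a clean single-channel recovery oracle.

Two generator details are deliberate. First, the injected nucleosome
oscillation uses period 10005/53 ≈ 188.8 bp — the exact analysis harmonic —
rather than literally 190 bp; a 190-bp cosine is not a Fourier mode of the
10,005-bp window, and the resulting spectral leakage (~18% at k = 53) would
make amplitude recovery systematically biased for reasons unrelated to the
pipeline. Second, per-fragment GC equals the reference GC of the window
holding the fragment midpoint, so control samples reproduce the reference GC
distribution exactly in expectation and the bias-≈-1 property is testable.

What the generator does *not* emulate: sequence-level errors beyond quality
tags, mappability-driven placement bias, chromatin-state correlation between
channels, inter-individual germline variation, and batch effects. Passing
tests therefore demonstrate correctness of the computations and
recoverability of planted effects — not clinical performance on real plasma.

## The ensemble

Per feature type, a random search (default 13 draws per algorithm, i.e. 52
candidates per type and >200 over the four types) runs over elastic-net
logistic regression (`glmnet`), gradient boosting (`xgboost`), random forest
(`randomForest`) and a single-hidden-layer neural network (`nnet`; the width
and weight decay are part of the search space — no architecture beyond one
hidden layer is assumed). Candidates are scored by 5-fold cross-validated
AUROC; the top five per type, regardless of algorithm, become the 20 base
models. Their out-of-fold scores (same folds throughout — stacking on
refit-on-all predictions would leak) feed a second random search over elastic
net, boosting and forest; the five best stacked models are kept and their
predictions averaged. Ties in any top-5 selection break by draw order. The
decision threshold maximizes Youden's J over midpoints between adjacent
sorted unique cross-validated scores plus the two degenerate cuts, ties going
to the lowest threshold.

**Evaluation is fold-honest.** Reporting the stack's cross-validated AUROC
after selecting base models on the full out-of-fold matrix is optimistic:
under a label permutation the top-5-of-52 selection alone pushes apparent
AUROC well above 0.5. The reported `cvAuroc` therefore re-does base-model
selection for each evaluated fold using only AUROC computed without that
fold's rows, and selects stack models by an inner 4-fold cross-validation on
the remaining rows, so the evaluated fold's labels touch nothing upstream of
its own predictions. The deployable model (the 20 + 5 specs used by
`predictEnsemble`) still uses global selection. Nested hyperparameter search
beyond this single level is not performed, and is documented as such.

One caveat the tests respect: with ~60 samples, a *fixed* label permutation
retains chance overlap with the true cancer axis (sd ≈ 0.065 of the
concordance), and since training aligns the score's sign with whatever
overlap exists, the null AUROC distribution is folded above 0.5 even for a
leakage-free pipeline. Null checks therefore average over several
permutations and, for the sharpest test of honesty, also use a cohort
generated with every effect channel disabled, where no latent axis exists.

**Rank-based importance.** Default importances (|coefficient|·sd for the
elastic net, gain for boosting, Gini decrease for the forest, Garson-style
products for the net) are incomparable across algorithms, so only ranks are
used: within each base model the top 25 variables get rank scores 25..1,
everything else 1. Each base model gets a weight score 20..1 from its rank in
the stacking layer; since there are five stacked models rather than one, a
base model's rank is its average importance rank across the five. A
variable's score is the weight-averaged rank score over its type's base
models, standardized to the type maximum, so each type's top variable scores
exactly 1.

**Differential profiling** uses two-sided Wilcoxon rank-sum tests per
feature, without multiplicity adjustment, matching the raw-p convention of
the group-comparison figures this mirrors.

## Population-scale screening simulation

Per iteration and modality: compliance C ~ Beta, compliers
N ~ Binomial(100,000, C), cases S ~ Binomial(N, 0.008), sensitivity and
specificity from their Beta priors, TP ~ Binomial(S, SE),
TN ~ Binomial(N − S, SP); then NPV = TN/(TN + S − TP) and FNR = (S − TP)/N.
The default priors are the published ones — gastroscopy: compliance
Beta(43.8, 56.2), sensitivity Beta(22, 3.7), specificity Beta(6000, 1051);
cfDNA assay: Beta(80, 20), Beta(67, 6), Beta(86, 8) — with the non-integer
shapes used exactly as printed. Point-mass priors are supported for
degenerate checks. Degenerate denominators resolve to NPV 1 and FNR 0.
Intervals reported by `summarizeDraws` are empirical central percentiles of
the per-iteration draws; note that full-prior resimulation yields wider
95% intervals for TP than some published interval constructions, so only the
means are treated as reproduction targets. `analyticExpectations` provides
the closed-form oracle: E[TP] = population·E[C]·prevalence·E[SE],
E[FNR] = prevalence·E[1 − SE], and a plug-in NPV approximation.

## Numerical conventions and degenerate inputs

Standardization over a zero-variance track returns zeros; 0/0-style ratios
resolve to their natural limits (bias 1 for unobserved reference-free strata,
depth 0 for empty bins, NPV 1 / FNR 0 for empty screens); zero baseline
medians are floored at 10^-3^ and GC bias at 0.05, keeping all ratios finite
and all weights bounded; every stochastic routine takes an explicit seed,
restores the caller's RNG stream, and is bit-reproducible given the seed with
single-threaded fits (`xgboost` runs with `nthread = 1`).

## Problem sizes used by the test suite

The suite exercises the pipeline at sizes chosen for minutes-scale runs while
keeping every statistical check well-powered: a 60-sample strong-effect
cohort (tumor fractions uniform on [0.10, 0.30]) at 50,000 fragments per
sample for ensemble structure and separation; 100,000–400,000-fragment
single-channel samples for CNV and NCP parameter recovery; 10,000 iterations
for the screening simulation. Larger cohorts are a matter of configuration,
not code.

## Known limitations

The baselines (depth and SNS) in `cohortFeatures` are built from the cohort's
controls, mirroring the role of an external healthy pool; when the same
controls also appear in cross-validation test folds this shares the baseline
(not the labels) across the split — acceptable here, but an external pool is
preferable on real data. The GC model is shared across all four extractors
rather than re-estimated per feature family. Real-genome mappability tracks,
curated TF panels and variant calling are inputs, not products, of this
package; published bin counts that depend on specific reference tracks
(e.g. 541 five-Mb bins on hg19) are consequently not reproduction targets.
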