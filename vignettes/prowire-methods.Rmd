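---
title: "Methods: quantifying transcriptional reprogramming from nascent-transcription tracks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying transcriptional reprogramming from nascent-transcription tracks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

prowire analyzes strand-specific, base-resolution nascent-transcription
coverage (PRO-seq-type data, where each read marks the 3' end of a nascent
RNA and therefore the active site of an engaged RNA polymerase) across two
conditions — here called NHS (unstressed) and HS (a 30-minute acute heat
shock). This vignette is the package's own account of the models and the
numerical choices behind each stage. Everything quantitative stated here is
computed by the test suite or by `scripts/acceptance.R`; nothing is quoted
from external data.

## The measurement model

A `signal_track` stores non-negative per-base signal for each strand of each
chromosome. All coordinates are 0-based half-open (BED convention), and every
quantification is performed in an element's own 5'→3' frame: relative
position 0 is the TSS base, positive positions run into the gene, and for
minus-strand elements the genomic axis is mirrored and the physical strands
swap roles ("sense" vs "antisense"). Mirroring twice is the identity, a
property the test suite asserts.

Three per-gene statistics drive the analysis:

* **Pause**: the maximal 50-nt window on the coding strand within −100..+400
  nt of the TSS, scored as RPK (reads per kilobase; `1000 × count / 50`).
  The scan uses a 1-bp step — the only reading under which "the window with
  the highest read count" is well defined — and breaks ties toward the most
  upstream placement, so a pause that tightens toward the TSS is measured
  deterministically. The step is exposed as `pause_scan_step`.
* **Divergent initiation**: the same 50-nt scan on the antisense strand over
  −800..+100 nt. The overlap with the sense search region is permitted as
  defined.
* **Body**: mean RPK from +500 nt after the TSS to −500 nt before the polyA
  site. Genes shorter than 1000 bp have an empty body; they keep their pause
  call and carry `NA` body and pausing index rather than being dropped
  silently.

The **pausing index** is pause-window RPK divided by body RPK. Both terms are
already length-normalized densities, which makes the index dimensionless and
comparable across genes; it is undefined (NA) when the body density is zero.

## Normalization

Within a 30-minute stress, engaged polymerases travel at most
`elongation_rate × hs_duration` bp (default 2 kb/min × 30 min = 60 kb), so
for genes longer than 150 kb the interval from +100 kb after the TSS to
−0.5 kb before the polyA site cannot yet have been reached by an advancing or
receding wave. Those intervals are condition-invariant by construction and
anchor the cross-sample scale factors. The default estimator is the ratio of
total reference-region counts (both strands summed — 3' gene ends are
dominated by sense signal, so the choice is insensitive); a
median-of-per-region-ratios variant is available via `method =
"median_ratio"`. Factors are fitted per replicate; pooling is the caller's
choice of inputs. `apply_scale()` refuses double application because
re-scaling an already normalized track is almost always a pipeline bug.

## Differential transcription

`nb_test()` is a negative-binomial Wald test on raw counts (gene-body
sense-strand counts for genes; per-strand whole-element counts for dTREs),
with size factors carrying the normalization — testing RPK would destroy the
count distributions. Per feature, dispersion is estimated by method of
moments across replicates and then **moderated toward the across-feature
common dispersion** with `prior_df = 10` pseudo-degrees of freedom. The
moderation is the one place this package deliberately departs from a plain
per-feature moment estimate: with two replicates per condition the raw
moment estimator is so noisy that the far tail of the Wald statistic
inflates roughly tenfold at α = 0.001, while the moderated estimator keeps
the empirical type-I error within twice nominal (asserted by the test
suite on 5000-feature null simulations). The common dispersion is the mean
(not median) of the per-feature estimates because the moment estimator is
right-skewed at small replicate numbers and the median would understate it.
There is no shrinkage *trend* over the mean — a documented simplification
relative to full empirical-Bayes machinery; an independent NB implementation
(DESeq2) is used in the tests as a cross-check oracle, never as the
implementation.

Response classes use fixed raw-p cutoffs, not adjusted p-values (a BH column
is emitted for reference only): Up/Down require p ≤ 0.001 and fold-change
magnitude ≥ 1.25 plus a detector-identified TRE of score ≥ 0.7 within 200 bp
of the TSS; genes without such a TRE are `Filtered`, untranscribed genes are
`UnExp`, and the remainder is `UnCh`. The five classes partition the gene
set. dTREs are tested per strand at p ≤ 0.05 and FC ≥ 1.25; a significant
change on either strand suffices, and the rare case of opposite significant
strands is reported as `discordant` rather than silently resolved either way.

## High-resolution TRE refinement

Broad candidate TRE regions (with detector scores) are inputs, not a product
of this package. Refinement imputes DNaseI hypersensitivity — which peaks
between divergently oriented paused polymerases — from PRO-seq shape using
ε-support-vector regression with a Gaussian kernel. Features are log1p
counts in 50-bp windows, 10 per side per strand (≈1 kb of context; both
config-exposed); targets are log1p DNaseI values (a flag disables the
transform). γ, C and ε are chosen on a small log-spaced grid by Pearson
correlation on a holdout split.

Peaks are called on the imputed profile (10-bp step, candidate regions
extended 200 bp) by a penalized cubic smoothing spline: strict local maxima
of the spline with height ≥ τ, apexes closer than 150 bp merged keeping the
higher, peak extent the run where the spline stays above max(τ, half apex
height). λ (smoothness) and τ (intensity threshold) are tuned by grid search
against truth peaks, maximizing sensitivity subject to FDR ≤ 0.10; matching
uses a 150-bp radius (config-exposed). The λ grid spans 10⁻⁶..10⁻¹ on the
spline's unit-scaled abscissa and τ defaults to pooled-profile quantiles
(20–70%); the grid deliberately brackets both under- and over-smoothing so
the FDR-capped selection, not the grid boundary, picks the operating point.
If no grid point meets the cap the lowest-FDR point is returned and flagged
rather than silently accepted.

## Promoter vs dTRE classification

The classifier follows a two-stage protocol: with the window size fixed at
50 bp the number of PRO-seq windows is chosen by 5-fold cross-validated AUC,
then the window size is re-tuned at the chosen genomic span; the single
CpG/GC window (GC fraction and CpG dinucleotide rate) is tuned the same way.
The final Gaussian-kernel SVM trains on the concatenated features with an
internal 10-fold cross-validation over (γ, C). Scores are signed margins
with promoter positive; the decision threshold sits at 0 and the score is
emitted so users can re-threshold. A dTRE-classified element overlapping an
annotated TSS (±1 bp) is relabeled `excluded_tss` — such regions are not
distal elements regardless of shape. Training labels come from synthetic
truth (or any user-supplied stable/unstable evidence); no transcript-
stability data ships with the package.

Repertoire comparison declares two elements shared at ≥50% single-sided
overlap (fraction of the first element; `reciprocal = TRUE` requires both),
with greedy best-overlap one-to-one matching so the shared/A-only/B-only
sets partition the union — a deliberate difference from interval tools that
report all overlapping pairs. The 1-nt overlap criterion used for factor-site
categorization is a different rule and the two are never conflated.

## Composite profiles and factor integration

Composite profiles average binned signal (20-bp bins by default; 10-bp for
heatmaps, 4-bp strand-paired for nucleotide-resolution footprints) over
anchors in their 5'→3' frames. The bootstrap resamples **anchors**, not
bases — the only reading under which the band is an interval "for the
group" — and reports the 12.5–87.5 percentile band, a nominal 75% interval
whose empirical coverage the acceptance suite verifies at 75% ± 5% over 500
simulations. Group scaling divides every profile of a factor by the single
highest mean bin across the groups, so the global maximum becomes 1 and all
ratios are preserved; the operation is idempotent.

Factor peaks are categorized promoter > dTRE > untranscribed with ≥1-nt
overlap; the promoter-first precedence for dual-overlap peaks is a choice
(promoters are the stricter annotation) and can be inverted. Binding scores
are mapped onto 107–1000 by an affine min–max transform — a documented
stand-in for browser-style score conventions whose exact transform is not
recoverable. Group statistics use Spearman's rank correlation (exact p for
n ≤ 20 without ties) and the two-sided Mann–Whitney U test.

## The synthetic genome

The generator emits the statistical structure the analysis assumes, with
full ground truth: divergent promoters (stable sense transcript, unstable
upstream antisense transcript 110–250 bp upstream — figure-level coupling
with no stated distance, so the range is configurable), pause peaks 20–60 bp
downstream of the TSS, uniform body signal, dTREs as two short unstable
divergent transcripts around separated strand summits, untranscribed control
sites, a DNaseI track that is a Gaussian-weighted sum (bandwidth 150 bp) of
initiation-proximal signal plus i.i.d. noise, first-order Markov sequences
with class-dependent GC/CpG, and factor peaks over a configurable mix of
categories.

Key modeling choices:

* **Wave fronts are hard.** A Down gene's body expectation drops to
  `fc_down ×` baseline from +500 to `min(elongation_rate × hs_duration,
  length)` while its pause grows by `hs_pause_gain` and tightens by
  `hs_pause_shift` bp; beyond the front the expectation is bit-identical to
  NHS. Up genes mirror this with `fc_up` below the front. No rate is stated
  for the underlying biology beyond "typical", so 2 kb/min is the default
  and the rate is a parameter.
* **Counts are independent per-base Gamma-Poisson draws with one shared
  dispersion parameter** (`nb_dispersion = 0.05`; 0 gives Poisson). The
  alternative — one latent Gamma factor shared across a whole element —
  would make reference-region sums fluctuate ~22% between replicates and no
  normalization estimator could recover an injected depth factor to within
  a few percent; the per-base law keeps long-range sums tight (CV < 1%)
  while still giving overdispersed counts at every base, and it is the same
  mean-variance law the differential model assumes.
* **Defaults are the study conditions**: 300 genes (12% Up, 40% Down, 10%
  untranscribed — a Down-dominated response), 4 genes forced longer than
  150 kb so normalization anchors always exist, 80 dTREs, 40 untranscribed
  sites on one 6-Mb chromosome, fold changes 3 and 0.3, body densities 5–80
  RPK, DNaseI noise sd 0.05. The fraction of dTREs responding with a pause
  profile change but no count change (`dtre_frac_paused`) defaults to 0:
  no quantitative claim about its prevalence is made, only the mechanism is
  modeled.
* Determinism: identical parameters and seed give byte-identical outputs,
  including written files; per-condition/replicate streams are derived from
  the master seed with a multiplicative congruential step.

What the generator does **not** emulate — and hence what green tests do not
show about real data: mappability gaps (everything is mappable, so RPK
lengths are plain lengths), multi-gene overlap and run-through transcription,
internal TSSs, sequence motifs (category labels stand in for motif
presence), non-uniform body profiles, and the heavy-tailed library artifacts
of real sequencing. Class composition differences for the classifier are
cleaner than reality (the synthetic GC gap is fully separable at 500-bp
windows), so classifier AUCs here are upper bounds, not forecasts.

## Problem sizes

The test suite exercises the full default simulation (300 genes, 6 Mb) for
the end-to-end checks and a 40-gene, 2-Mb configuration for module tests;
null calibration uses 5000 features, power runs 1000, oracle equivalence
1000 random genes and 120 elements, and bootstrap coverage 500 replicate
simulations at 40 anchors — sizes at which every check completes in a few
minutes on one core while keeping Monte-Carlo error well below the asserted
margins.

```{r example}
library(prowire)
params <- sim_params(seed = 1)
sim <- simulate_experiment(params)
genes <- filter_genes(sim$truth$genes)
quants <- quantify_genes(sim$tracks$NHS[[1]], genes, "NHS")
fit <- fit_scale_factors(
  list(NHS = sim$tracks$NHS[[1]], HS = sim$tracks$HS[[1]]),
  reference_regions(genes))
tidy(fit)
```
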