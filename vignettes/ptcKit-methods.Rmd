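---
title: "Methods and design notes for ptcKit"
author: "ptcKit authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for ptcKit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ptcKit)
```

# Scope

ptcKit covers three analysis arms around putative transcriptional
condensates (PTCs): (i) generative models of two-enhancer control of gene
expression with BIC-based family comparison; (ii) a DNA-FISH +
immunofluorescence (IF) image pipeline quantifying coactivator enrichment at
a labeled locus against a randomized in-nucleus null; (iii) genome-category
classification and enrichment statistics, plus PTC gene filtering and
timepoint-membership clustering. This vignette records the model
assumptions, parameter meanings and defaults, numerical choices, and the
design decisions taken where the problem was genuinely open.

# Two-enhancer expression models

## Model and error structure

Expression of the target gene over the four genotypes of a two-enhancer
excision design is modeled as `y = mu(x1, x2) + eps`, with `x1, x2 ∈ {0, 1}`
(1 = enhancer intact; the double knockout is the intercept baseline) and

* additive: `mu = b0 + b1 x1 + b2 x2`
* exponential: `mu = exp(b0 + b1 x1 + b2 x2)`
* logistic: `mu = g / (1 + exp(-(b0 + b1 x1 + b2 x2)))`, `g` the maximum
  expression level.

`eps` is Gaussian with constant variance. This is a deliberate choice: the
error term only needs to capture combined biological and technical replicate
noise on the WT-normalized scale, where variation is small (a few percent of
the WT mean) and approximately scale-free after batch normalization. Note
the exponential family places the noise *outside* the exponential — it is a
nonlinear Gaussian mean model, not a log-linear model, so nonpositive
measurements are admissible data. `sigma` is profiled by maximum likelihood
(`rss/n`, not `rss/(n-p)`) and is counted as a free parameter in the BIC for
every family: `n_params` is 4 for additive/exponential and 5 for logistic.

## Normalization

`normalizeToWT()` divides each observation by the mean of the wild-type
(x1 = x2 = 1) observations of its own batch. Because replicate noise in the
synthetic generator scales with the batch factor, this removes batch
structure exactly in law; on real RT-qPCR data it removes multiplicative
batch effects, which is the reason per-batch WT references are required
(a batch without a WT observation is an error, not a silent fallback).
Normalization is idempotent and leaves genotype labels untouched.

## Optimization

* additive: closed-form ordinary least squares (`lm`), no iteration.
* exponential: initialized from a log-linear regression on the genotype
  group means when all means are positive, otherwise from random starts
  only; refined by BFGS with a Nelder-Mead polish (relative objective
  tolerance 1e-12, well below the 1e-8 target accuracy).
* logistic: `g` kept positive via a log parameterization; initialized with
  `g = 1.05 × max(y)` and a logit-linear regression of group means clamped
  to (1e-3, 1-1e-3).

Both nonlinear families add 10 seeded Gaussian random restarts
(`N(0, 2)` per coordinate), so a fit is deterministic given data and seed
and multi-modality (a real risk for the logistic family when the response is
saturated) is handled by taking the best restart. On noiseless data the
residual SD is floored at 1e-9 to keep the Gaussian log-likelihood finite;
the floor is far below any measurable replicate noise.

## Model comparison and coefficient reporting

`selectEnhancerModels()` reports BIC differences against the additive
reference and returns the *set* of families within `threshold = 2` of the
minimum rather than forcing a single winner: BIC differences below 2 are
conventionally not decisive, and near-ties (additive vs logistic is a common
one at realistic sample sizes) are scientifically meaningful.
`coefficientSummary()` reports `b1`, `b2`, their ratio (potency comparison)
and sign-based role flags — a negative coefficient marks an enhancer that
dampens expression (antagonist). A zero `b2` yields an NA ratio with an
explicit `ratio_defined = FALSE` flag, not an error.

## What the tests show

Parameter recovery is assessed at the reference conditions used throughout:
6 replicates per genotype and `sigma = 0.05` (5% of the WT mean), 100 seeded
simulations per family; median relative error of `b1`, `b2` is well under
10%. The Day-1 worked example emulates a realistic Day-1 two-enhancer experimental design
(replicate counts 12/5/7/5, logistic truth with a 2.5× coefficient ratio);
it is a synthetic emulation — the original source measurements are not
shipped — so it demonstrates that the fitting machinery recovers a 2.5×
potency difference from data of that shape, not a reanalysis of the original
measurements.

# Image colocalization pipeline

## Pipeline steps and conventions

Channels are `H × W × Z` arrays in [0, 1] (`ChannelStack`). Coordinates are
(row, col) pixels; windows are 11×11 with the center at offset (6, 6) in
1-based indexing.

1. *Nucleus segmentation* per DAPI slice: Gaussian brush 31×31 with
   sigma 5 (a `k × k` truncated Gaussian kernel normalized to sum 1), Otsu
   threshold, hole filling. Otsu always splits an image, including pure
   noise, so a slice whose foreground/background contrast after smoothing is
   below `minContrast = 0.1` intensity units is treated as empty with a
   warning — without this guard a nucleus-free slice segments into one giant
   blob that falsely bridges all nuclei during 3D stitching.
2. *Spot detection* per FISH slice: brush 9×9 sigma 5, absolute threshold,
   connected components; any component with a pixel outside the nucleus mask
   is discarded. The default threshold (`defaultSpotThreshold()`) is
   mean + 6 SD of the smoothed FISH stack — a stringent heuristic standing
   in for a manually picked cutoff; it makes the pipeline invariant to joint
   rescaling of channel and threshold.
3. *Center refinement*: moment centroid, then shift to the brightest pixel
   of the (smoothed) FISH slice within the component; ties break to the
   lexicographically smallest (row, col), making centers deterministic.
4. *3D stitching*: per-slice objects are merged when their 2D footprints on
   adjacent slices overlap by ≥ 1 pixel (union-find). The criterion is the
   loosest sensible one; at typical spot densities footprint overlap between
   distinct spots on adjacent slices is not observed in the fixtures.
   Nuclei without spots are dropped before the null is built.
5. *Random-center null*: 50 voxels per spot-bearing nucleus, uniform with
   replacement from the nucleus's 3D voxel set (replacement because small
   nuclei may hold fewer voxels than requested centers), seeded and
   bit-reproducible.
6. *Windows and aggregation*: 11×11 IF windows per spot per slice; entries
   outside the image or outside that spot's nucleus volume are zeroed and
   flagged invalid. Per spot, slices are averaged over valid entries only;
   per position, the median across spots (and across random centers) gives
   the two maps and their ratio. A position with no valid observation is NA,
   never silently 0.
7. *Binned profile*: paired (FISH, marker) pixels pooled from all valid
   window entries, FISH binned into 20 quantile bins (5% percentiles),
   median marker per bin. Association is the Spearman correlation of the
   (bin index, bin median) pairs; its significance is a permutation p-value
   (marker values shuffled against FISH, default 10⁴ permutations in the
   standalone function; the orchestrator default is 2000). The choice of
   Spearman-on-bin-medians with a permutation null is this package's
   decision — the upstream experimental analyses report a correlation
   without naming the test.

Nuclei touching the image border are kept; window entries falling outside
the image are handled by the validity flags.

## Fixture sizes

Tests and the acceptance script use 160-320 px stacks with 6-8 z-slices and
3-20 nuclei. These sizes keep exact brute-force oracles (window validity by
double loop, per-voxel uniformity checks) cheap while exercising every code
path, and a full pipeline run takes seconds. The pipeline itself is
resolution-agnostic: nothing in the code assumes a stack edge length.

# Genome-category statistics

* `classifySegment()` implements the four-way rule on
  (p, log2FC, hub): PTC (p ≤ 0.05, log2FC ≥ 0, hub), very active (same, no
  hub), moderately active (p > 0.05, log2FC ≥ 0), inactive (p > 0.05,
  log2FC < 0). The remaining cell — significant depletion, p ≤ 0.05 with
  log2FC < 0 — is not covered by the four rules and is flagged
  `unclassified_depleted` explicitly rather than binned.
* `tfTargetEnrichment()`: expected targets in a category =
  (TF's share of the gene universe) × (category size); score =
  observed/expected. Scores weighted by category gene counts average to 1
  exactly per TF (conservation), which the tests assert as an identity.
* `tissueSpecificityScore()`: within-tissue expression ranks (higher
  expression = higher rank; replicate datasets of a tissue averaged first);
  the score is the fraction of *non-focal* tissues with a strictly lower
  rank. Excluding the focal tissue from the denominator makes the score
  attain 0 and 1 exactly at the extremes; ties count as not-lower. A
  consequence recorded here: reversing all rankings maps s to 1 − s only for
  genes without cross-tissue rank ties.
* `shuffleIntervals()`: length-preserving, genome-wide (chromosome drawn
  with probability proportional to its length among chromosomes long enough
  to host the interval; start uniform), intervals may overlap each other; no
  gap or blacklist exclusion. Two consequences worth knowing: a multi-
  chromosome genome fully covered by intervals is *not* invariant under this
  shuffle (intervals can stack on one chromosome), and interval self-overlap
  makes the expected shuffled SNP overlap
  `nSnps × (1 − Π(1 − len_i/L))` rather than `nSnps × coverage`.
* `snpOverlapEnrichment()`: observed = SNPs (0-based positions,
  `start ≤ pos < end`) in ≥ 1 interval, each counted once; enrichment =
  observed / mean(permuted overlap) over `nPerm = 100` shuffles. Zero SNPs
  give enrichment 0; a positive observed count with zero mean permuted
  overlap is flagged undefined.
* `moduleOverlapTest()`: upper-tail hypergeometric via `phyper`.
* Intervals are 0-based half-open throughout (BED dialect on disk);
  `GenomicRanges` is the in-memory container.

# PTC genes

`filterPtcGenes()` keeps protein-coding genes with mean TPM strictly > 1
across the three timepoints, at least one H3K27ac peak in the *closed*
window ±1000 bp around the TSS point (the promoter anchor; anchoring on the
TSS rather than an annotated promoter interval is the package's choice), and
PTC membership at ≥ 1 timepoint. Membership is any-overlap of the gene body
with a PTC segment (`ptcMembership()`), symmetric with the peak rule. The
seven-way clustering maps the (Day 0, Day 1, Day 7) membership flags; genes
with no membership are an error, so the clusters partition the
membership-positive universe by construction. `relativeExpressionToDay0()`
excludes genes with any variance-stabilized count below the floor
(default 1, configurable — "very low" counts make the Day-0 ratio
unstable) and anchors Day 0 at exactly 1.

# Synthetic generators: what they emulate, and what not

* *Expression*: replicate values `mu(x1,x2) × batchScale + N(0, sigma ×
  batchScale)`. Defaults (6 replicates/genotype, sigma = 0.05, WT mean 1)
  are the reference conditions for all recovery claims. The generator does
  not emulate heteroskedasticity across genotypes, outliers, or Day-0
  baseline differences between clones.
* *Images*: ellipsoidal nuclei (in-plane circles shrinking with z; the
  default z-half-extent 0.75 Z keeps nuclear signal in every slice, as in
  stacks focused within nuclei), compact Gaussian FISH spots spanning 2-4
  slices placed on an evenly rotated ring inside each nucleus (minimum
  sibling separation 16 px so planted spots remain resolvable after
  smoothing — merged fixtures would make recall unmeasurable), and an IF
  channel of uniform background plus optional Gaussian bumps at spot
  centers; additive Gaussian noise clipped to [0, 1]. Not emulated: optical
  PSF anisotropy in z, chromatic aberration, autofluorescence gradients,
  nucleoli or chromatin texture, touching nuclei. Passing tests therefore
  show algorithmic correctness on clean geometry, not robustness to every
  imaging artifact.
* *Genome*: three 10-Mb chromosomes tiled into 200 segments by default;
  category mixing defaults to realistic genome fractions (5.5 / 2.5 / 17.8
  / 74.2%). SNP planting: each SNP falls in the target category with
  probability `ratio × coverage`, so the planted ground-truth enrichment
  equals `ratio` exactly (an exact inside/outside density ratio of r would
  instead yield `r/(rc+1−c)`). TF bias is a sampling-weight multiplier;
  tissue matrices are Gaussian with an additive focal-tissue shift. No
  sequence content, LD structure, or gap/blacklist regions are emulated.

All generators are deterministic given (config, seed); ground-truth tables
are returned alongside the data so downstream stages can be scored without
re-deriving geometry.

# Known limitations

* The expression models are fixed to the two-enhancer design; the framework
  generalizes to more enhancers but this implementation does not.
* Only maximum likelihood + BIC is provided; no Bayesian posterior.
* The logistic family can be weakly identified when all genotypes are far
  from saturation; the seeded restarts make the reported optimum
  reproducible but cannot manufacture identifiability.
* The image pipeline assumes one FISH color and does not deconvolve,
  correct aberration, or track nuclei across time.
* The shuffle-based SNP enrichment is a plain uniform permutation; no
  GC/length-matched or LD-aware schemes.
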