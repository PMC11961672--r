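# ptcKit

Analysis toolkit for **putative transcriptional condensates (PTCs)** — 3D hubs
of enhancer-enriched genome segments — and for the enhancer pairs they
contain, built around three questions that arise when dissecting a
multi-enhancer locus during a cell-fate conversion:

1. **How do two enhancers combine to set a gene's expression?** Replicate
   expression measurements from the four CRISPR genotypes of a two-enhancer
   design (WT, two single knockouts, double knockout) are normalized to the
   wild-type mean of their experimental batch and fitted with three
   generative models of the mean `mu(x1, x2)`, with `x1, x2 ∈ {0, 1}` coding
   each enhancer intact (1) or excised (0):

   | family | mean function | interpretation |
   |---|---|---|
   | additive | `b0 + b1·x1 + b2·x2` | independent, linear enhancer action |
   | exponential | `exp(b0 + b1·x1 + b2·x2)` | multiplicative / synergistic |
   | logistic | `g / (1 + exp(−(b0 + b1·x1 + b2·x2)))` | two-state saturation; `g` = maximum expression |

   Noise is Gaussian with constant variance (`sigma` profiled by maximum
   likelihood and counted as a free parameter). Families are compared by
   `BIC = k·ln(n) − 2·ln(L)`; every family within 2 BIC units of the minimum
   is reported as jointly valid. Enhancer coefficients `b1, b2` measure
   per-enhancer potency; a negative coefficient marks an antagonist.

2. **Is a coactivator (e.g. BRD4) enriched at a locus in situ?** A DNA-FISH +
   immunofluorescence confocal z-stack pipeline: per-slice nucleus
   segmentation (Gaussian smooth 31/5, Otsu, fill holes), FISH spot detection
   (smooth 9/5, fixed threshold, spots fully inside nuclei), brightest-pixel
   center refinement, 3D stitching by adjacent-slice footprint overlap, a
   null built from 50 random in-nucleus centers per nucleus, 11×11 marker
   intensity windows with validity flags, positionwise median maps and their
   spot/background ratio, and a 5%-percentile-binned marker-vs-FISH intensity
   profile with a permutation-tested Spearman correlation.

3. **What distinguishes PTC segments genome-wide?** A four-way segment
   classification (PTC / very active / moderately active / inactive from the
   enhancer-enrichment p-value, log2FC and 3D-hub flag), TF-target enrichment
   scores (`observed / expected` targets per genome category),
   tissue-specificity rank scores in [0, 1], permutation SNP-overlap
   enrichment against length-preserving genome-wide interval shuffles, a
   hypergeometric gene-module overlap test, and PTC gene filtering plus the
   seven-way timepoint-membership clustering (Invariant, Early,
   Early-Intermediate, Intermediate, Intermediate-Late, Late, Early-Late).

Seeded synthetic-data generators (`simulateExpressionData`,
`simulateImageStack`, `simulateGenomeFixture`) produce inputs with known
ground truth for every stage, so the whole package is testable offline.

## Worked example

Simulate a Day-1-like two-enhancer dataset (logistic truth in which enhancer
1 is 2.5× stronger than enhancer 2; replicate counts 12/5/7/5), normalize to
the WT batch mean, fit and compare all three families:

```r
library(ptcKit)
raw <- simulateExpressionData("logistic",
         c(b0 = -2, b1 = 3, b2 = 1.2, g = 1.05), sigma = 0.05,
         repsPerGenotype = c("11" = 12, "01" = 5, "10" = 7, "00" = 5),
         seed = 1)
d   <- normalizeToWT(raw)
sel <- compareEnhancerModels(d, seed = 1)
sel
#> EnhancerModelSet of 3 fits
#>   additive     BIC =  -81.096   dBIC(vs additive) =   +0.000  *
#>   exponential  BIC =  -59.099   dBIC(vs additive) =  +21.997
#>   logistic     BIC =  -78.362   dBIC(vs additive) =   +2.734
#>   best set (threshold 2): additive
coefficientSummary(sel)
#>         model        b1        b2    ratio ratio_defined     role1     role2
#> 1    additive 0.6699057 0.2100848 3.188739          TRUE activator activator
#> 2 exponential 1.3181252 0.2534669 5.200385          TRUE activator activator
#> 3    logistic 3.1522286 1.3653800 2.308682          TRUE activator activator
```

The additive fit wins on BIC here (the logistic family pays for its extra
parameter at this sample size), and the fitted logistic coefficient ratio
`b1/b2 ≈ 2.3` recovers the planted 2.5× potency difference; both families
flag both enhancers as activators. On the imaging side:

```r
sim <- simulateImageStack(dims = c(256L, 256L, 8L), nNuclei = 8,
                          colocAmplitude = 0.15, background = 0.15, seed = 3)
res <- runColocalization(sim$stack, seed = 4)
centralEnrichment(res$enrichment)   # ~1.7: marker enriched at the locus
res$profile$rho                     # ~0.99: marker tracks FISH intensity
```

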