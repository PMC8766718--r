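---
title: "Modelling and calling chromatin interactions with hicstress"
author: "hicstress authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and calling chromatin interactions with hicstress}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hicstress)
```

## The analysis problem

Hi-C libraries record pairs of sequencing reads whose mates mark genomic
loci that were close in the three-dimensional nucleus.  Turning those read
pairs into a catalogue of chromatin interactions — and comparing catalogues
between growth conditions — requires four modelling steps, each implemented
here as a separate stage:

1. **Read-pair QC.**  Proximity ligation produces several artifact classes
   that carry no spatial information: self-ligation/dangling-end products
   (both mates in one restriction fragment), re-ligation products (mates in
   adjacent fragments), undigested continuous genomic fragments
   (close, inward-facing mates), and reads whose 3' ends are not anchored
   at a restriction site.  `filter_pairs()` removes them in that fixed
   precedence, so the QC report is a partition of the input.
2. **Expected-count model.**  The expected read count between bins `i` and
   `j` is `e_ij = f(i - j) * n*_i * n*_j / N*`, where `f` is the
   distance-decay profile, `n*_i` an inferred per-bin read total absorbing
   coverage and accessibility bias, and `N*` the library total.
   `contact_model()` fits this model and behaves like any R model object
   (`coef()`, `fitted()`, `residuals()`, `predict()`, `plot()`,
   `simulate()`).
3. **Interaction calling.**  For each locus pair the observed count is
   compared with the model expectation through the upper-tail cumulative
   binomial: `p = P(X >= observed)` with `X ~ Binomial(N*, e_ij / N*)`.
   Pairs at or below the cutoff (default 0.05, no multiple-testing
   correction, mirroring standard HOMER-style calling) become interaction
   records, classed cis or trans.
4. **Downstream statistics.**  Cross-condition overlap and exclusivity,
   expression fold-change classes of interacting genes, epigenetic-state
   (ES) preference against randomized control interactions, GWAS-SNP
   depletion in the interacting genome, and motif-region sequence export.

## The synthetic-data generator

Every stage is testable offline because the `make_*`/`simulate_pairs()`
generators produce all inputs with known ground truth: a multi-chromosome
genome with exponentially spaced restriction sites, read pairs drawn from a
power-law contact model with per-bin biases and planted enriched pairs,
contaminating ligation artifacts, an ES segment track, SNPs with planted
depletion, and lognormal FPKM tables with a treated effect subset.

Default study conditions (chosen once, desk-scale yet structurally rich):
3 chromosomes of 2 Mb; mean restriction-fragment size 4 kb (the order of a
6-cutter in a plant genome); truth resolution 10 kb (600 bins, so a 200-bin
chromosome still resolves >100 distance strata); cis decay `d^(-1)` floored
at 1 kb; trans floor 5% of the 100 kb cis level; lognormal per-bin biases
with sdlog 0.3; lognormal FPKM baselines around 20 with sdlog 0.8 and
measurement noise sdlog 0.25 (so a 4-fold planted effect is comfortably
above noise yet pseudocount shrinkage stays visible).  One seeded RNG
stream per generator call makes every output byte-reproducible.

Three generator choices deserve explanation:

* **Mates sit next to restriction sites.**  Real informative Hi-C reads
  terminate at a ligation junction, i.e. at a restriction site; reads
  without a nearby downstream site are discarded by QC.  The generator
  therefore samples each informative mate uniformly over the
  site-adjacent placement windows *inside* its bin.  Sampling inside the
  bin (rather than snapping a uniform position into the nearest window)
  keeps bin-level counts exactly equal to the sampled bin pairs, which is
  what makes planted-bias recovery a clean test.
* **Informative contacts connect distinct bins.**  Sub-resolution
  (within-bin) products are dominated by ligation artifacts in a real
  library and are excluded by the caller's minimum-distance rule anyway,
  so the generator assigns them zero weight and routes all sub-resolution
  products through `contaminant_fraction`.  The rare informative pair that
  still lands in the same or adjacent fragments is re-placed within its
  bins, keeping the truth labels exact for the QC agreement test.
* **What the generator does not emulate.**  No pericentromere geometry, no
  chromosome-length heterogeneity, no distance-dependent artifact mix, no
  replicate structure, no read sequences.  Passing tests therefore show
  that the algorithms recover the stated generating parameters — not that
  the pipeline reproduces any particular real library.

## Numerical choices

* **Decay estimation.**  `f` is the mean observed count per cis bin pair
  at each bin distance, pooled over chromosomes.  Distances are pooled
  into log-spaced strata until each stratum carries at least 50 reads,
  then smoothed non-increasing by weighted pool-adjacent-violators.  The
  diagonal stratum (d = 0) is summarized separately and exempt from the
  monotone constraint: within-bin products are a different ligation class,
  and forcing `f(0) >= f(1)` onto a library whose within-bin products were
  removed upstream would park a large expected mass on an empty diagonal
  and deflate every cis expectation (in our measurements this inflated the
  caller's type-I rate above its nominal level; with the free diagonal the
  observed type-I rate is below alpha, as the discreteness of counts
  implies it should be).  On data with a dominant diagonal the two rules
  coincide.
* **Bin totals.**  `n*` is fitted by damped multiplicative hill climbing,
  `n*_i <- n*_i * (observed marginal_i / expected marginal_i)^0.5`,
  with the trans floor refreshed at every iteration so trans mass stays balanced.
  The damping exponent 0.5 is the standard stabilization for symmetric
  matrix scaling (the undamped update can oscillate); the objective — the
  squared marginal mismatch — is asserted to descend and the fit aborts
  with diagnostics after five consecutive increases.  Marginals count read
  *ends* (a within-bin pair contributes twice), which makes global
  conservation (total expected = total observed) an exact consequence of
  marginal matching.  Convergence: maximum relative change of any `n*`
  below 1e-4, or 200 iterations.
* **Masking.**  Bins whose observed marginal is below 20% of the median
  marginal are masked and excluded from all statistics.
* **Correlation matrices.**  Pearson correlation between rows of
  `log2(obs/exp)`, excluding each pair's own two columns — the standard
  compartment-analysis practice; zero ratios become missing values rather
  than infinities.
* **Caller defaults.**  Resolution 1 kb, cutoff 0.05 on the raw p-value,
  minimum 5 observed reads per tested pair, minimum cis separation of two
  bins (adjacent-bin products are QC shadows).  A Benjamini–Hochberg
  option exists but is off by default.  On the 6 Mb toy genome the
  examples and tests call at 10 kb, which preserves the ~1:200 ratio of
  calling resolution to genome size that 1 kb has on a full plant genome.
* **Randomized controls.**  Control interactions preserve record count,
  anchor lengths and the cis/trans split, and resample cis distances from
  the observed distribution.  GWAS control intervals are drawn from the
  complement of the interacting union with matched piece lengths and no
  overlap with it.  The ES permutation p-value is `(1 + #{null >=
  observed}) / (K + 1)` (K = 1000 by default), reported alongside a
  normal-approximation p for reference, since a permutation bound cannot
  go below `1/(K+1)`.

## Open design points and how they were resolved

* The QC insert window (the "fragment length estimated from the 3' end")
  defaults to 500 bp, the typical Hi-C size-selection scale; it is a
  parameter of both the filter and the generator.
* PCR-duplicate removal is on by default (flag-switchable) and counted as
  its own QC category so the report remains a partition.
* Interaction overlap across conditions uses >= 1 bp anchor overlap in
  either anchor orientation; because match multiplicity makes counts
  reference-dependent, `overlap_counts()` reports every choice of
  reference.
* Same-state preference compares primary states (maximal-overlap state,
  ties to the lower state number); an `any`-shared-state mode is
  available.
* Expression classes use |log2FC| >= 1 with a pseudocount of 1 FPKM.

## Problem sizes used by the test-suite and acceptance script

Parameter-recovery checks run on 1e6 read pairs at 10 kb resolution
(decay slope within 0.15 of the generating exponent; bias recovery
Pearson r >= 0.9; caller type-I at or below alpha plus two binomial
standard errors over ~1.8e5 tested pairs; 20 planted 10-fold pairs with
>= 90% recovery).  The ES null runs 60–200 control replicates over 300
long-range records; the GWAS check uses 20,000 SNPs with a planted 0.5
depletion.  Unit tests use 2e4–5e5 pairs.  These sizes were chosen so each
statistical tolerance is several standard errors wide under the
generating model.

## Known limitations

* The hill-climbing stand-in is validated by parameter recovery, not by
  bit-compatibility with any external implementation of the same model.
* Dense matrices cap the practical bin count at a few thousand; calling a
  125 Mb genome at 1 kb would need a sparse path.
* The caller tests each unordered pair once and ignores strand throughout,
  as the underlying statistics are strand-free.
* Counts printed by published studies depend on their exact read depth and
  software versions; this package reproduces the *procedures* and verifies
  them on synthetic ground truth instead.
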