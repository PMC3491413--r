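---
title: "Methods: H2A.Z chromatin landscapes and modification stoichiometry"
author: "zedscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: H2A.Z chromatin landscapes and modification stoichiometry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(zedscape)
```

This vignette is the package's account of its models, the parameters
that matter, the design choices that were genuinely open, and what the
synthetic tests do and do not establish about real data.

## The genomics arm

### Counting model

Single-end ChIP-Seq reads are extended to the sonication fragment
length (`fragmentLength`, default 200 bp) from their 5' end in the
strand direction, and each fragment is reduced to its midpoint
(`assignFragments()`). Counting midpoints rather than overlapping whole
fragments means a read contributes to exactly one window of a tiling,
so window counts are sums of independent indicators and the Poisson
null below is exact under uniformity. Midpoints falling past a
chromosome end are clipped to the last base.

Enrichment is assessed in sliding windows (`scanWindows()`):
`windowSize` 1000 bp, `step` 200 bp. The 1-kb window is the analysis
unit; the 200-bp step was an open choice (any "sliding" step is
admissible) and was set equal to the profile bin width so that window
starts and profile bins share a grid. `windowSize` must be a multiple
of `step`.

### Null models and calling

`nullRate()` offers two exchangeable nulls:

* **poisson** (default): the count in a `w`-bp window is Poisson with
  `lambda = n * w / G`, where `n` is the number of midpoints and `G`
  the summed chromosome lengths. Tail probabilities are exact
  (`ppois`). Mappability is deliberately ignored: `G` is the full
  layout length.
* **empirical**: the `n` points are re-placed uniformly
  `nRandomizations` times (default 10) and counts in non-overlapping
  `w`-bp tiles are pooled; the tail is
  `(1 + #null >= k) / (1 + #null)`, which is never zero and has
  resolution `1/(1 + #null)`. This is the direct finite-sample
  randomised-read background; the Poisson model is its large-pool
  limit, and the test suite checks the two agree within a factor of
  two wherever the Poisson tail is at least 1e-3.

Windows with tail probability strictly below `alpha` (default 1e-4)
are retained. No multiple-testing correction is applied on top of the
fixed per-window threshold: fidelity to the established procedure was
preferred over improvement, and `alpha` is exposed for users who want
an FDR-calibrated value instead. Retained windows are merged
(`callEnriched()`) whenever the end-to-start distance between two of
them is strictly less than `mergeGap` (default 2000 bp); overlapping
and abutting windows always merge. Merging is idempotent and invariant
to input order, and is checked against a brute-force oracle over 1,000
randomized window sets.

Duplicate reads are retained: the generator has no PCR duplicates, and
deduplication of real libraries belongs upstream. Reads on
chromosomes absent from the genome layout are an error rather than a
silent drop, to surface annotation/genome mismatches.

### Promoter states and intergenic elements

Promoters are strand-aware windows `[tss - 500, tss + 2000)` around
every annotated TSS (`promoterRegions()`; `up`/`down` configurable),
clipped at chromosome bounds. Genes with several annotated TSSs simply
contribute several promoter records, and neighbouring promoters are
not deduplicated. A promoter is positive for a mark iff it overlaps at
least `minOverlap` bp (default 1, the simplest defensible rule —
exposed as a parameter) of a *merged* interval of that mark; whether
the original analysis intersected merged intervals or raw significant
windows is unknowable from the text, and merged intervals were chosen
as the published object. The state is then a pure function of the two
flags. `intergenicElements()` keeps intervals whose distance to every
promoter and gene body is at least `exclusion` (default 4000 bp), with
any overlap counting as distance zero.

### Profiles

`profileMatrix()` counts midpoints in `bin`-wide tiles spanning
±`span` around each anchor (defaults 200 bp and 5000 bp → 50 columns),
scales to reads per million, and flips minus-strand rows so columns
run 5' to 3'. Bins are non-overlapping tiles: that is what a heatmap
column set requires, and a sliding variant adds nothing to the
composite means. Bins extending beyond a chromosome are `NA` and are
ignored by `composite()`, which averages a row subset. Between-sample
normalisation is reads-per-million only; raw counts are kept alongside
so any other scaling can be applied downstream.

Expression-quartile composites use ±2.5 kb. Because 2500 is not a
multiple of 200, the pipeline's quartile composites default to 100-bp
bins (`quartileBin`), keeping the span exact. Quartiles rank genes by
expression with ties broken by input order (a stable rule), producing
group sizes that differ by at most one; quartile 1 is the lowest.

### A note on resolving the TSS dip

The generator places H2A.Z as two summits at `tss ± flankOffset`
(default 150 bp) — the nucleosomes flanking the nucleosome-free region
— with Gaussian midpoint spread `summitSd` (default 50 bp,
nucleosome-scale positioning jitter; an open choice). With 200-bp bins
anchored at −span, the TSS falls on a bin edge and both summits land
in the two TSS-adjacent bins, so the inter-summit dip (width ≈ 2 ×
150 bp) is narrower than one bin and invisible at that resolution.
Profile checks of bimodality therefore use 100-bp bins, where the two
maxima and the central minimum separate cleanly. This is a resolution
statement, not a model change: the same matrix at 200-bp bins is still
the heatmap object.

### Overlaps and MTL occupancy

`overlapFraction()` counts intervals, not base pairs: an interval is
"overlapping" if it touches at least `minOverlap` bp of any partner,
and counts once regardless of how many partners it touches. MTL
occupancy extends raw loci by ±2 kb, applies the same 4-kb intergenic
rule as `intergenicElements()`, and reports the fraction of surviving
loci touched by H2A.Z intervals; an empty intergenic subset raises an
explicit error instead of a silent NaN.

## The synthetic-data generator

`simChromatinConfig()` defines the study conditions: one 10-Mb
chromosome, 200 genes at least 20 kb apart (evenly spaced with ±2 kb
jitter, bodies 5–12 kb), chromatin-state probabilities
(K4-only 0.45, bivalent 0.25, K27-only 0.10, no-mark 0.20 — a
realistic stem-cell-like mix; neither the state proportions nor any
benchmark depends on the exact values), background midpoint density
0.005 reads/bp and enrichment fold 5. H3K4me3 and H3K27me3 are planted
as 2-kb promoter blocks over genes whose state carries the mark;
H2A.Z as the two TSS-flanking summits plus `nIntergenicSites` distal
1-kb sites placed at centres of wide intergenic gaps. Total planted
midpoint density is `enrichmentFold x backgroundRate`, i.e. added
reads at `(fold - 1) x background`. Expression for K4-only genes is
log-normal by quantile assignment (guaranteeing the multi-order
dynamic range) with the random permutation seeded; other states sit
near zero, below the positive floor of 1. With `depletionMax > 0`,
planted H2A.Z reads are thinned in proportion to the gene's expression
percentile, emulating elongation-coupled eviction at highly
transcribed genes. `backgroundExcludesPromoters = TRUE` produces
noiseless chromatin-state labels for classification-fidelity tests.
All generators run in a private RNG stream derived from the config
seed and restore the caller's RNG state; the same config always yields
the same genes, labels and reads.

The MS generator (`simMSConfig()`, `simulateXic()`,
`simulateCompositeSpectrum()`) emits Gaussian elution peaks with areas
proportional to isomer weights times the total ion current, and
per-site acetyl/propionyl b-ion currents equal to the weight-implied
fractions, with optional multiplicative Gaussian noise (clamped at
zero).

What the generator does **not** emulate: sequence content,
mappability and GC bias, paired-end reads, PCR duplicates, input
chromatin structure, antibody efficiency differences between marks,
isotope envelopes, co-eluting interferences, or retention-time drift.
Passing tests therefore establish the correctness of the computations
under the stated statistical model, not robustness to these real-data
artefacts; the empirical null and the `--dedup`-style preprocessing
expected upstream are the usual mitigations.

## The MS quantification arm

`integratePeak()` uses trapezoidal integration. Automatic bounds are
valley-to-valley around the global maximum, a valley being the first
local minimum below 5 % of peak height (`valleyFraction`) or the trace
edge — a robust rule for well-resolved isomer peaks; explicit bounds
override it. An all-zero trace integrates to 0 with a warning, and
fraction computations error when all areas vanish.

`diacetylDeconvolution()` fits the mixture model: observed per-site
acetyl-current fractions `f_k` are modelled as `sum of w_p over pairs
containing k` with pair weights on the probability simplex. The
estimator is least squares under the simplex constraint, solved by
projected gradient descent (Euclidean simplex projection, fixed step
`1/L` with `L` the largest eigenvalue of `2 A'A`, up to 20,000
iterations, convergence when the largest weight update falls below
1e-14). The objective is convex, so the fit is checked in the test
suite against an exhaustive simplex-grid oracle (step 0.1 over all ten
pairs, 92,378 candidates) at a 1e-6 objective tolerance. With five
sites and ten pairs the weights are generally not identifiable from
five marginals; the per-site marginals are the primary, identifiable
output (summing to 2 for a diacetyl precursor; `perAcetyl` halves
them), and `nonUnique` flags solutions whose support exceeds the rank
of the design. Whether monoacetyl b-ion proxies should be renormalised
to sum to one acetyl is not decidable from the published description,
so both the raw proxies and the renormalised occupancies are returned.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` run the genomics arm on a
10-Mb genome with 100–200 genes (about 50,000 reads per mark at the
default background) and the MS arm on 100-seed noise sweeps — sizes
chosen so the full suite completes in a few minutes on one CPU while
keeping per-window expected counts (λ ≈ 5–10) in the regime where the
1e-4 threshold is a meaningful tail event. Every stochastic step takes
an explicit seed; `runAll()` writes byte-identical summaries for
identical configs.

## Known limitations

* No input-chromatin correction or locally estimated background; broad
  domains in repetitive or unmappable regions of real genomes will
  violate the uniform null.
* Per-window thresholding without FDR control: at 1e-4 over ~50,000
  windows a handful of false windows per genome scan is expected, and
  merged false intervals appear at that rate.
* The interval overlap statistics carry no significance model (none is
  defined in the procedure they reproduce).
* The MS arm begins at extracted chromatograms and composite spectra;
  identification, isotope deconvolution and retention-time alignment
  are upstream concerns.
* Replicates are not modelled; marks are processed one library at a
  time.
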