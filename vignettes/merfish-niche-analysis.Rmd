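---
title: "Methods: MERFISH spatial niche analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: MERFISH spatial niche analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(merfishniche)
```

This vignette documents the models, parameter choices and numerical
conventions behind `merfishniche`, and what the synthetic-scene validation
does and does not establish about real imaging data.

## The barcode code

MERFISH reads each RNA species as a 16-bit binary barcode over 16
hybridisation/imaging rounds. The package constructs the extended Hamming
code of length 16 — the classical [15,11] Hamming code plus an overall
parity bit — which has minimum pairwise distance 4, and uses its
Hamming-weight-4 subset as the barcode set. Weight-4 words balance signal
density (four "on" rounds per molecule) against optical crowding, and the
distance-4 property makes any single-bit readout error uniquely
correctable. The construction yields exactly 140 weight-4 codewords;
`build_mhd4_codebook()` assigns them to genes by a seeded permutation, and a
published gene-to-barcode table can be loaded from JSON instead
(`read_codebook()`). Decoding with `max_errors = 2` is refused outright: at
distance 4, two errors can be equidistant from two codewords.

## Synthetic tissue scenes

Raw multi-round image stacks for fetal liver are not publicly deposited, so
validation rests on a generative model with known ground truth
(`simulate_scene()`). Its components, and the realism trade-offs:

* **Positions.** Poisson-disk (dart-throwing) sampling with a minimum
  centre separation, default 8 µm, emulating closely packed parenchyma.
* **Territories.** Each cell occupies the Voronoi cell of its centre; the
  membrane channel is a ~2 px bright ridge along territory boundaries plus
  Gaussian noise. Real membranes are irregular; Voronoi territories are the
  simplest model consistent with confluent tissue and give the watershed a
  realistic topology (ridges enclosing basins) without modelling optics.
* **Types.** Labels start as independent draws from the configured
  abundances and are resampled by a finite-temperature Potts-style Gibbs
  sampler (default 20 sweeps) on the 20-µm neighbourhood graph, with
  `P(type t) ∝ fraction_t · exp(Σ_neighbours affinity[t, type_j])`. A zero
  affinity matrix leaves the independent null intact, which is what the
  false-discovery-rate simulations rely on. The default abundances are
  fetal-liver-like (erythroid-dominated, endothelium ≈ 5%, HSCs 0.2%).
* **Counts.** Negative binomial per type and gene
  (variance = µ + µ²/dispersion, default dispersion 10; `Inf` gives
  Poisson). The default mean matrix places each type's markers at 15
  expected molecules, background genes at 6, and off-type markers at 0.3.
* **Images.** Every molecule contributes a unit-height Gaussian spot
  (σ = 1 px) to the four bit images where its barcode is 1, each
  independently dropped with probability `spot_dropout_rate` (default
  0.05); spurious spots arise per pixel at `spot_false_positive_rate`.
  Rounds are translated by cumulative integer drift, and a fiducial-bead
  channel is rendered with identical drift. The pixel size defaults to
  107.9 nm. Not modelled: point-spread-function asymmetry, photobleaching,
  chromatic aberration, z-extent. Passing recovery tests on these scenes
  therefore demonstrates the correctness of the decoding/segmentation
  logic, not robustness to every optical artefact of a real microscope.

## Imaging pipeline conventions

Coordinates are 0-based pixels with (x, y) = (column, row) and
µm = pixel × pixel_size / 1000; all modules share this frame.

**Drift** is estimated to integer-pixel precision as the argmax of the FFT
cross-correlation of bead images against round 1; blank bead images are an
error. **Decoding** normalises each bit image by its own
`threshold_quantile` (default 0.999) and binarises there; a quantile adapts
to per-round brightness differences and, because decoded pixels are sparse,
an image whose quantile is zero falls back to "any positive pixel". Only
pixels whose bit-weight is within one of 4 can decode, which keeps the
distance computation small. Same-gene pixels merge by 4-connected
components (conservative: diagonal blobs stay separate), one molecule per
component at its centroid; single-pixel components are kept.

**Segmentation** inverts the membrane image so interiors become basins,
pre-smooths with a Gaussian (σ = 2 px) so shot noise does not seed spurious
basins, and runs a tolerance-based watershed (EBImage, tolerance 0.1).
Pixels where two regions meet are set to background, leaving a ~1 px
boundary line; a constant image yields one label. Area filtering removes
regions below 2,500 or above 20,000 px with *strict* inequalities — a region
of exactly 2,500 px survives — and edge-touching regions are removed
entirely. Because boundary lines are background, two adjacent cells are
separated by ≥ 1 px; the direct-contact analysis therefore exposes its
dilation radius, and the pipeline uses 2 px where the strict 1 px default
of `contact_fraction()` would miss boundary-sharing watershed cells.

## Quantification and typing

Gene QC computes one dataset-level Pearson correlation between
log10(count + 1) and log10(FPKM + 1) (the log transform is a switch) and
gates the dataset at r > 0.7; a configurable exclusion list handles species
known to disagree with bulk data. Cells with fewer than 10 molecules are
dropped (exactly 10 survives), then counts are scaled to
molecules-per-thousand within each cell, making rows comparable
compositions.

Clustering builds a k-nearest-neighbour graph (k = 15 by default; smaller
for scenes with under ~300 cells so that rare types keep enough neighbours),
reweights edges by the Jaccard overlap of neighbour sets, and applies
Louvain under a fixed seed. As with any modularity method on a
shared-nearest-neighbour graph, the default resolution of 1 can split one
homogeneous population into several communities; the splits stay within
populations (marker-based typing then labels the fragments identically),
and a lower resolution (~0.1) merges them when a one-community-per-
population partition is wanted. Typing operates at cluster level: each type is
scored by the mean over its markers of cluster-mean expression relative to
the population mean — the ratio form stops highly expressed markers from
dominating — and the top type must beat the runner-up by a relative margin
(default 5%) or the cluster is "Unknown". Expression enrichment profiles
are log2 of type mean over population mean with a 10⁻⁶ pseudocount.

HSCs are called on **raw** counts ("copy numbers"): the Mecom threshold is
the 99.95th percentile with linear interpolation (R quantile type 7 — the
convention is pinned by worked examples in the tests), computed per
genotype dataset; a cell qualifies with Mecom strictly above the threshold
and Kit ≥ 1. By construction at most ~0.05% of cells (minus ties) qualify.

## Spatial statistics

Two cells are neighbours when their segmentation centroids are strictly
less than 20 µm apart; centroid distance is used because centroids are what
the pipeline produces. The same strict-< rule defines the 20-µm niche
around each HSC (the central HSC is excluded from its own member list;
another HSC in range is a member). Pair enrichment compares the observed
probability of each unordered type pair among neighbour pairs with the
random-pairing null `2·f_a·f_b` (or `f_a²` for self pairs); with self pairs
removed, the null renormalises to `2·f_a·f_b / (1 − Σ f_t²)`. Each pair is
tested by a 1-df chi-square with continuity correction on observed versus
expected pair counts, then FDR-adjusted; the continuity-corrected variant is
the one that reproduces the published niche-composition P value of 0.0422
from the counts 21/254 vs 5,876/112,392, which pins the choice. Abundance
fractions for the null are computed per replicate, matching per-replicate
significance calls; a pair is "reproducible" when positively enriched and
significant (adjusted P < 0.01) in at least three replicates.

## Differential expression and the co-expression screen

DEGs compare normalised expression between two disjoint cell sets with a
two-sided Wilcoxon rank-sum test — exact by enumeration (midranks for ties)
when the pooled sample is ≤ 20, otherwise the tie-corrected normal
approximation — and log2 fold changes of pseudocounted group means
(ε = 0.1 normalised units). Significance requires, in the total data,
|log2FC| ≥ 1 and FDR-adjusted P < 0.05, and in *both* replicate groups raw
P < 0.1 with a direction consistent with the total; the adjusted/raw
asymmetry mirrors how the thresholds are stated for the two stages. The
default replicate split is first half versus second half of the sorted
replicate ids (2+2 for four replicates, 2+1 for three), and is
configurable. Group-difference tests from summary statistics use Welch's
t-test with Welch–Satterthwaite degrees of freedom; the ± values such
tests consume are treated as standard deviations, the reading under which
the published P = 0.04 reproduces (SEM does not).

The niche co-expression screen correlates each candidate niche gene with
every cell-type marker across individual niche cells (Pearson), keeps the
highest r per (gene, type), adjusts P values over all tested gene–marker
pairs, and reports r > 0.1 with adjusted P < 0.05. Constant vectors are
skipped and logged rather than propagating NaNs.

## Validation scope and problem sizes

The test suite validates each stage against independent oracles: exhaustive
enumeration for the code, brute-force all-pairs computation for the
neighbourhood statistics, base-R `chisq.test`/`t.test`/`wilcox.test` for the
statistical primitives, and ground-truth scenes for the imaging path. The
end-to-end recovery check runs one 260-cell scene (~190 µm field, nine
types at equal abundance so every cluster is populated) and requires ≥ 90%
of molecules recovered with correct identity and ≥ 95% of cells correctly
typed; null-calibration checks use 20 seeds of 1,500-cell point patterns,
and planted-effect recovery uses 10 seeds each for spatial affinities
(700-cell scenes) and DEGs (240-cell comparisons). Balanced abundances in
the typing checks are a deliberate choice: with fetal-liver abundances a
scene of this size carries only a handful of cells of each rare type, and
cluster-level typing of a three-cell type tests sampling noise rather than
the method. Scenes large enough to type rare populations at realistic
abundance (tens of thousands of cells) are out of test-suite scope.

## Known limitations

The pipeline is strictly 2D, uses integer-pixel drift correction, and
assumes translation-only drift. Watershed segmentation carries no learned
shape prior and will split highly non-convex cells. Niche membership by
centroid distance ignores the sectioning bias whereby a contacting cell may
lie outside the imaged slab. The synthetic scene generator is a validation
instrument, not an optics simulator.
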