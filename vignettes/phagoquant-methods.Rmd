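---
title: "Rule-based quantification of microglial assays: models and design choices"
author: "phagoquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based quantification of microglial assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phagoquant)
```

# Scope

phagoquant quantifies four cellular phenotypes of microglia-like cells from
multi-channel fluorescence fields, plus the enrichment statistics of a
GFP-Trap TMT pulldown:

1. **Phagocytosis**: nuclei are detected by a rule-based classifier, expanded
   into perinuclear zones, pHrodo-positive particles are counted inside the
   zones after a strict fold-over-background filter, and the per-field index
   is *beads/cell* = retained spots / nuclei.
2. **Puncta and autophagy flux**: small bright puncta are counted per cell;
   tandem mCherry–GFP reporter puncta are classified into autophagosomes
   (dual-positive) and autolysosomes (mCherry-only).
3. **NF-kB translocation**: per cell, the count of NF-kB-positive pixels
   colocalized with the nucleus, and a continuous nuclear signal fraction.
4. **TMT interactome**: contaminant/reverse/min-peptide filtering, log2
   transform, per-protein Welch *t*, permutation-based FDR at 1% and 5%, and
   interactor calling by the conjunction of fold enrichment and FDR.

Because the raw assay data are not redistributable, every stage is developed
and validated against a synthetic generator (`simulateField`,
`simulateReporterField`, `simulateNfkbField`, `simulateTmt`) that emits
complete ground truth.

# The segmentation ruleset

`detectNuclei` applies, in order: a global fluorescence threshold (Otsu on
the nuclear channel by default; a fixed value can be supplied), connected
components (8-connected by default), hole filling, morphological smoothing of
each object by shrinking and regrowing it by `smoothingRadius` pixels
(default 2; if erosion splits an object the largest fragment is kept), and a
two-part classification: the area must lie within `areaBounds` and the
*elliptical fit* must exceed `ellipticalFitThreshold` (default 0.8,
strictly).

**Elliptical fit.** The shape feature is defined here as the Jaccard overlap
between the object mask $M$ and its moment-equivalent ellipse $E$: $E$ shares
$M$'s centroid, takes orientation and axis ratio from the eigendecomposition
of the second central moments of the pixel centres, and is scaled so its
continuous area $\pi a b$ equals $|M|$. The fit is
$|M \cap E| / |M \cup E| \in [0,1]$. This choice is bounded, rotation-aware
and testable by brute force; one-pixel masks score 1 by convention, and
degenerate (collinear) masks floor the minor semi-axis at 0.5 px. Solid
ellipses score near 1 (rasterization only), compact crosses score at or
below 0.8, which is what the gate is for.

**Area bounds.** No published values exist for the size gate ("small and
large objects" are excluded); the defaults (60–2500 px²) bracket the
synthetic nuclei generously and are explicitly a fixture, not an estimate of
the original analysis.

**Zones.** Accepted nuclei are expanded by `zoneRadius` = 50 px. Where
expansions would overlap, each pixel is assigned to the nucleus whose mask is
nearest in Euclidean distance (exact ties go to the lower label), so zones
are disjoint and double counting is impossible. Border objects are scored
like any other (a config flag can exclude them).

# Spot detection and the fold filter

`detectParticles`/`countPuncta` share one local-contrast detector: a white
top-hat (grayscale opening subtracted from the image, disc radius =
largest expected spot) restricted to the union of zones, thresholded at
`contrastSigma` (default 3) robust background sigmas above the in-zone
top-hat baseline, followed by binary smoothing (shrink/grow by 2 px for
particles, 1 px for the smaller puncta) and relabelling. The baseline term
matters because the top-hat of a noisy background sits above zero by
roughly the local noise range; thresholding relative to the baseline keeps
the detector calibrated both on noisy and on noise-free images, and the
top-hat itself makes counting invariant to flat background offsets.

The background level is the median intensity outside all zones (per-zone
annulus and global-median variants are available), floored at the smallest
positive observed intensity. Each particle's fold over background is its
mean intensity divided by this estimate, and it is retained only when the
fold **strictly exceeds 2.0** — a spot at exactly 2.0-fold is rejected, a
boundary pinned by tests using decoys generated at exactly that ceiling.

The per-field index is beads/cell = retained spots / accepted nuclei, i.e.
spots are pooled per image before normalizing (per-cell counts are also
emitted). Time courses are summarized as mean ± SEM across replicate fields
per genotype and timepoint; single-replicate cells report SEM 0 with n
flagged, and missing timepoints are preserved as gaps.

# Flux classification and NF-kB readouts

`classifyFlux` matches GFP puncta to mCherry puncta greedily by nearest pair
within `matchRadius` (default 3 px), each punctum used at most once. Matched
pairs are autophagosomes, unmatched mCherry puncta are autolysosomes, and
unmatched GFP puncta — biologically unexpected for this reporter — are
reported separately as anomalies. The AL/AP ratio is defined only when at
least one autophagosome exists.

`nuclearLocalization` reports two readouts per cell: the number of pixels
above a per-field Otsu threshold on the NF-kB channel that fall inside the
nucleus mask (the colocalized-pixel count, the figure-style metric and the
default for reports), and a continuous fraction — background-subtracted
NF-kB intensity summed over the nucleus divided by the sum over nucleus plus
cytoplasmic zone. The assay in the source imaging was measured in voxels;
this pipeline is single-plane, so "voxels" are handled as 2D pixels — an
intentional, documented divergence, and no numerical equivalence with the
original 3D measurements is claimed. Both thresholded and intensity-summed
variants are emitted because the original choice is not recorded.

# TMT enrichment statistics

`preprocessTmt` removes contaminant-flagged rows, reverse hits and proteins
with fewer than two unique peptides, then log2-transforms the reporter
intensities. Rows containing zeros are dropped with a reported count rather
than offset by a pseudo-count the source analysis never states (an offset
policy is available in the config).

Per protein, enrichment is the difference of group means of log2 intensities
(GFP − control); "fold enrichment" is reported as $2^{\Delta}$. Whether the
original fold was computed on raw or log2 means is not recorded; the log2
definition is used and flagged here. The test statistic is Welch's *t*
written from its closed form with Welch–Satterthwaite degrees of freedom
(validated against `stats::t.test` to 1e-10), with an optional SAM-style
variance fudge `s0` added to the denominator (default 0, since no s0 value
is recorded for the original analysis).

**Permutation FDR.** Group labels are permuted over the distinct balanced
relabelings of the 8 channels — 34 partitions besides the observed one for a
4 vs 4 design; the full exhaustive set is used whenever it is smaller than
the requested permutation count, otherwise a seeded uniform sample without
replacement. At each candidate threshold $\tau$ (the observed $|d|$ values)
the FDR estimate is the mean permuted count of $|d| \ge \tau$ divided by the
observed count. Two numerical choices: the permuted count is floored at one
exceedance over all permutations (a finite permutation set cannot certify a
zero tail probability; without the floor, a single protein whose observed
statistic happens to top every permuted value would be called at any level),
and the raw curve is monotonized step-down (each threshold receives the
minimum raw FDR at or below it) so the FDR is non-increasing in $\tau$ and
calls nest across levels. A mean-count estimator is the default; a median
variant is available, as the original software's exact variant is not
recorded.

Interactors are proteins with fold enrichment strictly above 2.0 **and**
significance at 1% FDR; the top set takes the 50 highest-fold proteins among
those at or above 3.0-fold, stable-sorted by fold then id. Both rules are
conjunctions: a significant protein below the fold cut, or an enriched
protein above it that is not significant, is excluded.

`twoWayAnova` uses the textbook partitioned sums of squares for balanced
designs (verified against brute-force cell/marginal sums) and Type II sums
of squares for unbalanced ones; Tukey HSD comes from the studentized range
on the residual degrees of freedom, Sidak adjustment is
$1-(1-p)^m$ capped at 1 (identity at $m=1$ by construction). Cytokine
concentrations normalize proportionally to a reference protein content
(100 µg for microglia monocultures, 500 µg for microglia–motor-neuron
cocultures).

# The synthetic generator

The generator is first-class, tested code; its defaults define the study
conditions used by the package's own validation:

* **Fields**: 512×512 px, 30 elliptical nuclei (semi-axes 8–12 × 5–8 px,
  amplitude 500 AU over a 100 AU background), placed with centroid
  separation at least the sum of semi-major axes so truth objects never
  merge. One nucleus per cell; the cell body is a dimmer (1.15× background)
  ellipse at 2.2× the nucleus axes, rendered in the pHrodo channel only —
  the assay identifies cells by nuclei.
* **Uptake kinetics**: the acquisition grid (0–135 min every 15 min, ten
  frames) is fixed by the assay design; no kinetic law is published, so a
  saturating exponential mean $\lambda_{\max}(1-e^{-kt})$ with Poisson
  per-cell counts is adopted — two parameters, concave, qualitatively
  matching observed uptake curves. Defaults: $\lambda_{\max}=6$ beads/cell,
  $k = 0.03$ (fast) vs $0.018$ min⁻¹ (slow).
* **Particles**: discs of radius 3–5 px painted at fold × background with
  true folds in (2.5, 5] and decoy folds in [1.2, **2.0**] — the decoy
  ceiling sits exactly at the filter boundary so rejection is falsifiable.
  Placement is non-overlapping within ~40 px of the owner nucleus.
* **Reporter puncta**: radius 2.5 px at 4× background; dual puncta are
  painted at identical positions in both channels; placement respects the
  nearest-nucleus partition so per-cell truth counts are exact.
* **NF-kB**: each cell's total signal S (5×10⁴ AU) is split f : (1−f)
  between the nucleus mask and the cytoplasmic annulus (which excludes all
  nuclei).
* **Noise**: Poisson shot noise (scale 1), additive Gaussian read noise
  (sd 5 AU) and an optional linear background ramp, applied after object
  rendering; `noiseFree()` zeroes all three for exact round-trip tests.
* **TMT tables**: 2000 proteins × (4 vs 4) channels; per-protein baselines
  N(20, 2) on the log2 scale with 0.5 (or, for the spike-in fixture, 0.2)
  per-channel measurement sd; spiked interactors shifted in the GFP group;
  contaminant/reverse rows flagged and disjoint from the spike-ins; spiked
  rows always carry at least two unique peptides (a "true interactor" that
  fails identification would be unrecoverable by construction, which is a
  property of the search engine, not of the statistics under test).

None of the per-cell count distributions or effect sizes are published
values; they are fixtures chosen once to be realistic for this assay class.
What passing tests show is therefore that the *pipeline* recovers known
truth under controlled noise — not that it numerically reproduces the
original study's measurements, whose raw images and tables are not
available. Real data differ in ways the generator does not emulate: PSF
blur, uneven illumination beyond a linear ramp, touching nuclei (watershed
splitting is out of scope), debris, and autofocus failures.

# Problem sizes and numerical choices

The validation suite and the acceptance script size their simulations to be
decisive yet quick: 50 (tests) or 25 (script) noisy 512² fields for
segmentation recovery; a 2-genotype × 10-timepoint × 20-field sweep of 256²
fields with 12 nuclei each for uptake recovery; 100 count-level replicates
for the genotype ANOVA power (one rendered-field sweep validates the pixel
pipeline; replicating the power study at the pixel level would multiply the
cost 100-fold without changing the count distribution, which the rendered
sweep is shown to reproduce); 100 (tests) or 50 (script) null TMT tables
for FDR calibration. Determinism is guaranteed by deriving every per-field
seed from the single run seed.

Other numerical conventions: Otsu thresholds are computed on the image
rescaled to [0,1] with 256 histogram bins; zone ties break to the lower
label; particle ownership is the zone containing the centroid (majority
zone of the mask as fallback); TIFF output stores 32-bit floats scaled by a
per-field factor recorded in the JSON sidecar (the tiff writer clips values
outside [0,1]).

# Known limitations

* No watershed splitting of touching nuclei and no 3D support.
* The elliptical-fit formula is this package's definition of an otherwise
  unspecified commercial feature; gates calibrated against one should be
  re-checked against the other.
* Permutation granularity: with 8 channels only 34 informative relabelings
  exist, so attainable FDR estimates are quantized; the pseudo-count floor
  makes the smallest attainable non-zero estimate explicit rather than
  reporting zero.
* The phagocytosis index counts spots; it does not calibrate spot intensity
  to bead units, track particles over time, or model pHrodo chemistry.
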