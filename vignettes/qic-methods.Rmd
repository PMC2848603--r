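---
title: "Cell identification and quantification: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell identification and quantification: models, parameters, design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qicyte)
```

This vignette is the package's account of its own methods: what each stage
assumes, why the defaults are what they are, what the synthetic data do
and do not emulate, and where the design was genuinely open and a choice
had to be made.

## The imaging model

A field is a set of aligned 2-D grayscale channels: a DNA stain marking
nuclei, a lipid-binding whole-cell stain marking cell bodies, and one or
two immunostain (antigen) channels. Intensities are carried in native
arbitrary units and never rescaled; every rule in the pipeline is
covariant under a global intensity scaling except the fixed pixel-unit
window sizes, which are tied to the optics (41 px is about 30 µm at the
10x magnification the defaults assume).

The background model is additive: a smooth non-uniform illumination plane
plus approximately Gaussian sensor noise. The 3-SD detection rule and the
SD-mode estimator both lean on this assumption; strongly Poisson-limited
images would call for a variance-stabilizing transform first, which the
package does not provide.

## Segmentation, stage by stage

**Nuclear thresholding.** A pixel is nuclear foreground when it strictly
exceeds the mean of the `nuclear_window_px` (default 41, odd) window
centred on it. Windows are cropped at the image border — the statistic is
taken over the intersection of window and image — because padding with
any constant biases border thresholds. The comparison carries a relative
tolerance of 1e-9 of the image maximum so that exactly flat regions,
where the windowed mean equals the pixel value up to float round-off,
never threshold as foreground.

Strict local-mean thresholding has an unavoidable property: in flat
background, any pixel above its window mean — about half of them — is
marked foreground. Compact bright nuclei are immune (the inflated local
mean around them carves a clean moat), but the distant background
degenerates into speckle. The *bright-object stage* resolves this at the
object level: a labelled object is kept only if its mean intensity
exceeds its local background mean by `bright_object_sd_multiplier`
(default 3) global background SDs *and* it has at least `min_object_px`
(default 16) pixels. Both criteria sit two orders of magnitude away from
real nuclei (a nucleus here is ~100+ px at ~100 SDs above background), so
they only remove noise. This is the package's operationalization of
"labelling bright objects"; it is what makes a blank noise field yield
zero cells.

**Limited watershed.** Adjacent nuclei merge into one thresholded clump.
The clump is split at the lowest intensity level whose strict
superlevel set has at least two connected components, and the split is
accepted only when the summed intensity above that watermark exceeds
`watershed_retention` (default 0.85) of the object's total intensity.
Retention is measured by *intensity*, not area — the wording of the rule
("retains an intensity") is taken literally, and the intensity reading is
also the noise-robust one: for a single noisy plateau, any separating
level strips roughly half the pixels, so the retained fraction falls far
below 0.85 and the object stays whole. Only the *lowest* separating
watermark is examined; if it fails the retention test the object is
final. Raising retention therefore strictly reduces splitting: at
retention ≥ 1 nothing splits (some pixel always sits at or below any
watermark), while near 0 any separable object splits. An accepted split
is completed by a marker-controlled watershed with the above-watermark
components as markers, so valley pixels are reassigned and the children
tile the parent exactly; children are examined recursively. Candidate
levels are the sorted unique intensities (exact mode); a 256-level
quantile mode (`watershed_levels = "quantized"`) exists for very deep
objects but the defaults never need it.

**Dim-object removal.** The "typical G1 DNA total" is estimated as the
mode of a Freedman–Diaconis histogram of per-object DNA totals, and
objects below `min_dna_fraction_of_g1` (default 0.5) of it are removed —
debris and apoptotic fragments carry far less DNA signal than any intact
nucleus. A histogram mode over fewer than `min_objects_for_g1` (default
20) objects is unreliable, so the filter is then skipped with a warning;
`g1_total` accepts a known absolute level instead and is the safer choice
for sparse fields.

**Cell-contour segmentation.** The threshold at each pixel is the *local
background mean* plus `cell_sd_multiplier` (default 3) times the *global
background SD*. The local background mean is the mean of the presumable
background — whatever local-mean thresholding with the same window calls
background — inside the 41-px window; a window containing no background
pixel (a field-filling object) falls back to the global background mean.
The SD is global, the mode of the per-pixel 5 × 5-window SD histogram,
because a local SD balloons wherever the window brushes an object while
the mode ignores that minority tail. Two consequences are worth knowing.
First, the threshold is independent of how bright neighbouring objects
are — the property that makes the rule robust to non-uniform
illumination. Second, the presumable-background mean is slightly biased
low (it averages the below-local-mean half of the noise), so the
effective rule sits nearer 2 σ than 3 σ and scattered single-pixel
exceedances are expected; they are discarded later because they contain
no nucleus.

**Division.** Nuclei are unioned into the cell foreground (a nucleus
protruding past the stained body must still end in its cell), and each
foreground component is partitioned among the nuclei it contains by a
marker-controlled watershed that admits pixels in order of decreasing
cell-stain intensity — flooding the inverted intensity surface from the
nuclear markers. Components without a nucleus are dropped. Ties are
deterministic: equal-priority pixels are processed first-in-first-out and
a pixel reachable from several regions joins the lowest-numbered one.
Labels are assigned in row-major raster-scan discovery order, so the
whole pipeline is reproducible bit for bit; there is no randomness
anywhere in segmentation.

## Quantification

Amounts are raw sums — no background subtraction — over the cellular and
nuclear masks, matching what a plate-level assay measures; downstream
statistics may subtract a baseline explicitly (`baseline_subtract()`,
which clips at a small positive floor and reports the clipped count so
log statistics stay defined and nothing is dropped silently).

**Roundness** is `P^2 / (4 pi A)`, the isoperimetric ratio: 1 for a
circle, about 1.51 for a 3:1 ellipse, so the 1.2 cutoff passes round
single-nucleus cells and rejects elongated unresolved doublets. The
perimeter estimator matters: a raw border-pixel count overestimates a
disk's perimeter by tens of percent. The 4-direction Crofton estimator
(integral-geometry weights over the 2 × 2 pixel-configuration histogram)
is used instead; it lands within about 1% of `2 pi r` on a radius-30
disk, and its small-shape bias is the reason the acceptance window for a
rasterized disk's roundness is [0.95, 1.15] rather than a point.

**NLI.** The nuclear localization index is the cosine between the
per-pixel nuclear-stain and antigen vectors over the cell. It needs no
delineation of a cytoplasmic compartment, and homogeneity of the cosine
makes it exactly invariant to per-channel scaling — staining level and
antigen amount cancel. Closed forms pin the scale: proportional channels
give 1, disjoint supports 0, and a uniformly distributed antigen over a
cell whose nucleus covers a fraction m/n of its area gives sqrt(m/n)
(0.5 for a quarter). Note the index is computed on raw intensities, so a
shared background raises its floor; it is a *relative* index, to be
compared across cells and time points, not an absolute nuclear fraction.

**Normalized NLI.** The cell-stain NLI of the same cell responds to the
same nuisances (cell density, staining level) but not to antigen
localization, so it serves as a per-cell correction. The exact published
form of this correction was not recoverable, so the package fixes it as
the per-cell ratio re-centred by the well average,
`nli * mean_well(nli_cellstain) / nli_cellstain`, and exposes the simpler
well-level division `nli / mean_well(nli_cellstain)` behind
`strategy = "well_mean"`. Both are exact when the cell-stain NLI is
constant in the well and both cancel a multiplicative nuisance; the
per-cell ratio additionally removes cell-to-cell nuisance variation,
which is why it is the default.

**Ill-identification.** When the apparent nucleus position in the cell
channel is displaced (chromatic aberration between filter sets), the
nuclear mask sits on the wrong part of the cell body and every
measurement of that cell is suspect. The detector is a reconstruction,
not a transcription: the colocalization index is the *mean-centred*
cosine (Pearson correlation) of the two segmentation channels over the
cell's pixels, clipped below at zero. Centring is essential — the shared
background plane plus any flat positive noise would hold a raw cosine
near sqrt(m/n) regardless of geometry, whereas the centred cosine
collapses toward zero as soon as the two patterns stop co-varying. The
default threshold of 0.3 was chosen on synthetic fields: undisplaced
cells measure about 0.7–0.8 and fully displaced ones below 0.05, so 0.3
splits the two regimes with a wide margin on both sides. Flagged cells
are *kept* by default (`exclude_ill_identified = FALSE`) so that
population averages remain comparable across quantification methods;
the run report carries the flagged fraction.

**HCS baseline.** The conventional quantifier is implemented as
described for a 10x objective and deliberately not improved: the ROI is
the nucleus dilated by 16 px (disk structuring element), overlapping ROIs
double-count shared pixels — that *is* the cross-contamination mechanism
— and the Circ (nucleus eroded 2 px) / Ring (dilated 4 px minus eroded
1 px) average-intensity ratio is computed without clipping to any cell
boundary, since the baseline has none. A nucleus emptied by the Circ
erosion is flagged and its ratio left undefined.

## Population statistics

Per-cell totals are treated as lognormal: averages are geometric
(`exp(mean(log x))`), spreads are SDs of natural-log values, and
association is the Pearson correlation of log values, which is invariant
to per-channel rescaling. Time points with fewer than two usable cells
are omitted with a warning; non-positive values are excluded from log
statistics and counted.

Inter-experiment normalization treats every sample as an internal
standard. The published objective was not recoverable, so two defensible
variants ship. The default alternates least squares on
`sum_jk (a_j x_jk - m_k)^2` — scaling factors against the cross-experiment
means of the scaled samples — to convergence; the `"geometric"` method is
the closed form `a_j = exp(-mean_k(log x_jk - mean_j log x_jk))`. The
overall scale is unidentifiable, fixed by the gauge `mean(a) = 1`; both
methods collapse a pure rescaling exactly and never touch
within-experiment ratios.

## What the synthetic data emulate — and what they do not

`generate_field()` renders what the segmentation stages assume:
star-convex cell bodies (truncated Fourier perturbation of a disk —
irregular enough to exercise contour identification, simple enough for
exact ground truth), one nucleus per cell, a touching fraction placed as
overlapping-body pairs whose contact pixels go to the nearer cell in
normalized radius, ploidy-determined DNA totals (constant in G1, doubled
in G2, 5% staining jitter — DNA content does not scale with nucleus
size), lognormal per-cell antigen totals split between nucleus and
cytoplasm (per-channel fractions allowed, e.g. a cytoplasmic kinase next
to a partly nuclear substrate), a cell stain that fades to 65% at the
contour (cells are thinner at their edges — this also gives the dividing
watershed a real valley at cell–cell contacts), a background plane with
linear gradient, additive Gaussian noise, and an optional integer
chromatic shift of the cell channel. Defaults are a 512-px field, 50
cells of radius 14 ± 2 px, 20% touching, nucleus/cell area ratio 0.35,
background 100 with slope 0.05/px and noise SD 5, stains at 500
(nuclear) and 180 (cell) above background — a subconfluent 10x field
with stains far above the 3-SD floor, as a usable experiment would be.

Not emulated: point-spread blur and defocus, Poisson photon statistics
(a Poisson option is deliberately out of scope; the thresholds assume
additive noise), autofluorescence texture, non-convex or migrating cell
shapes, and real antibody binding variability. Passing the synthetic
acceptance battery therefore demonstrates that the algorithms implement
their contracts — not that segmentation accuracy on real micrographs
will match the synthetic recall. The generator's determinism (a mandatory
seed, RNG state restored afterwards) is itself load-bearing: it is what
lets the test suite freeze expectations.

`generate_population()` plants the kinase–substrate mechanism the
trajectory statistics probe: per time point,
`log MEK ~ N(mu_t, sigma_MEK^2)` and
`log ERK = c log MEK + eps_t`, `eps_t ~ N(0, sigma_eps(t)^2)`, so the true
log-Pearson correlation is
`c sigma_MEK / sqrt(c^2 sigma_MEK^2 + sigma_eps(t)^2)` — a closed form
the measured trajectory can be checked against.

## The QIC-vs-HCS comparison

On dense touching-cell fields with two antigen channels of different
subcellular geometry, the dilated-ROI baseline mixes each cell's signal
with its neighbours' and with background. The robust consequences, and
the ones the acceptance suite asserts per time point, are smaller
log-space SDs in both channels and a smaller log-covariance than
contour-based quantification on exact masks. The correlation coefficient
itself is *not* asserted: contamination adds both shared distortion
(ROI-coverage variation multiplying both channels, which raises
correlation) and channel-specific distortion (mixing weights that depend
on each channel's spatial distribution, which lowers it), and on this
generator the net sign is not stable across seeds. The covariance and SD
statements are the mechanism's unambiguous signature.

## Problem sizes and numerical conventions

The test battery runs at deliberately modest sizes — 512-px fields, 5
seeds for segmentation recovery, 6 time points of 60 cells for the HCS
comparison, 10^4 cells per time point for trajectory recovery — chosen so
the whole suite completes in well under a minute while keeping
Monte-Carlo error far from every tolerance (correlation SE at n = 10^4 is
about 0.01 against a 0.03 band).

Conventions fixed for reproducibility: row-major raster order with origin
top-left; object connectivity 8 and background 4 by default; windowed
sums via summed-area tables with the image centred on its global mean
before the sum-of-squares pass (curbing cancellation to ~1e-9 relative
against a two-pass oracle); watershed ties FIFO-then-lowest-label; CSV
serialization at 17 significant digits so tables round-trip bit-exactly;
label masks stored as 16-bit TIFF. Degenerate inputs degrade explicitly:
constant images give a zero SD estimate with a warning, empty fields give
empty masks and header-only tables, and an all-zero intensity vector
yields an `NA` index with a flag rather than a number.

## Known limitations

The G1-mode estimate assumes G1 cells are the modal DNA class; heavily
aneuploid or debris-dominated preparations should supply `g1_total`. The
41/5-px windows and the HCS 16/2/1/4-px geometry are pixel-unit constants
for a 10x objective and must be rescaled by the user for other optics.
The ill-identification threshold was calibrated on synthetic geometry;
real chromatic aberration is sub-pixel to a few pixels and will produce
intermediate colocalization values, so the threshold deserves a per-rig
look. 2-D only: confluent monolayers with significant overlap in z are
outside the model.
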