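---
title: "Methods: stiffness-map, collagen and expression quantification on phantoms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stiffness-map, collagen and expression quantification on phantoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stiffpdx)
```

`stiffpdx` re-implements, as a tested pipeline, the measurement chain of an
in vivo stiffness study of ovarian-cancer xenografts: shear-wave-elastography
(SWE) map quantification, collagen morphometry from second-harmonic
generation (SHG) and trichrome histology, and a gene-signature subtype
classifier with compartment-specific differential expression. Animal and
patient data are not reproducible at desk scale, so every stage runs against
synthetic phantoms whose ground truth the package also generates. This
vignette documents the models, the conventions, and the choices made where
the design was genuinely open.

## Elastography model

SWE maps report the Young's modulus per pixel. For soft, nearly
incompressible, isotropic tissue of constant density $\rho$, the modulus
follows from the shear-wave speed $v_s$ as

$$E = 3\,\rho\,v_s^2,$$

reported in kPa (`young_modulus_from_shear_speed()`). The density is a
required argument — the analysis paths never assume a hidden default, because
no numeric $\rho$ is part of the published protocol.

A measurement session produces repeated acquisitions (three by default) of
the same tumor at each timepoint. The analysis chain mirrors the instrument
software: a hand-drawn contour defines the ROI; `summarize_roi()` gives
min/max/mean/SD (sample SD, $n-1$); `mean_tumor_stiffness()` averages the
per-replicate ROI means; `select_representative_frame()` picks the cine-loop
frame with the least coupling-gel signal, since gel carries no shear-wave
signal and its level is pure noise; `estimate_noise_floor()` summarizes that
noise as the 95th percentile (linear interpolation, R type 7) of gel pixels
and is used for frame QC only — tumor pixels are never censored.

### Geometry convention

One convention serves every module: pixel coordinates are 0-based, $x$ to the
right, $y$ down, with vertices and pixel centers at pixel-center positions.
`pixels_in_contour()` keeps pixels whose centers fall strictly inside the
polygon (even-odd rule); centers lying exactly on the contour are excluded.
An axis-aligned square with corners at pixel centers $(0,0)$–$(10,10)$ thus
contains the $9\times9$ interior block, not the boundary.

### Radial analysis

The radial profile relates each ROI pixel to the tumor barycenter (the
unweighted centroid of the ROI pixel centers). The normalized radius of a
pixel is its distance to the barycenter divided by the distance from the
barycenter to the contour *along the same ray* (ray–polygon intersection), so
$r_\text{norm}=1$ on the boundary in every direction regardless of tumor
eccentricity. When the barycenter falls outside a non-convex contour the
package falls back to $d/d_\max$ and warns.

The center-to-edge decrease is estimated as minus the OLS slope of pixel
stiffness on $r_\text{norm}$ — the fitted drop across $r_\text{norm}$ 0→1.
For the linear radial profile of the phantoms this estimator is unbiased and
uses every pixel; the published account states only a magnitude
("more than 70 kPa"), not an estimator, so the choice is ours and is
documented here.

`partition_center_periphery()` splits the ROI at $r_\text{norm} = 1/\sqrt2$,
the radius that encloses half the area of a disk, giving an equal-area
center/periphery partition.

### Histograms, classification, correlation

`stiffness_histogram()` uses right-open 1-kPa bins over [0, 200) kPa with the
final bin absorbing values ≥ 200, and reports percent of tumor area rather
than counts, so growing tumors remain comparable. Percentages sum to 100 by
construction.

Tumors are classified soft below 40 kPa mean stiffness and stiff at or above
it. The study reports ranges, not a rule; 40 kPa separates all its printed
soft removal ranges (≤ 31.8 kPa) from the stiff ones (≥ 42.5 kPa), and the
boundary value is assigned to stiff. The cut is a parameter everywhere it is
used.

Stiffness–growth association is Spearman's rank correlation (average ranks
for ties; two-sided p from the large-sample t approximation) over all
(mean stiffness, area) measurement pairs of a cohort, pooled across tumors —
each acquisition at each timepoint is one point. Whether radial profiles
should pool pixels across tumors or average per tumor is not stated in the
source; the package records `tumor_id` with every radial record so either
view can be taken, and pools by default.

## The stiffness phantom

`generate_stiffness_map()` renders an elliptical tumor (axis ratio uniform in
[0.7, 1], random orientation, both fixed per tumor seed) on a 256×256 grid at
0.1 mm/px. Grid size and spacing are stand-ins: the acquisition hardware's
export geometry is not public, and all downstream geometry is spacing-aware.
Inside the contour the stiffness is

$$E(r) = E_\text{edge} + (E_\text{center}(t) - E_\text{edge})\,(1 - r_\text{norm}^k) + \varepsilon,$$

with $k=1$ by default (the source shows a monotone gradient; the exponent is
a preset parameter), $\varepsilon \sim N(0, 6\ \text{kPa})$, and the result
clipped to the preset clip range. One acquisition-noise SD serves all
presets. Clipping is truncation, not rejection, so the soft presets literally
satisfy the printed 0–40 kPa pixel range. Outside the contour, pixels are
coupling-gel draws $N(3, 1.5)$ kPa truncated at zero.

Preset magnitudes are anchored to the printed ranges: the stiff Mesenchymal
preset runs 120 kPa (center) over 40 kPa (edge) with clip [0, 200]; the soft
Mesenchymal and Non-Mesenchymal presets are radially flat at 18 and 22 kPa
with clip [0, 40]. Tumor area grows exponentially from 30 to 120 mm² over 10
timepoints (a scale consistent with the order of magnitude of the grafted
volumes), and the core stiffness of the stiff preset interpolates from edge
to center proportionally to relative area growth (`stiffness_coupling = 1`;
the soft presets couple with 0). At the final timepoint the planted
center-to-edge decrease of the stiff preset is therefore exactly 80 kPa.

Every map comes with a truth record. `true_area_mm2` is the pixel-count area
of the emitted contour (exactly what `tumor_area()` recomputes); the analytic
ellipse area $\pi ab$ is stored separately as `model_area_mm2`, because
lattice-point counts of a ~50 px ellipse deviate from $\pi ab$ by several
pixels. `true_mean_kpa` is the disk average of the radial profile,
$E_\text{edge} + (E_\text{center}-E_\text{edge})\,(1 - 2/(k+2))$.

What the phantom does *not* emulate: B-mode texture, probe repositioning
variability between replicate acquisitions (replicates differ only in noise),
skin-rim biomechanics, and non-elliptical tumor shapes. Passing tests
therefore validate the quantification chain, not the physics of acquisition.

## Collagen imaging

`max_intensity_projection()` collapses SHG z-stacks; intensities are never
rescaled, mirroring acquisition at constant detector voltage and laser power
so that integrated densities stay comparable.

The published fiber measurements were manual (freehand lines along fibrils,
straight lines across them). The package substitutes a deterministic
automated analogue, validated on synthetic truth and *not* claimed equivalent
to the manual protocol: Otsu threshold (or a fixed value), Zhang–Suen
thinning to an 8-connected skeleton, spur pruning below 3 px, junction
splitting (junctions are pixels with crossing number ≥ 3 — the raw
8-neighbour count misfires on staircase pixels), and per-path measurement.
Fibrils in the manual protocol are unbranched, so each surviving path is one
fiber record.

Two lengths are exposed. `fiber_length()` is the literal chain sum (1 per
axial step, $\sqrt2$ per diagonal) — exact on straight and diagonal runs but
biased high by up to ~8% on arbitrary orientations, the classical staircase
bias. `fiber_table()` therefore reports `fiber_length_resampled()`: the path
resampled every 4 px and summed as a polyline, which cancels the staircase
bias against the cap extension of the rendered mask and recovers synthetic
truth within 5% on the phantom settings. Thickness is twice the median
Euclidean distance-transform value along the skeleton — the automated
equivalent of a straight cross-line — and recovers truth within one pixel.

The SHG phantom renders smooth random polylines with a Gaussian cross-section
whose FWHM equals the nominal thickness (an Otsu cut between background and
fiber peak then lands near half maximum, so the mask width matches the
nominal thickness). Fibers are placed without mutual contact so the recovered
count is well defined; in crowded configurations the clearance relaxes
gradually but never below surface contact plus one pixel.

Trichrome quantification works in optical-density space:
$OD = -\log_{10}((I+1)/256)$ per channel, concentrations $= OD\,M^{-1}$ with
$M$ the row-unit-norm stain matrix, clamped at zero. The shipped stain matrix
(`masson_stain_model()`, also in `inst/extdata/`) is synthetic — a plausible
collagen / cytoplasm / residual triplet, since no measured vectors are
published — and any user matrix can be read with `read_stain_model()`. The
"identical threshold" of a batch defaults to Otsu computed once on the
batch-pooled collagen channel and then frozen (`batch_collagen_threshold()`).
Collagen density is the integrated density (mean gray × area in mm²) of the
suprathreshold collagen signal over the tissue area. The trichrome phantom
synthesizes concentrations directly and converts to float RGB, so the
deconvolution round trip is exact (≪ 1e-6 OD) without noise; the collagen
mask is cut from a smoothed Gaussian field at the quantile matching the
requested fraction. ROI-level densities are computed on the raw projection
(whether the original ROIs were fiber-masked is ambiguous; the option is
recorded on the density call).

Stroma/epithelium segmentation of real sections is out of scope:
`stroma_percentage()` consumes masks. `hscore()` is
$\sum_i 100\,f_i\,i$ over intensity levels 0–4; the cell-level fractions are
inputs, not detections.

## Transcriptomics

The classifier follows the published recipe: per-gene standardization to mean
0 / SD 1 *within each dataset*, merging on shared genes, hierarchical
clustering of samples on the 36-gene signature (Euclidean distance, complete
linkage), dendrogram cut in two. The published phrasing "standardization per
array ... (for each gene, ...)" is internally contradictory; we standardize
per gene within each dataset before merging, the reading consistent with its
stated purpose of removing platform artifacts, and do not re-standardize
after concatenation. The cluster with the higher mean expression of the
anti-correlated (stromal, Mesenchymal-up) signature half is labeled
Mesenchymal — an inference, since the source only states that the cut
discriminates the groups. The 36 signature gene identities live in external
prior work; the package ships a placeholder signature for synthetic data and
accepts any user list (`read_signature()`, with a `#anticorrelated` marker).

Differential expression uses Student's equal-variance t by default (the
protocol says "unpaired t-test" without Welch; `var_equal = FALSE` switches),
or a paired t for center-versus-periphery within stiff tumors, on
log2(x+1)-scale values. Fold change is $2^{|\Delta|}$ of the mean log2
difference, with direction carried separately, and a gene passes at
$p \le 0.05$ and $FC > 1.2$ with **no multiple-testing correction** — faithful
to the published filter; a Benjamini–Hochberg option exists but is off by
default and is an extension, not the protocol. `de_contrast_suite()` runs the
six contrasts (stiff-center vs soft, stiff-periphery vs soft, paired
center vs periphery; each per compartment); tumors lacking one region are
dropped from the paired contrast with a warning.

The expression phantom emits linear-scale values $2^x-1$ so the downstream
log2(x+1) transform recovers the simulated log2 values exactly. Signature
genes separate subtypes by a chosen multiple of the within-group SD
(default 2 SD — wide enough that clustering recovery is exact, and 0 serves
as a negative control at chance); planted stromal DE genes are raised by
1 log2 unit in stiff-center samples over a 0.25-SD noise floor, the regime in
which the filter recovers ≥ 95% of planted genes with ≤ 6% null pass rate.
Soft tumors contribute a single center-dissected sample, stiff tumors a
paired center/periphery sample, as in the study design.

## Determinism and numerics

Every generator is a pure function of (parameters, seed): a global seed fans
out to per-stage seeds through `mix_seed()`, a documented integer mixer that
stays below $2^{31}$, so any stage can be regenerated in isolation and
`run_end_to_end()` is byte-reproducible from (config, seed). Ties: Spearman
uses average ranks; the representative frame takes the lowest index;
`classify_soft_stiff()` sends the boundary to stiff. Degenerate inputs are
flagged, not silently patched: constant vectors give `NA` correlations,
zero-variance paired differences give a flagged `t = NA`, zero-variance genes
are dropped with a warning, and an empty pixel set or a zero-area polygon is
an error surfaced to the caller.

On-disk stiffness maps are 32-bit float TIFFs divided by a 256-kPa full scale
recorded in the JSON sidecar; the power-of-two scale adds no error beyond
float32 rounding (~1e-7 relative). PNG trichrome files quantize to 8 bits;
exactness claims hold for the in-memory arrays.

## Problem sizes

The test suite and the acceptance script run the study at desk scale, chosen
as the package's own working sizes: 20 stiff-preset maps for the radial
gradient, 16 Non-Mesenchymal growth series of 10 timepoints × 3 replicates
for the softness bound, 10 seeds of 6-fiber SHG fields for morphometry
recovery, 20 seeds of 8+8-tumor expression sets for classifier recovery, and
10 seeds of 10,000-gene matrices for the DE error rates.

## Known limitations

- The phantoms are geometric idealizations; none of the acceptance evidence
  bears on acquisition physics, segmentation of real B-mode images, or
  manual-measurement variability.
- Fiber morphometry assumes non-contacting, unbranched fibers; crossing
  fibers are split at junctions and counted as separate paths.
- The H-score consumes intensity fractions; there is no cell detection.
- Gene lists stop at export; enrichment analysis is delegated to external
  tools by design.
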