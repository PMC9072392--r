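---
title: "Quantifying collagen structure in SHG micrographs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying collagen structure in SHG micrographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shgtex)
```

## The problem

Second harmonic generation (SHG) microscopy images fibrillar collagen
label-free: the non-centrosymmetric triple helix emits frequency-doubled
light, so SHG intensity maps collagen content and the image texture maps
fiber organization. In pulmonary arterial hypertension (PAH), perivascular
fibrosis progresses as collagen is overproduced, bundles and reorients
around blood vessels. `shgtex` implements the quantitative image-analysis
chain used to track this process: square regions of interest (ROIs) near
vessel walls are scored with a Fourier-domain fiber orientation index,
first-order histogram statistics, and gray-level co-occurrence (Haralick)
texture features; DAB-stained immunohistochemistry (IHC) micrographs are
scored with a positive-pixel expression index; and per-ROI feature
distributions are compared between experimental groups.

Because no public micrograph set accompanies this problem, the package
includes a first-class synthetic-scene generator with exact ground truth.
Every downstream stage is therefore testable end-to-end without external
data, and the generator's defaults define the study conditions used by the
test suite.

## Orientation index

For a ROI image $I$, the mean is subtracted (suppressing the DC
component), an optional separable Hann taper is applied, and the 2D FFT
magnitude is center-shifted and normalized by its maximum. The magnitude
is binarized at a threshold of 0.38 of the maximum (inclusive `>=` at the
boundary), and the resulting point set is summarized by its central second
moments. With eigenvalues $\lambda_1 \ge \lambda_2$ of the $2 \times 2$
moment matrix, the equivalent-ellipse convention gives long axis
$4\sqrt{\lambda_1}$ and short axis $4\sqrt{\lambda_2}$, and

$$\mathrm{OI} = 1 - \frac{\text{short axis}}{\text{long axis}}.$$

An isotropic fiber network yields a circular thresholded spectrum and
$\mathrm{OI} = 0$; perfectly parallel fibers yield a collinear spectrum,
$\lambda_2 = 0$, and $\mathrm{OI} = 1$.

Design choices where the procedure is under-determined:

* **Magnitude, not log-magnitude or power**, is thresholded at 0.38 of the
  maximum — the most direct form of a binarized spectrum, and the
  convention this index is defined with.
* **Hann taper on by default.** Without it, the periodic-extension cross
  from tile edges contaminates the thresholded mask and biases the axes
  toward the image axes. The flag is recorded in output, and turning it
  off is supported.
* **Axes from second moments of the full thresholded point set** (no
  connected-component filtering). Moments are rotation-covariant and well
  defined for any mask shape; bounding-box extents are not.
* **Degenerate limits.** A constant ROI has an empty spectrum: it is
  flagged and its OI reported missing rather than invented. A collinear
  mask gives OI = 1; a single-pixel mask carries no anisotropy and gives
  OI = 0.

Numerically, OI is exactly invariant under multiplying the image by a
positive constant (the normalized spectrum is identical) and invariant
under rotation up to resampling error; the tests bound the latter by 0.05
at 37 degrees.

## Texture features

**First-order statistics** are population moments of the intensity
histogram with the divide-by-$n$ convention: mean $\mu$, standard
deviation $\sigma$ (the variance formula is evaluated and its square root
reported), skewness $s$, and *non-excess* kurtosis $k$ (a normal law gives
$k = 3$, a symmetric two-point law $k = 1$). When $\sigma = 0$, skewness
and kurtosis are reported missing.

**Second-order statistics** come from a gray-level co-occurrence matrix
$P_{ij}$: intensities are linearly rebinned to 64 levels over the ROI's
own $[\min, \max]$ range, pixel pairs are counted at distance 1 px along
the four standard directions (0, 45, 90, 135 degrees), counts are
symmetrized by adding the transpose and normalized to sum 1. The five
scalars are

$$\textstyle
\mathrm{Energy} = \sum_{ij} P_{ij}^2,\quad
\mathrm{Inertia} = \sum_{ij} (i-j)^2 P_{ij},\quad
\mathrm{Correlation} = \sum_{ij}
  \frac{(i-\mu_i)(j-\mu_j) P_{ij}}{\sigma_i \sigma_j},$$
$$\textstyle
\mathrm{IDM} = \sum_{ij} \frac{P_{ij}}{1+(i-j)^2},\quad
\mathrm{Entropy} = -\sum_{ij} P_{ij} \ln P_{ij},$$

with natural-log entropy, $0 \ln 0 := 0$, and the correlation of a
zero-variance (single-entry) matrix defined as 0, so a uniform image has
energy 1, inertia 0, IDM 1, entropy 0 and correlation 0.

Choices worth knowing about:

* **GLCM construction parameters** (64 levels, distance 1 px, four
  directions averaged, symmetric) are the standard Haralick conventions;
  all four are arguments and are recorded in output.
* **Per-ROI min–max rebinning** makes the features invariant to intensity
  gain and offset (an exposure change does not move any feature). Users
  who need fixed absolute binning can pre-scale and pass data already in
  level units. One consequence: a family of images that differs only by an
  affine intensity map has identical SOS features, so the package's
  order-to-disorder tests perturb structure (pixel replacement), not gain.
* **Kurtosis is non-excess** to match the printed fourth-moment formula;
  comparisons against software reporting excess kurtosis need an offset
  of 3.

The optimized implementations are held to brute-force double-loop
evaluations of the same formulas within $10^{-10}$ on batteries of random
images; the GLCM must sum to 1 within $10^{-12}$.

## ROI selection

Analysis regions are squares of 150 µm side placed so that the ROI
*center* is at most 500 µm from the vessel wall, no ROI pixel lies inside
the vessel lumen, and ROIs are pairwise disjoint; 50–80 ROIs per group is
the working range, with a recorded warning when fewer fit. Distances are
Euclidean, computed on an exact distance transform of the lumen mask
(`EBImage::distmap`) and scaled by the pixel size.

Where the published rule is under-determined, the package decides and
records:

* the 500 µm rule is applied to the ROI **center** (symmetric, and robust
  to ROI size);
* lumen exclusion is made explicit — perivascular tissue, not lumen, is
  analyzed;
* placement is a **greedy pass over a seeded random ordering** of a
  half-side-stride candidate grid, making a manual selection step
  reproducible; the seed is part of the run configuration;
* without a vessel mask (pure synthetic runs) a config flag enables
  whole-image tiling, recorded in output metadata.

Vessel segmentation itself is out of scope: masks are inputs.

## IHC expression index

The expression index is the percentage of DAB-positive pixels,
$\mathrm{IE} = \text{positive}/\text{total} \times 100$. Commercial
positive-pixel counting tools are proprietary, so the package specifies
classification as the published standard for DAB: per-channel optical
densities $OD = -\log_{10}((I+1)/256)$ are unmixed with the
Ruifrok–Johnston hematoxylin/DAB stain matrix and a pixel is positive when
its DAB density exceeds a threshold (default 0.15). A hue/saturation box
classifier is available as an alternative, and every threshold is recorded
in the result. Absolute IE values from real slides depend on staining
protocol and thresholds; the defaults are validated against the synthetic
generator (recovery within one percentage point across fractions
0.05–0.9), not against any published tissue value.

## Group statistics

Feature distributions are compared with the classical unpaired two-tailed
Student's t-test (pooled variance). Significance stars follow the
convention common in this literature — `*` for $p < 0.1$, `**` for
$p < 0.01$, `***` for $p < 0.001$ — including the unusually permissive
one-star threshold; no multiple-testing correction is applied by default,
matching that practice (the comparison table carries raw p-values so any
correction can be applied downstream). A global one-way ANOVA F-test is
available separately (`anova_groups`). Box summaries use
linear-interpolation quartiles (R type 7) with whiskers at 1.5 IQR clipped
to the data range. Comparisons can run each group against a control or all
pairs.

The t-test's type-I behaviour is verified by simulation: with both groups
drawn from the same normal law ($n = 60$ per group, 1000 replicates), the
fraction of runs earning at least one star must be $0.10 \pm 0.03$.

A known limitation, documented rather than fixed: ROIs from the same
animal/section are treated as independent observations. A mixed-effects
model would be the remedy when per-animal structure is available.

## The synthetic generator

`generate_fiber_image` renders straight fibers with a Gaussian
cross-profile (width parameter = FWHM) on a constant background, with
orientations from an **axial von Mises** law — a von Mises distribution on
the doubled angle, the standard model for undirected fiber data — sampled
with the Best–Fisher rejection algorithm. Concentration $\kappa = 0$ is
isotropic; $\kappa = 16$ is visually near-parallel. Optional noise is
Gaussian (default sd = 5% of peak fiber intensity) or Poisson shot noise.
`generate_vessel_scene` adds a circular low-intensity lumen and a
fiber-dense annular wall of tangentially oriented fibers.
`generate_ihc_image` colors an exact number of pixels
($\mathrm{round}(f \cdot n)$) with the DAB stain vector and the rest with
hematoxylin, through the Beer–Lambert law with per-pixel amount jitter.

Defaults, chosen once as a plausible fibrotic-lung tile and then left
alone: 1000 × 1000 px at 0.15 µm/px (a 150 × 150 µm² tile), 60 fibers,
lengths uniform on 200–800 px (30–120 µm), width 5 px (0.75 µm), peak
intensity 150 over background 10. No quantitative morphology of the real
fibers is published, so these are explicit arguments, not hidden
constants.

What the generator does *not* emulate — and hence what passing recovery
tests do and do not show: fibers are straight (no curvature or waviness),
the background is flat (no parenchymal autofluorescence texture), there is
no optical point-spread function or depth sectioning, and SHG contrast
physics (phase matching, polarization) is absent. Recovery results
demonstrate that the estimators measure what they claim on images whose
ground truth is known; they do not certify absolute values on real tissue.

Every generator is a pure function of (parameters, seed): the same call is
bit-identical, and the caller's RNG stream is left untouched.

## Pipeline and reproducibility

`run_pipeline` takes a single validated configuration (simulation spec or
file manifest, ROI/FFT/GLCM/star parameters, mandatory seed) and produces
one feature row per ROI plus a comparison table, optionally written as CSV
with a JSON run log. Per-image sub-seeds are derived deterministically
from the run seed, so a rerun is byte-identical; every output file header
carries the package version, a hash of the configuration, and the seed.
Degenerate (constant) ROIs stay in the table with missing OI, skewness and
kurtosis, are dropped pairwise from statistics, and are counted in the
log. A thin command-line wrapper (`inst/cli/shgtex.R`) exposes
`simulate`, `analyze`, `compare` and `report` subcommands over the same
functions.

Problem sizes in the shipped test suite are the package's own choices:
orientation-recovery runs use 20 seeds per concentration at the default
1000-px tile; oracle-equivalence batteries use 100 random 32 × 32 images;
statistical calibration uses 1000 null replicates at $n = 60$ per group;
pipeline determinism and effect tests use 192–256 px tiles with
tile-sized ROIs, mirroring how each micrograph tile contributes one
analysis region.

## Known limitations

* OI at moderate concentration depends on fiber length and density as well
  as $\kappa$; the monotone $\kappa$-recovery property is a statement
  about means over seeds, not about single tiles, whose OI at $\kappa = 0$
  has high variance (few bright spectrum pixels survive the 0.38
  threshold).
* The GLCM offset conventions of the original analysis are not published;
  a different choice (e.g. single direction, other distance) changes the
  absolute SOS values, which is why all construction parameters are
  explicit and recorded.
* IE thresholds cannot be claimed to reproduce any published tissue value
  (proprietary classifier, undeposited data); they are validated on
  synthetic ground truth only.
* TIFF resolution tags are honored on read, but written pixel size travels
  in a JSON sidecar (the R TIFF writer does not emit resolution tags).
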