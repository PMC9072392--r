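# shgtex

Quantitative texture and orientation analysis of second harmonic
generation (SHG) collagen micrographs, for tracking perivascular fibrosis
— e.g. in pulmonary arterial hypertension (PAH) models — from image tiles
rather than stains. The package is aimed at microscopists and image
analysts who have (or want to simulate) SHG tiles of lung tissue and need
reproducible, per-region collagen metrics and group statistics.

## What it computes

For each square region of interest (ROI, by convention 150 × 150 µm²
placed within 500 µm of a vessel wall):

* **Orientation index** — from the ROI's mean-subtracted, Hann-tapered 2D
  FFT magnitude, binarized at 0.38 of its maximum; with eigenvalues
  λ₁ ≥ λ₂ of the mask's central second moments,

  OI = 1 − short/long = 1 − √(λ₂/λ₁),

  so OI = 0 for an isotropic network (circular spectrum) and OI = 1 for
  perfectly parallel fibers.
* **First-order statistics** — population mean, standard deviation,
  skewness and (non-excess) kurtosis of the intensity histogram.
* **Second-order statistics** — energy, inertia (contrast), correlation,
  IDM (homogeneity) and natural-log entropy of a 64-level, distance-1,
  four-direction symmetric gray-level co-occurrence matrix (GLCM).
* **IHC expression index** — IE = positive/total × 100 over DAB-positive
  pixels classified by color deconvolution (Ruifrok–Johnston stain
  vectors, optical-density threshold).

Groups of ROIs are compared with unpaired two-tailed Student's t-tests
(stars: `*` p < 0.1, `**` p < 0.01, `***` p < 0.001) and summarized as
1.5-IQR box statistics. A seeded synthetic generator (axial von Mises
fiber orientations, Gaussian-profile fibers, vessel scenes, IHC scenes
with exact positive-pixel counts) provides ground truth for every stage.

## Worked example

Simulate a control group (isotropic, sparser collagen) against a
fibrotic-like group (denser, oriented collagen), one tile-sized ROI per
image, and compare:

```r
library(shgtex)

cfg <- run_config(
  simulation = list(
    control = list(n_images = 12, shape_px = c(256, 256), n_fibers = 25,
                   orientation_concentration = 0,
                   length_law = list(type = "uniform", min = 60, max = 200)),
    pah_2w  = list(n_images = 12, shape_px = c(256, 256), n_fibers = 40,
                   orientation_concentration = 6,
                   length_law = list(type = "uniform", min = 60, max = 200))),
  roi = list(side_um = 38.4, min_count = 1, max_count = 1),
  stars = list(control = "control"),
  seed = 42)

run <- run_pipeline(cfg, out_dir = "demo_out")
print(run)
```

```
<shg_run> 24 ROIs from 24 image(s), 2 group(s)
  config 7ef3259b, seed 42; 10 comparison row(s)
  significant (starred) comparisons:
    oi               control vs pah_2w  p = 0.00115 **
    fos_mean         control vs pah_2w  p = 1.2e-12 ***
    fos_std          control vs pah_2w  p = 2.97e-08 ***
    fos_skewness     control vs pah_2w  p = 1.26e-07 ***
    fos_kurtosis     control vs pah_2w  p = 3.65e-05 ***
    sos_correlation  control vs pah_2w  p = 0.00275 **
    sos_entropy      control vs pah_2w  p = 0.00411 **
```

The oriented, denser group has a higher orientation index (median 0.82 vs
0.63 here), higher mean intensity (more collagen) and higher entropy
(bright distinct fibers over background), and the t-tests flag those
shifts. `summary(run)` returns the per-group box statistics, `plot(run)`
draws the boxplots, and `demo_out/` holds `features.csv` (one row per
ROI), `comparisons.csv` and `run_log.json`, each stamped with the
configuration hash and seed; rerunning with the same config and seed is
byte-identical.

Single-stage use is just as direct:

```r
sc <- generate_fiber_image(orientation_concentration = 16, seed = 1)
orientation_index(sc$image)
#> <axis_estimate> OI = 0.9381 (short 7.99 px, long 129.22 px)
```

A thin CLI over the same functions lives at `inst/cli/shgtex.R`
(subcommands `simulate`, `analyze`, `compare`, `report`).

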