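# retoct

Retinal layer and microvascular phenotyping from polarization-sensitive
OCT (PS-OCT) volumes of the mouse eye.

Mouse models of neurodegeneration are routinely phenotyped through the
retina, which is optically accessible and shares its tissue lineage with
the brain. This package implements the full measurement pipeline for
such studies as reusable, tested R code:

* **Preprocessing** — the retinal pigment epithelium (RPE) scrambles
  polarization, so its top edge is detected per A-scan from the
  cross-polarized channel (derivative-of-Gaussian edge detection); the
  retina is flattened to a plane by integer A-scan translation, which
  simultaneously compensates inter-frame axial motion. A scripted QC
  screen (signal, vignetting) replaces manual scan exclusion.
* **Layer thickness** — seven retinal boundaries (ILM, RNFL/GCL–IPL,
  IPL–INL, INL–OPL, OPL–PRC, PRC–RPE, RPE-bottom) segmented per B-scan
  as lowest-weight paths through a column-monotone pixel graph with
  edge weights `w(a,b) = 2 − (g(a)+g(b)) + w_min`, `g` the
  polarity-signed vertical gradient normalized to [0, 1]; thickness maps
  for six sublayers plus IRL, ORL and TOTAL (= IRL + ORL pointwise),
  averaged over a 200–600 µm annulus centred on the optic nerve head.
* **OCT angiography** — pairwise normalized decorrelation over the
  repeated B-scans, maximum projection into the SVP/ICP/DCP slabs,
  spectral de-striping of motion line artifacts, multi-scale Frangi
  vesselness (4–12 µm in 2 µm steps) with adaptive thresholding and a
  majority vote, SVP projection-artifact subtraction, subregion SNR
  confidence masking at 20/20/15 x the noise floor (20/15/10 profile for
  low-quality data), ONH removal, and vessel density per plexus.
* **Statistics** — a random-intercept mixed model (eyes within mouse,
  REML), pairwise group contrasts with Satterthwaite degrees of freedom
  and Bonferroni correction.
* **Phantom** — a synthetic PS-OCT generator (layered retina,
  depolarizing RPE band, curvature, ONH depression, three decorrelating
  vascular plexuses, per-frame motion, speckle-like noise) with
  exhaustive ground truth, plus a two-level cohort simulator, so every
  stage is verifiable without instrument data.

## Worked example

```r
library(retoct)

cfg <- phantom_config(n_repeats = 3, n_fast = 64, n_slow = 48,
                      n_depth = 280, dx_fast = 1000/64, dx_slow = 1000/48,
                      dz = 2, noise_sigma = 0.1, seed = 11)
ph  <- generate_phantom(cfg)
rpe <- segment_rpe_crosspol(ph$volume)      # [slow, fast, repeat] depths
fl  <- flatten_volume(ph$volume, rpe)
bs  <- segment_all_layers(fl)
tm  <- thickness_maps(bs, onh_center_um = cfg$onh_center_um,
                      spacing_um = c(cfg$dx_slow, cfg$dx_fast))
for (ly in c("RNFL/GCL", "IPL", "INL", "OPL", "PRC", "RPE", "TOTAL"))
  cat(sprintf("%-9s %6.2f um\n", ly, annular_mean(tm[[ly]])$mean))
```

```
RNFL/GCL   29.86 um
IPL        36.05 um
INL        25.05 um
OPL        12.00 um
PRC       100.00 um
RPE        11.02 um
TOTAL     213.98 um
```

The phantom was configured with layer thicknesses 30 / 36 / 25 / 12 /
100 / 11 µm: every annular mean is recovered within one axial pixel
(2 µm) despite 10% speckle noise, curvature and injected frame motion.
Angiography runs the same way on a finer lateral grid (see
`analysis/04_angiography.R`); `analyze_volume()` chains all stages for
one volume.

## Analysis workflow

The `analysis/` scripts reproduce a small end-to-end study on synthetic
data, writing tables under `results/` (volumes go to `scratch/`):

```sh
Rscript analysis/01_simulate_cohort.R    # phantom cohort + manifest
Rscript analysis/02_qc_screen.R          # QC report
Rscript analysis/03_layer_thickness.R    # per-scan annular thicknesses
Rscript analysis/04_angiography.R        # per-scan plexus densities
Rscript analysis/05_group_statistics.R   # mixed-model group comparison
```

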