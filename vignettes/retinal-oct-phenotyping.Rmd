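---
title: "Retinal layer and microvascular phenotyping from PS-OCT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Retinal layer and microvascular phenotyping from PS-OCT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

retoct quantifies two retinal phenotypes from volumetric
polarization-sensitive OCT (PS-OCT) of the mouse eye: the thickness of the
retinal sublayers, and the vessel density of the three retinal capillary
plexuses from OCT angiography (OCTA). This vignette explains each stage's
model and assumptions, the parameters that matter, what the synthetic
phantom does and does not emulate, and the design decisions taken where
the method family leaves choices open.

## Acquisition model

A scan is a pair of co-registered intensity volumes — co-polarized and
cross-polarized — indexed `[depth, fast, slow, repeat]`: `n_repeats`
B-scans are recorded consecutively at each slow-axis position (default
5 repeats, 512 A-lines x 400 positions over ~1 x 1 mm, centred on the
optic nerve head, ONH). Depth indices are 0-based and increase away from
the vitreous; all en-face maps are `[slow, fast]`; physical pixel
spacings (`dz`, `dx_fast`, `dx_slow`, in µm/px) travel with every object
and no operator assumes a value. The axial spacing default is 2 µm/px;
axial resolution of the modelled system is ~3.8 µm in tissue, so this
slightly oversamples, which is the common choice.

The neural retina largely preserves polarization, while melanin in the
retinal pigment epithelium (RPE) scrambles it. The cross-polarized
channel therefore shows essentially one structure — the RPE band — which
makes it the robust anchor for segmentation and motion correction.

## Preprocessing: RPE detection, flattening, motion

`segment_rpe_crosspol()` smooths each A-scan of the cross-polarized
channel with a depth Gaussian (`sigma`, default 2 px) and takes the
maximum of the backward difference inside a search window: the top edge
of the depolarization band. The backward-difference convention places a
boundary on the *first row of the deeper structure*; every boundary in
the package uses this convention, so thicknesses (boundary differences)
carry no systematic offset. Each frame's en-face map is cleaned with a
running median along the fast axis (`median_k = 5`); the filter must not
cross B-scan boundaries because neighbouring B-scans carry different
axial motion. A volume whose cross-polarized band contrast (per-column
max over median after smoothing) falls below `noise_factor = 5` raises
`NoDepolarizingLayer` — the input is likely not PS-OCT.

`flatten_volume()` translates every A-scan by an integer number of
pixels so the detected RPE sits at a common target depth. Repeats are
first aligned to repeat 1 with one rigid shift per frame, the rounded
median of the RPE-map difference. Two reasons: axial bulk motion within
a repeat group is rigid to good approximation, and the median of the map
*difference* cancels the per-column detection jitter, which is common to
all repeats of a static scene. This keeps static voxels bit-identical
across repeats — the property the OCTA stage depends on. Integer (not
subpixel) shifts are used throughout: they preserve the intensity
statistics that the decorrelation estimator needs, and they preserve
within-column distances exactly, so flattening cannot change a
thickness. Shifts that would push tissue (intensity above `clip_frac`
of the column maximum) out of the depth range raise `OutOfDepthRange`.

`qc_screen()` emulates the manual exclusion of unusable scans with two
scripted statistics: mean tissue SNR over the vitreous background
(threshold `snr_min = 3`) and the fraction of A-scans whose maximum falls
below a quarter of the median column maximum (vignetting, threshold
`v_max = 0.25`).

## Layer segmentation by graph shortest path

Seven boundaries are segmented on the repeat-averaged, flattened
co-polarized volume: ILM, RNFL/GCL–IPL, IPL–INL, INL–OPL, OPL–PRC,
PRC–RPE and RPE-bottom. Each B-scan becomes a column-monotone graph:
nodes are pixels, a node connects to the three nodes in the next column
within one row, and an edge costs
`w(a, b) = 2 − (g(a) + g(b)) + w_min`, where `g` is the signed vertical
gradient normalized to [0, 1] under the requested polarity
(dark-to-bright or bright-to-dark) and `w_min = 1e-5` keeps weights
positive. A boundary is the lowest-cost left-to-right path (dynamic
programming; ties break toward smaller depth, so a featureless band
yields the horizontal line at the band top). The gradient normalization
is per B-scan min–max after clipping intensities at the
`despike_q = 0.995` quantile — fully developed speckle inside flowing
vessels otherwise produces isolated spikes that compress the normalized
gradient of every true edge toward 0.5 and flatten the cost landscape.

Boundaries are found in a fixed order, each searched in a per-column
band bracketed by boundaries already found: the RPE top and bottom from
the cross-polarized channel around the flattening target; the ILM as the
dominant dark-to-bright edge above the RPE; then INL–OPL
(dark-to-bright), IPL–INL, RNFL/GCL–IPL and OPL–PRC (bright-to-dark).
Band margins (2–6 px) keep each search outside the smoothed tail of the
much stronger neighbouring edges — the ILM edge in particular spans
several pixels after smoothing and would otherwise capture the INL–OPL
path. The band construction makes the depth ordering invariant by
construction; an ordering violation after search raises
`SegmentationOrderError`. B-scans are pre-smoothed anisotropically
(default depth sigma 1 px, lateral 2.5 px): after flattening the
boundaries are near-horizontal, so lateral averaging suppresses speckle
without blurring the axial edges.

Thickness maps (µm) are boundary differences times `dz`; composites are
IRL = RNFL/GCL + IPL + INL, ORL = OPL + PRC + RPE, and TOTAL (ILM to
RPE-bottom) = IRL + ORL, an identity that holds pointwise and exactly by
construction. Summary statistics use `annular_mean()`: the mean over
pixels whose centre lies at 200–600 µm (half-open interval) from the
manually annotated ONH centre, clipped to the field of view. The inner
radius excludes the ONH, the outer radius covers as much of the field as
possible.

## OCT angiography

The decorrelation estimator is deliberately simple and bounded: per
voxel, the mean over all C(R, 2) repeat pairs of
`|I_i − I_j| / (I_i + I_j + eps)`. Static voxels give 0; fully
decorrelated exponential speckle gives expectation 1/2 (for i.i.d.
exponentials, `|X−Y|/(X+Y) = |2U−1|` with `U` uniform); the value is
invariant to global intensity rescaling. The estimator is a swappable
strategy — any motion-contrast signal with these limits can be
substituted without touching the downstream chain.

Slabs follow the plexus anatomy: SVP = ILM to IPL–INL, ICP = IPL–INL to
INL–OPL, DCP = INL–OPL to OPL–PRC (config-overridable). Each slab is a
per-column maximum projection, then:

1. **De-striping.** Inter-frame motion shows up as periodic horizontal
   or vertical lines. Pure stripes put their spectral energy exactly on
   the frequency axes, while genuine structures spread comparable energy
   into adjacent off-axis bins; an axis bin whose magnitude exceeds 5x
   the median of its nearest off-axis neighbours is attenuated (x0.01).
   This oriented band rejection is the notch equivalent of Gabor
   filtering and, unlike a threshold against the axis median itself,
   does not fire on ordinary sparse vessel content.
2. **Multi-scale binarization.** Frangi vesselness at scales 4–12 µm in
   2 µm steps (the scale is the Gaussian SD of the Hessian filter,
   matching the common toolbox parameterization), each normalized and
   thresholded against a local mean (window 64 px, offset −0.04, i.e.
   threshold = local mean + 0.04); a pixel is vessel if positive in a
   strict majority (≥ 3 of 5) of the per-scale binaries. The offset was
   calibrated once on phantoms with known vessel calibres so that the
   binarized width is unbiased (an offset of 0 over-segments
   capillary-calibre vessels by roughly half their width); it is exposed
   in the run config.
3. **Projection artifact removal.** Large superficial vessels shadow
   into deeper slabs: the final SVP mask is subtracted from the ICP and
   DCP masks, negative values clipped to zero.
4. **ONH removal**, a disk of 200 µm (config) around the annotated
   centre, applied before the SNR step so the saturated ONH cannot
   inflate the noise floor.
5. **SNR confidence masking.** The field is tiled (64 x 64 px); per
   tile, SNR = mean angiogram signal inside the vessel mask over the
   mean in the remainder (the noise floor, in "times stronger than the
   noise floor", SNF). Tiles below threshold are excluded from the
   density denominator: SVP/ICP/DCP thresholds default to 20/20/15 SNF,
   with a 20/15/10 profile provided for lower-quality acquisitions.
   Tiles with no vessel or no background pixels are excluded and
   flagged.

Vessel density is the percentage of vessel-positive pixels within the
included, ONH-free area.

## Group statistics

Outcomes (annular thickness means, plexus densities) are compared with a
random-intercept linear mixed model, `value ~ 0 + group + (1 | mouse)`,
fitted by REML via lme4: the left and right eye of one mouse are
repeated measurements, and the mouse intercept absorbs the shared
anatomy. Group is a single factor (model x genotype cells). Pairwise
contrasts use t statistics with Satterthwaite degrees of freedom
(lmerTest's moment-matching implementation); with g groups all C(g, 2)
contrasts are corrected by Bonferroni (`min(1, m p)`) at a family alpha
of 0.05. The Kenward-Roger alternative is not implemented — Satterthwaite
serves the same small-sample purpose here and the two are used
interchangeably in this setting; this is a documented limitation. Sex is
recorded but not modelled by default. Repeated scans of the same eye are
averaged at table-assembly time, before modelling.

Two analytic limits pin the df implementation: with no between-mouse
variance the df approaches the OLS residual df (eyes − groups); with no
residual variance it approaches the mouse-level df (mice − groups). Both
are verified in the tests within 5%.

## The phantom: what it emulates, what it does not

`generate_phantom()` builds a layered retina with analytically known
geometry: piecewise-constant reflectivity per layer (plexiform layers
brighter than nuclear layers, so each boundary carries a gradient of the
correct sign), spherical bowing (default radius 1.7 mm, the mouse eye),
an ONH depression where the inner layers pinch, a depolarizing RPE band
in the cross-polarized channel (default 15x background), three vascular
plexuses, per-frame integer axial motion, and multiplicative
exponential-type speckle noise. Ground truth is exhaustive: boundary
depth maps in µm, per-layer thickness maps, per-plexus en-face vessel
masks and the injected frame shifts.

Noise model: each voxel's mean is modulated by a shared speckle factor
`1 − s + s·E`, `E ~ Exp(1)` (`s = noise_sigma`), identical across
repeats; voxels inside a vessel tube blend in a fresh fully developed
speckle draw per repeat, weighted by the vessel's decorrelation level,
so decorrelation 1 gives i.i.d. exponential repeats — the closed-form
limit of the angiography estimator. The ONH disk is fully decorrelated
through the retina depth, mimicking its saturated angiogram. Vessel
tubes are clamped to their plexus' anatomical slab so a capillary cannot
leak decorrelation into a neighbouring projection. The default vessel
layout is irregular on purpose (jittered spacing and orientations):
capillary meshes are not periodic, and a strictly periodic layout would
mimic the very line artifacts the de-striping stage removes.

Deliberate simplifications, and hence what passing tests do *not* show
about real data: no coherent speckle simulation (only its contrast and
decorrelation statistics), no per-repeat background noise (static tissue
is exactly static, so the angiogram noise floor is lower than in vivo),
no flow projection tails under large vessels (the SVP-subtraction step
is exercised through en-face mask overlap only), no absorption shadows,
no lateral eye motion, and reflectivity levels that are constant within
a layer. The ONH pinch floors at 25% of nominal thickness rather than 0
so that ground-truth ordering stays strict and integer boundary paths
can remain 1 px apart inside the pinch; the ONH is excluded from every
reported statistic anyway (annulus inner radius 200 µm > ONH radius
100 µm).

## Numerical conventions and degenerate inputs

* Boundary = first voxel row of the deeper structure; integer boundaries
  against continuous truth therefore differ by up to 1 px plus 0.5 px of
  flatten rounding — the recovery tolerance used everywhere is one
  axial pixel (2 µm) on annular means.
* Gradient normalization of a constant image is defined as 0.5
  everywhere (every edge costs `1 + w_min`; the path degenerates to the
  geometric shortest, placed at the band top by the tie-break).
* Path ties break toward smaller depth, deterministically.
* A subregion SNR with an exactly zero noise floor is `Inf` (included);
  a tile with no vessel or no background pixels is excluded and flagged.
* Empty ROIs (annulus outside the field, no included area) are classed
  errors (`EmptyROI`), not NaN.
* All randomness is seeded through configuration objects; identical
  config + seed reproduces volumes bit for bit.

## Desk-scale problem sizes

Tests and the acceptance script run on reduced grids chosen to keep the
geometry faithful: thickness analyses use 64 x 48 A-lines over the full
1 x 1 mm field (the annulus must fit) with 3 repeats and 280 depth
pixels; angiography uses 4 µm lateral sampling over a ~0.5 x 0.4 mm
field with the protocol's 5 repeats, because capillary-calibre vessels
(8–14 µm) must span multiple pixels for the Frangi bank to be
meaningful, and the ONH exclusion radius scales down (120 µm) with the
field. The full acquisition geometry remains the `phantom_config()`
default. Statistical calibration uses 200-replicate simulations (6-group
null for the family-wise error rate; a 20 µm shift at 10 mice/group for
power).

## Known limitations

* The column-monotone path (±1 row per column) cannot follow the steep
  walls of the ONH depression; boundaries cut the corner there. All
  reported statistics exclude the ONH region.
* Kenward-Roger df are not implemented (see above).
* The TIFF archive stores 32-bit integer samples (the underlying
  library does not write float TIFFs); continuous data round-trips to
  ~2e-10 of the intensity range, integer-valued data exactly. NIfTI
  archives are lossless.
* Automatic ONH localization (centroid of the inner-layer pinch) is a
  fallback only; the intended workflow uses the manual annotation
  carried in the volume metadata.
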