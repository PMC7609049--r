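---
title: "Quantifying whole-mount 3D organoids: models, parameters, and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying whole-mount 3D organoids: models, parameters, and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(organoidhcs)
```

## The analysis problem

Whole-mount-stained, optically cleared 3D organoids can be imaged intact on
a confocal high-content imager as multi-channel z-stacks, one aggregate per
well of a 96-well plate. Turning those stacks into per-well, per-marker,
per-subpopulation numbers requires four stages, each of which this package
implements as an explicit, testable function:

1. **Sample identification** — find the aggregate region on every confocal
   plane and reject contaminated or badly positioned wells
   (`detect_aggregate()`, `qc_classify()`).
2. **Background correction** — remove the non-uniform haze that large
   spherical samples retain even after clearing (`subtract_blur()`,
   `gaussian_highpass()`, `sliding_parabola()`).
3. **Segmentation** — detect nuclei or cell somata inside the aggregate and
   gate them by area/brightness windows (`find_nuclei()`, `find_cells()`,
   `apply_gate()`).
4. **Data reporting** — sum counts and brightness over all planes and
   fields per well, and derive plate-level analytics
   (`quantify_nuclear_marker()`, `quantify_filamentous_marker()`,
   `dilution_linearity()`, `edge_effect_report()`, `batch_cv()`).

Functional readouts (calcium spike trains and synchrony, field-potential
oscillation metrics and spectra) complete the screening toolbox.

Because no public image data accompany this kind of assay, the package
ships a synthetic-data generator with full ground truth. Every claim the
test suite makes about recall, linearity, or effect recovery is made
against planted truth, not against curated example images.

## Aggregate detection

Detection operates on the **sum of all channels** (wider dynamic range, no
dependence on any single marker's spatial pattern), median-smoothed, then
thresholded — Otsu by default, because an absolute threshold would tie the
package to one instrument's gain; an absolute override exists. The binary
mask is cleaned by dilation (10 px) then erosion (3 px). The asymmetry is
kept deliberately, so the final mask is grown by roughly 7 px relative to
the thresholded region; this matches the described screening procedure and
gives segmentation a margin at the aggregate boundary. Candidate regions
must exceed 4000 µm² and 300 abu; the brightness gate applies to the
region *mean* (the convention is ambiguous in screening software; a
`brightness_measure = "total"` switch is provided). When several regions
pass on one plane, the largest is kept and the plane flagged — the
workflow assumes one aggregate per well.

QC rejects wells for `dust` (compact bright object off the aggregate),
`fiber` (roundness < 0.2 and length above 50 µm), `incomplete` (mask
touching the field border), or `missing`. The artifact intensity threshold
defaults to 1.5× the brightest tissue pixel inside any detected aggregate
region of the stack; artifacts of interest out-shine stained tissue, and
deriving the reference from all planes keeps it valid on planes where the
artifact itself defeats aggregate detection.

## Background correction

Two families are provided. The Gaussian high-pass subtracts a blurred copy
of the plane from itself (channel conventions: 10 px for soma-scale
markers, 5 px for finer filamentous markers) and clips at zero. The
sliding parabola computes a grayscale **opening with a paraboloid
structuring element** of height profile $\kappa r^2$ and subtracts it; the
opening is anti-extensive, so the corrected image is bounded by
$0 \le \text{out} \le \text{raw}$ pointwise — an exact property the tests
assert, not an approximation.

The opening is computed separably: a 1-D min-plus transform (the lower
envelope of a parabola family, computed in $O(n)$ per line) along columns
then rows gives the erosion, and its max-plus adjoint the dilation. This
is exactly the 2-D operation, because the paraboloid is additively
separable across axes; the test suite verifies equality against a
brute-force 2-D structuring-element oracle on random grids to $10^{-12}$.

Screening software exposes this step as a dimensionless "curvature"
setting. We map setting $c$ to $\kappa = c/1000\ \mathrm{abu/px^2}$ and
expose $\kappa$ directly as an advanced option. Numeric equivalence with
any proprietary implementation is **not** claimed — only the role of the
step. Two consequences of the morphology deserve emphasis:

* A *sharper* paraboloid (higher curvature) tracks the intensity surface
  more closely, so the corrected residual is pointwise **non-increasing**
  in curvature. High curvature settings therefore suppress background
  harder, which is exactly how the setting is used in practice (2 for a
  bright nuclear marker, 10 to squeeze extra background out of dim
  channels).
* The curvature that separates "background" from "feature" depends on the
  spatial scale of the data. At the full instrument scale (aggregates
  spanning ~500 px) a setting of 2 isolates nuclei; at this package's
  scaled-down synthetic geometry (aggregate radius ~60 px) the equivalent
  role requires a much sharper element, and the validation suite uses a
  setting of 500 ($\kappa = 0.5$). This is analysis configuration, not a
  model parameter: every high-content experiment tunes these settings to
  its optics.

## Segmentation and gating

Nucleus/cell detection is a Laplacian-of-Gaussian (difference-of-Gaussians)
seed detector at the expected object scale (nuclei 7 µm, somata 12 µm by
default), followed by marker-controlled region growing on the corrected
intensity, clipped to the aggregate mask. Two policy details matter:

* Objects are clipped to a radius of 1.25× the expected diameter around
  their seed. Without the cap, a lone seed in a sparse plane floods any
  connected low-intensity area and its measured brightness stops tracking
  cell content — the failure mode is invisible at high density and severe
  at low density, precisely where dose-response floors are measured.
* For channels corrected by blur subtraction, the subtraction leaves a
  bright transient just inside the sample boundary. `mask_erode_px`
  excludes a border zone of that width from segmentation; the exclusion is
  uniform across doses, so normalized readouts are unaffected.

Object brightness is the **sum of raw-channel intensities over the
footprint** (per-well reporting sums object counts and total brightness);
the corrected image is used for detection only. Gates are strict
inequalities — an object must be strictly larger and strictly brighter
than the lower bounds, and strictly below any upper cap:
`gate_preset()` ships the standard windows (Sox2 10–70 µm² and
1200–6000 abu; TH/Map2 cells 25 µm² and 200 abu; cCasp3 11–100 µm² and
2700 abu). The upper caps are not cosmetic — they reject fused/overlapping
nuclei and small bright artifacts, and the tests verify that a deliberately
fused pair of planted nuclei is rejected by exactly those caps.

## The synthetic-data generator

`generate_organoid_stack()` renders a spherical aggregate with:

* **Nuclei** as Gaussian blobs (radius 3 ± 0.3 µm), placed by
  dart-throwing. Nucleus centres snap axially to the nearest confocal
  plane (`snap_to_planes = TRUE`), reflecting that each optical section
  resolves a thin slab; the minimum-separation constraint (1.5× nucleus
  radius) is then enforced *within* each plane, which is what "resolvable
  blobs" means for a per-plane counting convention. Lower separation
  factors deliberately create overlapping nuclei for stress tests.
* **Marker identity** per nucleus from concentric-zone probabilities
  (`zone_fractions`, core → surface) or a uniform `labeled_fraction`
  (dilution series; realized counts are Bernoulli/binomial and recorded in
  the ground truth).
* **Diffuse tissue signal** (300 abu) inside each cross-section: stained
  tissue is a coherent bright region, which is what makes summed-channel
  Otsu detection and the 300-abu region gate meaningful. Sparse
  nuclear-marker channels receive only 15% of it (nonspecific antibody
  background); abundant cell-body stains receive all of it.
* **Haze** — a smooth dome plus a correlated random field — and
  **depth attenuation** $e^{-\alpha\,\mathrm{depth}}$ with
  $\alpha = 0.0015/\mu m$ (half-intensity ≈ 460 µm, a residual effect
  consistent with well-cleared tissue), and Gaussian sensor noise
  (sd 7 abu).
* **Artifacts** on demand: `plant_dust()` (compact, 3× brighter than
  tissue) and `plant_fiber()` (long thin streak) as QC positive controls.

The functional generators plant periodic synchronized calcium events
(instant rise, 2 s exponential decay; events at $(k-\tfrac12)T$ so a
240 s recording at a 30 s period holds exactly 8) and phase-locked
multi-tone field potentials.

What the generator does **not** emulate: realistic point-spread functions
(blobs are isotropic Gaussians), light scattering, chromatic aberration,
nucleus shape variability, spatially structured marker co-expression, or
stitching artifacts between fields. Passing tests therefore demonstrate
that the *analysis logic* is correct and self-consistent on data matching
its assumptions — they do not certify performance on any particular
microscope.

## Study conditions used by the validation suite

A full-scale screen of this kind images 100k–200k-cell aggregates as
16-plane stacks. The validation suite reproduces the *designs* at a scale
a desktop test run can afford, chosen once:

* **Dilution series**: labeled fractions 1.25–40% in 6 steps, 3
  replicates, two aggregate sizes of ≈1000 nuclei (radius 60 µm) and
  ≈2000 nuclei (radius 75 µm, mirroring the cube-root size scaling of the
  full-scale design), 6 planes, 160–192 px fields. The linearity statistic
  regresses per-fraction replicate means of summed tracker brightness on
  the fraction (dilution results are conventionally summarized as mean ± SEM
  per fraction);
  R² ≥ 0.99 must hold for both sizes. At 1000–2000 cells the binomial
  noise of the realized label counts is the dominant error term — the
  full-scale experiment enjoys a 100-fold larger cell count there.
* **Toxin plate**: doses 0/50/100/250/500 µM, a 4-parameter-logistic kill
  curve on TH (EC50 100, Hill 1.5, max kill 0.9) with Map2 spared, 100
  cells per marker at radius 55 µm. Analysis: channel-specific Gaussian
  high-pass (10 px TH, 5 px Map2), soma-scale segmentation, area
  normalization, then normalization to the dose-0 mean.
* **Edge effect**: 10 edge + 10 inside wells with a planted 10% reduction
  of all rendered signal in inside wells; the null calibration re-runs 20
  unplanted plates. The bootstrap interval is the normal-approximation
  form with a Student-t quantile and small-sample variance inflation;
  straight percentile intervals measurably under-cover (≈85%) at 8–16
  wells per class.

## Numerical and statistical choices

* **Spike detection** thresholds are centred on the *median* of
  ΔF/F₀ (the rolling 10th-percentile baseline biases ΔF/F₀ positive) at
  5 MADs; a 3-MAD (≈3σ) threshold would produce ~3 false events per
  pure-noise 240 s/10 Hz trace (2400 samples × 1.3·10⁻³). Events are
  delimited with hysteresis (runs above half-threshold containing a
  supra-threshold sample) and merged within a 5 s refractory window —
  aggregate-wide calcium events decay over seconds, so the refractory
  must exceed the event width.
* **Savitzky–Golay** smoothing uses the conventional window of 50 samples
  adjusted to 51 (the filter needs a centre point) and polynomial order 3.
* **Spectra** are Blackman-windowed, mean-removed, one-sided power
  spectra. A "dominant peak" is a local maximum within ±4 bins exceeding
  20× the median spectral power: for white noise the periodogram
  ordinates are exponential, making a 20×-median excursion vanishingly
  rare, while a planted tone concentrates orders of magnitude above it.
* **4PL fits** run bounded (bottom ≥ 0, top ≤ 1.5) multi-start
  Levenberg–Marquardt in log-dose, with dose 0 at a pseudo-log position
  one decade below the lowest non-zero dose. Non-convergence is reported,
  never thrown; a fitted dynamic range < 0.1 flags a degenerate (flat)
  series.
* **Degenerate inputs**: constant planes produce empty detections rather
  than errors; zero-variance traces produce empty spike trains; a zero
  control mean, zero DAPI count, or constant brightfield image is a
  reported error.

## Known limitations

* Per-plane counting means a nucleus spanning two optical sections counts
  on each; totals are section counts, not deconvolved cell numbers. The
  generator's plane snapping mirrors this convention.
* The LoG/watershed segmentation degrades when centre-to-centre distances
  fall below roughly twice the detection scale; the generator can create
  such data (lower `min_separation_factor`), and the gates' upper caps are
  then the only defence, exactly as in full-scale screening practice.
* The "find nuclei"/"find cells" algorithms of commercial high-content
  software are proprietary; equivalence with them is claimed at the level
  of gated counts on well-separated objects, never pixel masks.
* The edge-effect interval is calibrated for ≥5 wells per class; below
  that, no bootstrap is trustworthy.

## A short worked example

```{r example, eval = FALSE}
# render a small labeled-cell aggregate and quantify the tracker channel
ph <- organoid_phenotype(radius_um = 60, n_nuclei = 1000,
                         labeled_fraction = 0.2)
g <- generate_organoid_stack(
  ph, channels = list(channel_spec("DAPI", "nuclear"),
                      channel_spec("tracker", "nuclear-marker")),
  planes = 6, rows = 160, cols = 160, seed = 1)
s <- quantify_nuclear_marker(
  g$stack, "tracker", gate = gate_spec(5, NULL, 2500, NULL),
  background = list(method = "parabola", curvature = 500),
  seg_params = list(expected_diameter_um = 4, detection_threshold = 30))
s$n_objects          # detected tracker+ nuclei, all planes
sum(g$truth$tracker) # planted ground truth
```
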