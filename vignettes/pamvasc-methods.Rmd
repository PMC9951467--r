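---
title: "Quantifying layered skin vasculature in OR-PAM volumes: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying layered skin vasculature in OR-PAM volumes: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4)
library(pamvasc)
library(dplyr)
```

## The measurement problem

Optical-resolution photoacoustic microscopy (OR-PAM) images hemoglobin
directly, so a volumetric scan of skin is, to good approximation, a map of
the blood vessels. That makes it a natural instrument for watching
vasoconstriction happen — for example the capillary constriction induced by
topical or injected corticosteroids, which clinically is only graded
indirectly through skin blanching. The quantitative questions are:

* how much does vascular density drop over an hour of monitoring, and
* in *which* anatomical layer — the papillary dermis (PD, the dense
  sub-epidermal capillary plexus), the reticular dermis (RD, sparse
  near-vertical connector vessels), or the hypodermis (HD, large paired
  arterioles and venules)?

`pamvasc` implements the full analysis chain for such studies: skin-surface
detection and flattening, depth-histogram layer segmentation, layer-wise
maximum-amplitude projections (MAPs), averaged-Otsu density quantification
over a timepoint series, depth-centroid tracking, and group statistics.
Because in vivo volumes of this kind are rarely shareable, the package also
ships a synthetic skin-vasculature phantom whose analytic ground truth
drives every validation in the test suite.

## The pipeline

A subject contributes seven volumes, one per 10-minute timepoint over an
hour. For each series the pipeline:

1. **Detects the skin surface** of every volume: per A-line, the shallowest
   depth where the amplitude reaches a fraction (default 0.5) of that
   A-line's maximum. A-lines below a global noise floor (default 20% of
   the volume maximum) are filled from neighbours; detections far deeper
   than the robust field median (beyond 3.5 scaled MADs) are rejected the
   same way, because on an A-line with no shallow signal the first strong
   absorber is a deep vessel, not the surface. The field is then smoothed
   with an 11 x 11 median filter, which also suppresses heartbeat- and
   respiration-like row artifacts.
2. **Flattens** each volume by shifting every A-line (linear interpolation;
   the 3 um axial sampling is fine relative to the 30 um axial PSF, so
   linear is adequate) so that depth means depth below the skin surface.
3. **Segments the layers once per subject** from the t = 0 volume: the
   depth histogram counts voxels above a global Otsu threshold per depth;
   after smoothing with a moving average one axial PSF width wide, its two
   most prominent interior maxima (at least 100 um apart) mark the
   papillary and hypodermal plexuses. Boundaries are placed at the
   least-count depths between each peak and their midpoint ("valleys", the
   default) or at the peaks themselves ("peaks"). The boundaries are
   reused for all seven timepoints: constriction itself reshapes the
   histogram, and re-segmenting each timepoint would fold segmentation
   drift into the density measurement. (Both choices are configurable.)
4. **Projects layer MAPs** — the pixelwise maximum over each layer's depth
   slab — for PD, RD, HD, and the whole sub-epidermal depth range. The
   shallowest 30 um (one axial PSF width, configurable) are excluded from
   every slab: the epidermis is avascular and carries the surface signal.
5. **Binarises with the averaged-Otsu scheme**: the seven MAPs of one
   layer series view the same location, so one threshold — the arithmetic
   mean of the seven per-image Otsu thresholds (256 bins over each image's
   own range) — is applied to all of them. Vascular density is the count
   of pixels *strictly greater* than that threshold; relative density
   normalises by t = 0, and the constriction percentage is
   `100 * (1 - relative)` at the final timepoint.
6. **Tracks the depth centroid** of the suprathreshold voxels of each
   flattened volume (unweighted by default; amplitude weighting is a
   flag). Capillary-dominated constriction moves the centroid deeper.
7. **Summarises groups**: pointwise means and standard errors (sample SD
   over sqrt(n)) of relative density, final constriction mean +/- SEM, and
   two-tailed paired t-tests over a configurable comparison list. Pairing
   by subject index is used even between groups, following the analysis
   convention of the motivating study design; an unpaired Welch test is
   available via `compare_constriction(method = "welch")`. No
   multiple-testing correction is applied by default (a Bonferroni option
   exists); p-value bands are reported as p < 0.05 and p < 0.005.

### Why "valleys" is the default boundary rule

The literal reading of peaks-as-boundaries places the PD/RD boundary *at*
the papillary peak. But the peak sits at the mode of the capillary centre
depths, so about half of every papillary vessel's cross-section falls below
it and is attributed to the reticular slab, which otherwise contains little
vasculature. Any layer-selective signal then bleeds between layers. The
valley rule places boundaries in the low-occupancy zones between the
plexuses, which is where the anatomical transitions are; with it, layer
attribution of the phantom's tagged vessels is essentially exact. The peaks
rule remains available (`layers$boundary_rule = "peaks"`).

## The phantom

`phantom_spec()` parameterises the generator. The default grid is
200 x 200 x 300 voxels at (5, 10, 3) um — a 1.0 x 2.0 x 0.9 mm field, a
desk-scale stand-in for a full 4 x 6 x 3 mm acquisition at the same
spacing (which the same code renders if asked). Components:

* **Surface**: a Gaussian random field (white noise smoothed at half the
  requested correlation length, rescaled to the requested amplitude) with
  mean depth 50 um, undulation 25 um, correlation length 500 um, mimicking
  the unsmooth profile that breathing and heartbeat leave in a real scan.
  A thin (9 um) bright sheet at the surface plays the epidermis /
  coupling-interface signal. It is what anchors surface detection; without
  it the detected "surface" is the top of the shallowest vessel, which
  destroys the papillary histogram peak (depth counts become a monotone
  survival curve from depth zero) and drifts as the plexus constricts.
* **Papillary plexus**: 10 meandering near-horizontal capillary tubes,
  radius 38-48 um, centred 100 um below the surface.
* **Reticular connectors**: 20 near-vertical tubes, radius 20-30 um, with
  about 150 um of lateral wander, spanning the zone between the plexuses
  and stopping short of both (where real communicating vessels anastomose
  into the plexuses).
* **Hypodermal pairs**: 2 arteriole-venule pairs, radius 40-60 um, running
  the length of the field 500 um below the surface.
* **Optics and noise**: anisotropic Gaussian PSF with 5 um lateral and
  30 um axial FWHM; additive Gaussian noise (sd 0.02 of the unit vessel
  amplitude) clipped at zero. Optional per-B-scan surface jitter
  (`motion_jitter_um`, off by default) mimics heartbeat/respiration
  displacement between successive B-scans.
* **Constriction**: per-layer schedules scale vessel radii by
  `1 - c_max * (1 - exp(-t / tau))` (saturating exponential, tau = 20 min;
  a linear ramp is available). Radius scaling preserves topology, which is
  why it is the default mechanism. Four presets mirror a four-arm steroid
  experiment: *injection* constricts RD only; *topical* constricts
  PD > RD > HD; *nonsteroid* and *control* do nothing.

On vessel sizes: real papillary capillaries are below the 30 um axial PSF.
For a vessel much thinner than the PSF, constriction dims the rendered
amplitude more than it narrows the footprint, and any threshold-based
density measure then *overestimates* the geometric loss — an intrinsic
property of resolution-limited binarised densitometry, present in real
data too. The phantom is deliberately parameterised in the resolvable
regime (tube diameters at or above the axial PSF) so that measured density
loss is attributable to geometry and can be validated against the analytic
oracle to within a few percentage points. Passing tests therefore certify
the pipeline's bookkeeping and its behaviour on resolvable vasculature;
they do not certify absolute density accuracy for sub-resolution
capillaries, where the measured loss should be read as a sensitive but
biased index of the true geometric loss.

The preset magnitudes are calibrated so that the *measured* group means
land near the published in vivo arm means (topical PD/RD/HD about
56/45/24%, injection RD about 50%) — the published values are themselves
outputs of this measurement procedure, so calibrating the measured output
(rather than the geometric input) is the faithful choice.

### Ground truth

Each simulated subject carries its analytic oracle: the projected area
fraction of every layer's tubes on the lateral plane, computed from tube
geometry alone. The default evaluator rasterises the union of footprints
on a supersampled grid (cells at most 2.5 um), so overlapping vessels are
not double counted; a closed-form variant (`method = "rect"`, sum of
`2 r L + pi r^2`) ignores overlap and is exactly linear in the radius for
a lone tube. Oracle traces are constant without schedules and strictly
decreasing wherever a schedule acts.

## Numerical choices and degenerate inputs

* Otsu uses 256 bins over each image's own `[min, max]`; ties break toward
  the lower threshold; a constant image raises a degenerate-image error
  rather than returning an arbitrary cut. The implementation is verified
  against an exhaustive between-class-variance scan.
* Density comparisons are strict (`>`), so a threshold equal to the image
  maximum yields density zero.
* Histograms and thresholds are derived from the data, never absolute, so
  globally rescaling amplitudes changes no trace (thresholds scale along).
* Fewer than two admissible histogram peaks, an empty reticular slab, a
  zero baseline density, zero-variance differences in a paired test, and
  a volume with no detectable surface are all explicit, classed errors.
* Per-subject seeds derive deterministically from the master seed, and
  noise seeds from the subject seed and timepoint, so studies are
  bit-reproducible end to end.
* TIFF export stores 16-bit fractions of a recorded maximum with a JSON
  sidecar; quantification always runs on the raw volumes, never on
  display-scaled exports (PNG export is 8-bit, display-only, with its
  scaling recorded in a sidecar).

## Problem sizes used in validation

The shipped validation suite exercises: the full four-arm design (4 groups
x 6 subjects x 7 timepoints) at the default 200 x 200 x 300 grid for
oracle-agreement checks; twenty independent phantoms (noiseless and at
default noise) for peak-recovery checks; and twenty master-seed preset
studies on a reduced phantom (100 x 100 x 250 voxels, half lateral field,
proportionally fewer vessels, one subject per arm) for the qualitative
layer-selectivity pattern. These sizes are the package's own choice of a
balanced validation design: large enough that group means stabilise,
small enough to re-run routinely.

## What the phantom does not emulate

Physically accurate photoacoustic wave propagation and fluence decay with
depth, limited-view suppression of vertical vessels (the phantom's
connectors render at full amplitude; in vivo they are notoriously faint),
oxygen-saturation contrast, motion between timepoints, and sub-resolution
capillary beds. Results on the phantom certify the analysis chain, not the
instrument physics.

## A worked example

```{r example, eval = FALSE}
# a reduced two-arm study, one subject per arm (seconds, not minutes)
st <- run_study(small_phantom_spec(),
                groups = steroid_presets()[c("injection", "control")],
                n_subjects = 2, seed = 1)
st$constriction_summary
autoplot(st)
compare_constriction(st,
  list(list(type = "between", layer = "RD", a = "injection", b = "control")))
```

The full-size run (`phantom_spec()`, all four presets, six subjects) takes
on the order of ten minutes on one CPU and is what the acceptance script
reproduces.
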