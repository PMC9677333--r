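---
title: "Models and methods behind protonrad"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind protonrad}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protonrad)
```

`protonrad` implements the computational chain of an image-guided
small-animal proton irradiation workflow built around a flat-panel detector:
proton radiographs are formed from raw detector frames, quality-scored,
registered to a 2D treatment plan through manually placed landmarks, turned
into motor-stage coordinates, verified by a daily QA phantom, and finally
related to biology through DAPI/γH2AX damage maps overlaid on a dose
distribution. This vignette explains the models, the tunable parameters, the
synthetic-data generator that stands in for beamline and microscope data, and
the numerical choices that were genuinely open.

## Radiograph formation and quality metrics

Raw frames are corrected in two independent steps: the detector dark pattern
`I_dark` is the pixelwise mean of a dark stack, and the beam-fluence
background `I_beam` is the mean of a beam-only stack *after* `I_dark` has
been removed from it. Each raw frame then becomes
`frame − I_dark − I_beam`, and frames are combined by the per-pixel median
(`stack_median()`), which absorbs up to `floor((n − 1)/2)` salt-and-pepper
impulses per pixel without any output change. For an even frame count the
median is the mean of the two central order statistics.

Quality metrics follow the usual definitions, with the standard-deviation
convention fixed to the population form (divide by *N*):

* `SNR = S / σ` of one region;
* `CNR = (S_a − S_b) / σ_b`, signed, with the noise taken from the
  low-contrast (background) region — the defining formula leaves the σ
  assignment open, and fixing it to the background makes CNR estimates
  comparable across feature sizes.

Detector bookkeeping is linear: `acquisition_time = n_frames / frame_rate`
(default 8.4 Hz) and `dose = time × dose_rate`, where the dose rate is a
geometry-specific calibration constant carried in the run config (1.98 mGy/s
for the grid-phantom geometry, 2.875 mGy/s at the mouse position). The two
calibrations are not mutually derivable, so they are config entries, never
hard-coded.

### Edge enhancement and its width

Proton radiography at shoot-through energies draws its contrast from
scattering: fluence is depleted inside dense material and enhanced just
outside its boundary. `edge_fwhm()` quantifies the enhancement peak by
averaging at least 20 profile lines perpendicular to the edge, estimating the
far-field plateau, and returning the full width at half maximum of the peak
above that plateau with subpixel linear-interpolated crossings. Two numerical
details matter:

* the crude localisation pass uses the profile *median* as baseline, because
  the profile also contains the in-material valley and the global minimum
  would misplace the far field;
* the peak height is refined by the vertex of a parabola through the three
  top samples before the half level is set. A peak almost never sits exactly
  on a sample; without the refinement the sampled maximum underestimates the
  height and biases the FWHM upward by about 2.5% at σ = 2 px, which is
  outside the estimator's 2% recovery target. With it, synthetic Gaussian
  enhancements with σ between 2 and 10 px are recovered within 2% of
  `2.3548 σ`.

A peak must exceed the plateau by more than three times the far-field noise,
otherwise the function raises a "no edge enhancement" error — a perfectly
sharp edge has no peak to measure.

### Line pairs and detectability

`line_pair_resolution()` folds the bar-group profile at its known period
(phase averaging) and scores the Michelson contrast `(max − min)/(max +
min)`. A group is resolved when its contrast exceeds 0.1 *and* three times
the contrast of the background region; the threshold pair is a package
convention, chosen because the source material reports outcomes, not
criteria. `detectability_vs_frames()` median-stacks the first `n` frames for
growing `n` and flags a feature detectable when its CNR exceeds 4 — the Rose
criterion, standing in for "clearly recognisable". Note that the CNR gain
from stacking is capped by the noise of the background-correction images
themselves; the imaging workflow records 300 dark and beam frames for
exactly this reason, and the package's √n behaviour is tested under that
condition.

## The synthetic beamline (what it emulates, what it does not)

All tests run on synthetic data with known ground truth; no beamline or
microscope data are required. The generator emulates the *structure* of the
measurement, not its physics:

* **Transmission model.** A phantom is painted as an areal-density map
  (relative stopping power × thickness). The scattered fraction
  `s = 1 − exp(−k·RSP·t)` (k = 0.05 per RSP·mm, a generator convention) is
  removed locally and returned as a broad Gaussian halo (σ = 1 mm), so the
  canvas-mean fluence is conserved exactly — the convolutions are circular.
  Material boundaries additionally receive a difference-of-Gaussians
  redistribution `a·(G_{σ2} − G_{σ1})(s)` with `σ1 = σ2/2`, producing the
  valley-inside/peak-outside signature. The widths are calibrated through
  the analytic FWHM constant of that bump shape (1.1685·σ2) so that the
  peak FWHM grows by 0.08 mm from the 200 MeV preset (0.30 mm) to the
  150 MeV preset (0.38 mm). Because the convolutions are periodic, phantom
  layouts keep material away from the canvas border.
* **Detector.** Counts are `gain × beam_profile × transmission + dark
  pattern`, with optional per-pixel Poisson noise and salt-and-pepper
  corruption; companion dark-only and beam-only stacks use the same
  conventions. Every render is a pure function of (parameters, seed) and
  bit-identical on repetition. The acquisition defaults are *not* tuned to
  reproduce any measured detectability curve — those curves are empirical
  properties of a particular detector and beam.
* **Phantoms.** The hole-grid phantom carries 7 groups of 3 × 3 circular
  air holes from 1.2 mm down to 0.3 mm diameter (spacing 2.5 diameters, a
  documented convention); the lead grid carries bar groups from 0.6 to
  6.0 lp/mm with bar and gap each half a period.
* **Mouse pair.** A procedural skull-like plan image (nested ellipses,
  sutures, five high-contrast landmarks, an embedded hippocampus-shaped
  label) is warped through a known similarity transform and rendered through
  the detector model. True landmark positions in both frames are emitted, so
  registration error can be scored exactly.
* **Depth dose.** A deliberately non-physical stand-in: range from the power
  law `R = 0.022·E^1.77` mm (R(90 MeV) ≈ 63.5 mm), an entrance plateau with
  erfc roll-off plus a Gaussian Bragg peak at the residual range
  `R − WET`, and a lateral top-hat with Gaussian penumbra, normalised to
  the prescribed peak dose. It is labelled a stand-in and should not be used
  beyond benchmarking the damage pipeline. The WET itself is physical:
  Bethe stopping powers with standard compound constants (water
  Z/A = 0.55509, I = 75 eV; polycarbonate Z/A = 0.52697, I = 73.1 eV,
  ρ = 1.20 g/cm³) give 53.16 mm for the 46.51 mm polycarbonate shifter at
  90 MeV.
* **Nuclei.** DAPI nuclei are Gaussian blobs placed by minimum-distance
  rejection sampling; each is damaged with probability
  `p(D) = p_bg + (p_max − p_bg)·D/(D + D50)`. The saturating hyperbola is a
  documented emulation device — the biology shows a correlation, not a
  functional form. Per-tile truth counts are assigned by the nucleus's
  rounded pixel position, the raster a maxima detector sees.

Passing tests on these data therefore demonstrate the correctness of the
*algorithms* (correction, counting, registration, statistics), not the
physical fidelity of any image-formation model.

## Plans and observer agreement

Treatment plans are 2D label images (0 background, 1 brain, 2 hippocampal
region) obtained from maximum-intensity projections over 15–25 sagittal
slices; label projection gives the hippocampus priority (2 > 1 > 0).
Agreement is quantified by the Jaccard coefficient of the target masks
against the majority vote of the observers: `J_i = |A_i ∩ F| / |A_i ∪ F|`,
`F = majority(A_1 … A_n)` with an odd observer count. Two open points were
fixed as package conventions: an empty union scores J = 1 (two empty
contours agree perfectly), and the intra-observer reference is the majority
of that observer's own repeats, mirroring the inter-observer formula.
Summary rows report mean ± population standard deviation, matching small-n
reporting practice.

## Registration, stage coordinates and QA

The plan-to-radiograph mapping is the isocentric similarity transform
`q = s·R(θ)·p + t` without reflection. The least-squares fit is closed-form:
both landmark sets are centred, and the complex cross-covariance
`Σ q̃ conj(p̃) / Σ|p̃|²` yields scale and angle at once — reflections are
excluded by construction and recovery on consistent pairs is exact for any
n ≥ 2. Fitted objects support `tidy()` and `glance()`.

The beam isocenter is the intensity-weighted centroid of the largest
connected component above an Otsu threshold of the min–max-normalised
collimator radiograph, which makes it invariant to global intensity scaling;
quality flags mark border-touching components and circularity
(`area/(π r_max²)`) below 0.8. Stage coordinates are
`(x, y) = M·(Δrow, Δcol)·pitch` with `M` a named, registered axis-convention
matrix — hardware-specific, never inferred. Observer spread of targets is
reported as mean distance to the centroid ± population sd, a documented
choice where the reporting convention was unstated.

Daily QA segments the dark irradiated spot on the film (Otsu), then the
bright ball shadow enclosed by it (a bright component not touching the film
border), and passes when both centres are within tolerance (default 0.5 mm)
of the expected position.

## Damage maps and dose correlation

`find_maxima()` implements prominence-thresholded maxima detection with
fully specified semantics: 8-connectivity, strict comparisons, one
representative per plateau (rounded centroid), deterministic ordering. A
candidate is rejected exactly when a path to a strictly higher pixel exists
that never descends more than the threshold below it; the implementation is
a union-find flood over descending levels (in C++), and the test suite pins
it, point for point, to an exhaustive path-search oracle on hundreds of
random images. Two consequences of the rule are worth stating: the global
maximum can never be rejected (it has no higher ground; it is reported with
infinite prominence), and a constant image has no maxima at all.

`damage_map()` counts DAPI maxima (prominence 600) and γH2AX maxima
(prominence 1400) over the whole image, bins them into 256 px tiles, clips
`n_damage` to `n_dapi` so the ratio is a damaged-cell fraction, and flags
tiles with fewer than 5 nuclei invalid — the count statistic is unstable at
very low cell density. Edge tiles are processed and flagged rather than
discarded, preserving beam-edge information. `align_to_dose()` resamples the
tile field into dose-grid coordinates through a user-supplied affine
(nearest tile), and `profile_correlation()` averages dose and damage per
along-beam bin (invalid tiles excluded) and reports Pearson's r.

## Problem sizes and numerical conventions

The simulation-based checks use deliberately compact problem sizes, chosen
as the smallest configurations that still separate signal from noise
cleanly: the end-to-end dose–damage check runs one 256 × 2048 px microscopy
pair (64 px tiles, 32 profile bins) for the correlated case and one hundred
128 × 2048 px pairs for the dose-independent null. At 32 bins the null
distribution of Pearson's r gives |r| < 0.4 with probability ≈ 0.975 per
seed, so the 95%-of-seeds requirement is met with margin; at 20 bins the
same probability is only ≈ 0.92, which is why the bin count is part of the
stated design. Transform-recovery statistics use 1000 seeded trials with
five landmarks and 1 px noise.

Conventions used throughout: pixel coordinates are 0-based `(row, col)` with
rows increasing downward; physical lengths are mm via the pitch
(0.05 mm/px detector, 0.325 µm/px microscope); slice indices into R arrays
are 1-based; all randomness flows through explicit seeds.

## Known limitations

* The transmission, detector and nuclei models are structural emulations;
  none of them claims physical accuracy, and the analytic depth-dose curve
  is explicitly a stand-in for a Monte Carlo dose engine.
* Atlas registration (the step that produces plan label images from a brain
  atlas) and deformable histology-to-volume registration are out of scope;
  plans and damage-to-dose affines enter as user-supplied inputs.
* The maxima counter shares the known weaknesses of its family: it
  over-counts in very sparse regions (the global maximum is always reported)
  and under-counts merged nuclei in dense clusters; the `min_cells` tile
  flag mitigates but does not remove this.
* Beam-range (depth) verification is not attempted — radiography at
  shoot-through energies constrains lateral position only.
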