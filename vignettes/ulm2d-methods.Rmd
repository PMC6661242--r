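---
title: "ulm2d: models, parameters, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ulm2d: models, parameters, and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ulm2d)
```

`ulm2d` implements a super-resolution pipeline for low-frame-rate 2D
contrast-enhanced ultrasound (CEUS), together with the synthetic
vessel-network simulator and evaluation machinery needed to benchmark it
without real recordings. This vignette is the package's own account of the
science: the models, their assumptions, the parameters that matter, and the
design decisions taken where the problem left genuine freedom.

## 1. The imaging model

A microbubble (2–3 μm) is far smaller than the transmit wavelength
(λ = 1540 m/s ÷ 3 MHz ≈ 514 μm) and images as one point-spread-function
(PSF) shaped echo. In focused clinical CEUS the PSF varies across the image,
so echoes are modeled empirically as anisotropic 2D Gaussians with variable
size, elongation (aspect ratio up to 2.5), orientation, and peak intensity.
The pixel pitch is 132 μm, so a typical echo covers 5–35 pixels.

Two echoes closer than three quarters of a wavelength
(`merge_threshold_um()` = 385 μm) coalesce into one image event. The
pipeline embraces this: merged events are detected and localized as single
events whose centroid is assumed to lie inside the common vessel — this is
what lets short loops at high microbubble density still map large vessels.

## 2. The synthetic data generator

`generate_sequence()` produces ground-truthed loops from a `synth_config()`.
Its defaults are the package's reference study conditions.

**Vessel network** (`build_vessel_network()`). The only structural guidance
available is "a grid of interconnecting vessels" spanning 1.1 × 2.2 cm with
diameters 10–500 μm and segment lengths 25 μm–2 mm. The package realizes
this as a jittered rectangular lattice (spacing 1 mm, jitter ±200 μm),
randomly pruned by 25% under a connectivity constraint, with log-uniform
diameters — reproducible for any seed, spanning the stated ranges. Left-edge
nodes are inlets, right-edge nodes outlets.

**Flow** (`solve_flow()`). Each segment obeys Poiseuille's law
`Q = π r⁴ ΔP_seg / (8 μ L)`; nodal pressures follow from mass conservation
(a weighted graph-Laplacian solve; interior net flows vanish to better than
1e-9 of the largest flow). Viscosity defaults to 3.5 mPa·s (blood-like);
since only relative flows steer the particles, the absolute pressure drop
just sets the velocity scale. The default 5 kPa across the network yields
segment mean speeds from tens of μm/s in capillary-sized vessels to ~1 cm/s
in the largest — the physiologic range.

**Advection** (`advect_particles()`). Particles move by the segment *mean*
velocity (the profile-resolved speed is not used, as the flow value is the
stated driver), advancing `v/frame_rate` per frame and choosing outgoing
segments at junctions with probability proportional to outgoing flow. A
fixed random radial offset (≤ radius, redrawn per segment) keeps every
reported position inside the lumen. Particles leaving an outlet are replaced
at an inlet (chosen ∝ inlet inflow) under a fresh identity; the initial
population is seeded along segments ∝ segment volume, the steady state of
inlet injection at uniform concentration, so the loop is statistically
stationary from frame 1. The default 54 in-field bubbles per frame over 200
frames at 10 Hz gives placements at the 10⁴ scale.

**Echo appearance** (`sample_echo_appearance()`). The observed echo-size
histogram is a *detected*-size distribution: pixel areas above the detection
floor, with hard minimum 5 px and quartiles 8/12/20 px. Two calibration
decisions follow:

* *Size law.* A log-normal fitted to the quartiles alone puts the median at
  12.65 px, and truncating it at the 5 px minimum pushes Q1 to ~9.1 px. The
  package instead uses 5 px + a log-normal fitted to the shifted quartiles
  (3, 15), which pins the minimum and both quartiles exactly and puts the
  median at 11.7 px.
* *Floor.* Given a drawn area `A`, aspect ratio ρ and peak `p`, the Gaussian
  sigmas solve `2 log(p/floor) π σ_a σ_b = A · pitch²` with the floor equal
  to the study noise level. Calibrating at half maximum instead would make
  faint echoes too small and bright echoes too large relative to what a
  floor-thresholding detector measures. A consequence worth knowing: at
  fixed area, fainter echoes are physically wider.

Near-minimum draws that would pixelate below 5 px when rendered are redrawn.
Peak intensities are uniform on [0.3, 1] (arbitrary grayscale); elongation
is uniform on [1, 2.5] with uniform orientation.

**Rendering and noise** (`render_frame()`). Gaussians are evaluated at pixel
centers (pixel `(i,j)` center at `((j−0.5)·pitch, (i−0.5)·pitch)`, origin
top-left), summed, and i.i.d. zero-mean Gaussian noise is added with
negatives clipped to zero (log-compressed ultrasound noise is well
approximated as additive Gaussian). The noise sigma defaults to one third of
the faintest echo peak (0.1), i.e. single-echo peak SNRs of 3–10×. The
field of view is padded ~1 mm beyond the network extent so echoes of
boundary vessels render fully — without the pad, clipped edge echoes bias
centroids by roughly one echo sigma.

**What the simulator does *not* emulate.** No beamforming, attenuation,
speckle texture, nonlinear bubble dynamics, spatially varying PSF, tissue
clutter, or out-of-plane motion. Passing tests therefore demonstrate the
*algorithmic* properties of the pipeline (detection completeness,
localization precision, tracking and mapping correctness) under a clean
additive-noise model; they do not certify performance on clinical data,
where PSF variability and clutter dominate.

## 3. Detection

`haar_feature_image()` convolves the frame with center-surround box kernels
(core half-widths 1, 2, 3 px; surround ring out to three core widths),
normalized to zero mean and unit positive mass so responses are in intensity
units, and takes the per-pixel maximum across scales. The significance
threshold is literally the sequence's *average noise level*
(`estimate_noise_sigma()`: the one-sided quantile scale
`(Q75 − median)/z₀.₇₅` over pooled pixels, which recovers sigma exactly for
zero-clipped Gaussian background and is insensitive to sparse bright
echoes). This liberal pixel threshold passes ~1% of pure-noise pixels; the
subsequent area (≥ 5 px) and mean-intensity (≥ noise level) filters act as
the closing noise classifier, which is why pure-noise false events are rare
while echoes barely above noise are still found.

`particle_probability_image()` labels the significance image (8-connected,
implemented in compiled code — the general-purpose image libraries available
label 4-connectivity only) and scores each pixel by the fraction of
significant pixels in a window matched to the component's bounding-box scale
(mean of the two sides, minimum 3 px; using the *max* side starves elongated
components below the region threshold). Initial regions are components of
PPI ≥ 1/e of its maximum; watershed seeds are local maxima of the smoothed
frame inside a region, with the region's brightest pixel as a fallback so no
region is left unseeded.

Granularity knobs: `gaussian_sigma` (default 1 px, matched to the ~1 px echo
core) and `local_maxima_width` (default 3 px ≈ 400 μm, matched to the merge
scale). Larger values deliberately fuse nearby maxima into single merged
detections; smaller values attempt splits.

## 4. Segmentation and localization

`watershed_segment()` floods a relief from the seed markers by priority
flood (8-connected, FIFO tie-break; plateaus resolve to the lexicographically
smallest pixel). Background markers surround the flood domain, which — when
the noise floor is supplied — is the set of pixels whose smoothed intensity
exceeds the floor. Two reliefs:

* *Inverted Gaussian* (`max − smoothed`, the operative choice): echoes are
  basins, the flood recovers the full above-floor footprint before meeting
  the background, and the segmented area tracks the echo's true extent.
* *Gradient magnitude* (the baseline): the relief ridge at the echo's
  steepest slope lets the background flood claim the outer annulus, so
  regions shrink by roughly the ratio of the above-floor to the within-sigma
  area — and small echoes shrink below the 5 px minimum and are eliminated.

`localize()` computes the intensity-weighted center of mass of each region
over the original (not smoothed) intensities, in micrometers. On noiseless
echoes at random sub-pixel offsets this is accurate to ~7 μm RMSE (a
twentieth of a pixel), far below the pitch/5 requirement; localization error
on noisy data is dominated by pixel noise on the region periphery (see §7).

## 5. Tracking and maps

`link_tracks()` associates events in consecutive frames when each is the
other's nearest neighbor within the gate (default 20 mm/s ÷ frame rate,
covering arterial speeds at 10–13 Hz; ties break to the earlier event).
Unmatched events open (birth) or close (death) tracks; deaths beside a
merged-flagged event and births emerging from one are recorded as
parent/child merge/split annotations without changing track identity.
Mutual-nearest-neighbor is deterministic and near-optimal at these
densities; the exhaustive minimum-cost assignment is kept as a test oracle,
not as the implementation.

`render_density_map()`/`render_velocity_map()` rasterize each track's
polyline onto a grid subdivided 3× per pixel (44 μm subpixels — on the scale
of the localization RMSE, which is the criterion for choosing the
subdivision). A track counts at most once per subpixel; velocity subpixels
average the local step speed of the crossing tracks (per an open design
choice, the *local* segment speed is used rather than the track's mean —
both interpretations fit the mapping rule; the local one preserves
intra-vessel velocity gradients). Single-point tracks contribute to neither
map. `measure_fwhm()` samples a profile by bilinear interpolation and
returns the distance between the half-maximum crossings around the global
peak — the vessel-width measure (a Gaussian ridge of sigma σ reads
2.355 σ within 5%).

## 6. Evaluation

`evaluate_run()` collapses per-frame ground truth into scoring events:
merged mode takes each 385 μm single-linkage cluster as one event at the
intensity-weighted mean of its particles (weights: rendered peaks, matching
what the localizer estimates); single mode keeps only well-separated
particles (clusters of one). Detections pair to events greedily,
globally-closest-first, within 385 μm — beyond that distance two echoes are
distinct events by the merge criterion itself, which makes it the natural
pairing radius. Reported: RMSE `√(mean e_t²)`, missed % (unpaired ground
truth), spurious % (unpaired detections), min/max deviation.

## 7. Accuracy regimes of the benchmark

The reference experiment (`reference_config()`, recomputed from scratch by
`scripts/acceptance.R`) runs the merged-mode inverted-Gaussian pipeline on
the default 200-frame loop and scores it against the well-separated single
ground-truth events. Two regimes govern what the numbers can be; both are
measured by the package's own tests, not asserted:

* **Localization is noise-limited.** The centroid of a region whose
  periphery sits at ~1 noise sigma carries variance
  `σ_n² Σ d² / (Σ I)²`. Under the study SNR (peaks 3–10× noise) this floors
  the per-event RMSE near 30 μm even for the brightest echoes and ~40 μm
  overall — noiseless localization is an order of magnitude better, so any
  substantially lower RMSE target presupposes higher echo SNR than these
  study conditions provide.
* **Pairing is geometry-limited.** At ~54 bubbles per frame, roughly a fifth
  of ground-truth events have a neighboring event within 500 μm, and echoes
  of this size physically merge in the image out to ~440–600 μm — beyond the
  385 μm labeling threshold. Such events share one detection, and
  one-to-one vicinity pairing counts the partner as missed regardless of
  detector quality. Missed percentages at this density therefore measure
  echo-overlap geometry as much as detection completeness; at lower density
  (see the README example) missed rates fall accordingly.

The same two regimes invert the relief comparison on one axis: the gradient
baseline misses clearly more events (its shrunken regions fall under the
5 px minimum), but its *paired* RMSE measures slightly lower here, because
truncating the noisy periphery helps the centroid at low SNR. The
area-recovery advantage of the inverted Gaussian — the motivating finding —
is directly visible in the segmentation tests (full footprint vs. strictly
smaller gradient regions) and in the detection counts.

## 8. Numerical choices and degenerate inputs

* Flow solve: dense reduced-Laplacian solve (networks are a few hundred
  nodes); isolated subgraphs without a boundary node abort with the node
  list. Single tubes agree with the closed form to 1e-12 relative.
* Watershed: priority flood with FIFO tie-break; seeds outside the frame are
  contract violations; regions with zero total intensity raise degenerate
  -event errors.
* Registration: translation-only phase correlation with parabolic sub-pixel
  refinement, zero-fill at the borders; flat frames register with a warning
  and zero shift. Rotation is out of scope (breathing motion is in-plane by
  experimental design).
* I/O: 16-bit multi-page TIFF with a JSON sidecar (pitch, rate, intensity
  scale as a full-precision string, so written sequences reload
  bit-exactly); ground truth/events/tracks as CSV. DICOM reading is part of
  the interface but not supported by this build — no DICOM reader is
  available to it; convert loops to TIFF first.
* Zero-duration requests return empty sequences without error; empty frames
  detect zero events; zero pressure drop leaves particles stationary.

## 9. Problem sizes used by the tests

The shipped test suite exercises the full 200-frame reference loop once
(shared across acceptance checks), 10,000-echo sampler calibrations,
1,000-echo seeding sweeps, and 200-echo localization sweeps; the package's
own choice of these sizes keeps the whole suite within a few minutes on one
CPU while leaving every statistical check well-powered.

## 10. Known limitations

* The echo model is stationary: no spatial PSF variation, so the detector's
  robustness to position-dependent echo shape is untested by synthetic data.
* Merged-event ground-truth labeling uses a fixed chaining threshold (¾λ);
  the image-level merge scale actually varies with echo size and brightness,
  so label/image granularity disagree in a band around the threshold.
* Velocity maps project 3D flow onto the 2D plane; out-of-plane angle is
  unknown, so mapped speeds are lower bounds on true speeds.
* The adaptive nonlocal-means pre-filter (`nlm_filter()`, bandwidth tied to
  the noise level) is available ahead of the Haar stage but off by default:
  the Haar + PPI path is the operative detector, synthetic noise is already
  white, and the composition order is fixed as nonlocal means, then Haar.
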