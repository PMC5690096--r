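---
title: "Models and methods behind mrsimqa"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mrsimqa}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrsimqa)
```

mrsimqa implements the quantitative characterization and routine
quality-assurance analyses used when commissioning an MRI scanner as a
dedicated simulator for radiation therapy planning (an "MR-SIM"). Because
geometric fidelity directly affects dose delivery, an MR-SIM program
measures geometric distortion, main-field (B0) homogeneity, spatial and
volumetric accuracy, respiratory-resolved (4D) imaging behaviour, and
bone-visualizing sequence performance on physical phantoms, and tracks a
set of daily tolerances. This vignette explains the models behind each
analysis, the synthetic phantoms that stand in for the scanner, the
numerical choices, and what the passing tests do and do not demonstrate
about real data.

## Coordinate conventions

All modules share one frame: physical millimetres, origin at the magnet
isocenter, voxel-center convention (`origin + (index - 1) * spacing` for
1-based R indices), axes x = right-left, y = anterior-posterior,
z = foot-head. Distortion is defined radially about the isocenter, so
every generator centers its grid there. Phase images use the wrap interval
`[-pi, pi)` throughout; a vendor convention of 0 to 2 pi is an affine
relabeling of the same information and is not reproduced separately.

## Synthetic phantoms as ground truth

No public image archives exist for the phantoms this kind of program
uses, so every analysis is exercised against a generator with known
ground truth:

* **Capsule-grid phantom** (`gen_grid_phantom_pair()`): a lattice of
  oil-capsule markers, 25 mm apart in-plane and 27 mm along z, filling a
  40 cm cube. The lattice is trimmed to the scanner's acquisition field
  of view, modeled as the ellipsoid with semi-axes 225 x 225 x 200 mm
  (a 450 x 450 x 400 mm FOV); that trimming yields 2440 markers, in line
  with the roughly 2500 control points of the physical device. Markers
  are rendered as solid capsules with true partial-volume weighting
  (each voxel's intensity is the in-capsule fraction estimated from 27
  sub-voxel samples), which keeps the intensity-weighted centroid of a
  rendered marker accurate to a few hundredths of a millimetre at the
  default 2 mm voxels. The distortion applied to the "MR" member of the
  pair is a smooth parametric model (radial cubic `d(r) = a r^3` plus
  optional polynomial terms up to total degree 5, zero at the
  isocenter), standing in for gradient nonlinearity, whose closed form
  is the oracle for the whole mapping pipeline.
* **Uniform sphere with programmed inhomogeneity**
  (`gen_phase_pair()`): a 31 cm sphere inside a 35 cm reconstruction,
  imaged at two echo times (defaults 10 and 12 ms). The phase at each
  echo is `wrap(2 pi f0 ppm 1e-6 TE + phi0)`; the programmed ppm field
  (typically parabolic in radius) is returned as truth. The generator
  refuses fields whose echo-difference phase steps reach pi between
  neighbouring voxels, where unwrapping is ill-posed (the Itoh
  condition).
* **Crossed-ramp insert** (`gen_ramp_volume()`): a ramp at ~11 degrees
  converts slice thickness t into an in-plane band of width
  `t / tan(angle)`; the band is rendered with a one-voxel linear edge so
  the half-maximum crossings sit exactly on the geometric edges.
* **Multi-compartment tissue object** (`gen_multiecho_phantom()`):
  water body, cortical-bone ring, fat sphere and air pocket, with
  complex signal `s(TE) = rho ((1-ff) + ff e^{i 2 pi dfw TE}) e^{-TE/T2*}`
  per voxel. Tissue constants are standard literature magnitudes:
  T2* of 0.4 ms (cortical bone), 40 ms (water), 30 ms (fat); fat-water
  shift 3.4 ppm of f0. Proton densities are 1 (water), 0.9 (fat) and
  0.55 (bone): the bone value reflects that ultrashort-echo acquisitions
  see roughly half of soft-tissue signal in cortical bone, and it keeps
  the documented bone > soft tissue > air ordering of the bone-enhanced
  image valid over the whole 1.1-1.5 scaling range rather than only at
  the 1.3 default. Only the orderings and ratios of these constants
  matter to the analyses.
* **Respiratory motion phantom** (`gen_waveform()`,
  `gen_motion_series()`): a sinusoidal surrogate `(ptp/2) sin(2 pi t/T)`
  with optional drift, spike, or cycle-period-jitter anomalies, driving
  a 55 mm cube along the superior-inferior axis next to a round static
  reference. The programmed 30 mm excursion is attenuated by a
  mechanical transmission factor of 0.6, emulating the string-and-
  trolley drive of real motion platforms, so the realized excursion is
  18 mm - inside the 15-20 mm band such setups actually deliver.

Deliberate non-goals of the generators: no Bloch simulation, no coil
sensitivity or parallel-imaging model, no radial k-space reconstruction
(the out-of-body "halo" of radial ultrashort-echo scans is emulated only
as a painted artifact and removed by masking), and only white Gaussian
noise. Passing tests therefore demonstrate that the *analysis chain* is
correct against a known signal model; they do not certify behaviour
under structured artifacts, susceptibility distortion, or physiological
variability.

## Geometric distortion mapping

The pipeline is detect, align, match, summarize:

1. `detect_markers()` thresholds at half maximum, labels 3-D connected
   components (26-connectivity, compiled), and computes each marker's
   intensity-weighted center of mass. The center of mass includes the
   partial-volume shell around the component (voxels above 5% of
   maximum within a 2-voxel margin of its bounding box): cutting the
   shell off at the segmentation threshold makes the centroid jump as a
   marker translates through the grid, while including it keeps the
   estimate continuous and sub-voxel accurate. Lattice indices come from
   rounding `(centroid - lattice_origin) / spacing`; index collisions
   keep the larger-mass component and are reported.
2. `align_rigid()` performs a Kabsch rotation-translation fit using only
   markers within 5 cm of the isocenter, where system distortion is
   smallest, so the distortion being measured is not absorbed into the
   rigid registration. The physical pairing for the fit uses the same
   greedy nearest-neighbour matching as the main analysis.
3. `match_control_points()` pairs reference and measured centroids
   one-to-one, greedily by ascending distance with ties broken in
   lattice lexicographic order, within a 12 mm radius (just under half
   the smallest lattice spacing; beyond that the warning notes that
   matching can be ambiguous).
4. `radial_distortion_summary()` bins matched points by the radius of
   the *reference* position into the 0-5 cm sphere and 5-10, 10-15 and
   15-20 cm annuli, reporting mean, population standard deviation
   (divisor n; recorded here because either convention is defensible and
   the choice must be fixed), maximum, and the fractions in the 2-3 mm
   band and at or above 3 mm. Empty shells report NA, never zero.

Dense displacement maps are interpolations of marker displacements, not
the output of deformable image registration: where a marker exists the
displacement is exact, and the known boundary artifacts of
intensity-based deformable registration on this kind of phantom are
avoided entirely. The 2-D daily-QA analysis
(`planar_distortion_analysis()`) interpolates in-plane magnitudes
bilinearly over the marker lattice, extracts 2-6 mm isocontours, and
grows an axis-aligned compliant rectangle from the isocenter, one
lattice step at a time alternately per axis, for as long as at least 75%
of enclosed control points stay under 2 mm. The vendor's rectangle
algorithm is undisclosed; this fully specified rule reproduces the
qualitative readout (rectangle dimensions of the order of 300 mm for a
field crossing 2 mm near a 150 mm radius) with a quantization of one
lattice step.

## B0 homogeneity by phase difference

`phase_difference_map()` wraps the echo-2 minus echo-1 subtraction into
`[-pi, pi)`. `unwrap_phase_map()` is quality-guided region growing
(compiled): voxels are unwrapped in descending order of an inverse
local-phase-gradient-energy quality measure, growing from the
highest-quality voxel, so smooth regions resolve before noisy ones; each
connected mask component is unwrapped independently and the inter-
component 2 pi ambiguity is flagged. `phase_to_ppm()` converts via
`ppm = (dphi - mean(dphi)) / (2 pi f0 dTE) 1e6`. The reference to the
masked mean is a deliberate choice: volume-RMS homogeneity is
conventionally a deviation measure, and the absolute frequency offset is
tracked separately by the daily QA module. Consequently the map is
invariant both to adding 2 pi k to an input phase and to a global
frequency shift - both are asserted as properties. `dsv_rms()` reports
the RMS over voxels inside the centered sphere (the DSV); a slicewise
variant exists because multi-slice 2-D protocols are sometimes pooled
per plane, and the two pooled figures agree for smooth fields.

The acceptance-level check programs a parabolic field scaled in closed
form so its mean-removed RMS over the 31 cm ball is 0.9 ppm (using
`<r^2> = 3R^2/5`, `<r^4> = 3R^4/7` over a ball), and requires the full
pipeline to return 0.9 within 0.02 ppm.

## Spatial and volumetric fidelity

`line_profile_peaks()` samples the volume along a physical line by
trilinear interpolation at half-voxel steps and finds one peak per
search box. Sub-sample refinement fits a parabola to the logarithm of
three samples spaced one voxel apart around the maximum: on axis-aligned
lines those samples are raw voxel values, and the log-parabola is exact
for Gaussian-shaped markers, recovering off-grid bead positions to
better than 0.01 mm where a plain parabola on interpolated samples is
biased by about 0.15 mm. Manual peak verification, as a human operator
would do, is not reproducible and is replaced by this deterministic
rule. `threshold_segment()` uses half of the foreground-background range
by default - an operator-set window/level cannot be recovered from a
publication, so a reproducible rule is fixed and exposed as a parameter;
measured volumes are stable to within one voxel-shell for thresholds
anywhere in 0.4-0.6 of the range. Volumes are voxel counts times voxel
volume; equivalent diameter is `(6V/pi)^(1/3)`.

## Amplitude-triggered 4D MRI

The simulator reproduces the logic of amplitude-triggered respiratory
acquisition: a calibration window of exactly the first two breathing
cycles fixes the signal minimum and maximum; `n` trigger levels sit at
the centers of `n` equal amplitude bins; each level carries a slope tag
so the inhale and exhale limbs produce distinct phases, with phase 0
(0%) at end-inhale and phase n/2 (50%) at end-exhale.

The assignment of levels to limbs is the one genuinely open design
point, since the clinical implementation is proprietary. Assigning the
top half of the levels to the falling limb en bloc clusters all usable
crossings into two narrow windows per cycle, and with the protocol's
TR of 2000 ms and a 3 s period the dead time after each shot lands in
the gap between windows essentially every cycle - a resonance that
inverts the duty-cycle ordering between 3 s and 5 s breathing that real
systems show. The package instead interleaves: the falling limb takes
every other level from the top, the rising limb the rest from the
bottom. This keeps the phase sequence monotone in time within a cycle
(physiologically sensible), reduces exactly to levels at -0.5 and +0.5
of amplitude for two phases, spreads crossings over the cycle, and
reproduces both the duty-cycle ordering (faster breathing = higher duty
cycle) and the roughly fourfold ten-versus-two-phase scan-time increase
at the protocol parameters (TR 2000 ms, 25 slices of 5 mm).

Remaining simulator limitations, documented rather than hidden: one
slice is acquired per trigger and the shot blocks for a full TR
(multi-slice packaging per trigger is not modeled), so absolute duty
cycles run higher than a clinical system's; and at two phases with a 3 s
period the 1.5 s spacing between the only two crossings per cycle is
shorter than TR, so every other opportunity is necessarily skipped and
the duty-cycle ordering between periods genuinely inverts there under a
pure sinusoid - the ordering claim is therefore asserted at the
ten-phase configuration that the phantom study features.

Acquisition amplitudes sit exactly on the trigger levels, which yields
the captured-excursion law: the maximum-intensity projection (MIP) over
all phases spans `object size + excursion (n-1)/n` along the motion
axis, an analytic oracle the simulator matches within one voxel.
`object_extent()` measures edge-inclusive extent (first-to-last
above-half-max voxel centers plus one voxel). Duty cycle is nominal
programmed acquisition time (`slices x phases x TR`) over overall scan
time, calibration excluded, matching the worked clinical example
(220 s / 440 s = 50%).

## Two-point Dixon and UTE bone enhancement

The triple-echo acquisition gives one ultrashort echo (0.144 ms) and two
Dixon echoes (2.44 and 4.74 ms) that are not exactly in/out-of-phase, so
the solver is a flexible-echo-time two-point method: per voxel it solves
`s(TE_k) = (W + F e^{i theta_k}) e^{-TE_k R2*}` for non-negative water
and fat, with theta_k the fat phasor angle at each echo. A decay-free
two-point model is inconsistent with the signal physics at these echo
spacings - T2* decay between 2.44 and 4.74 ms alone leaves about 3%
error for 40 ms tissue - so by default a common per-voxel R2* is
estimated jointly: for each candidate decay rate on a grid over
0-0.6 /ms (T2* down to about 1.7 ms; shorter species carry essentially
no Dixon-echo signal and would only amplify noise) the echoes are
demodulated and W, F solved in closed form by real least squares, and
the residual minimum is refined parabolically. For the generator's
signal model this inversion is exact, and the round trip recovers
water/fat maps to well under 1% noiseless. The classic decay-free solve
remains available (`r2star = NULL`), as does demodulation with a known
decay rate. The in-phase image is defined as `W + F`, so
water + fat = in-phase holds to machine precision by construction.
Echo pairs whose fat phasors are colinear (angle difference a multiple
of pi) leave the system singular and are rejected with the condition
value.

Cortical bone, with T2* near 0.4 ms, contributes essentially nothing at
the Dixon echoes and is therefore invisible in water, fat and in-phase
images - which is exactly why the ultrashort echo is acquired. The
bone-enhanced image is `1.3 x UTE - in_phase`, clipped at zero; the 1.3
default follows the ad hoc factor used in practice and is exposed as a
parameter. Out-of-body halo signal is removed by masking with the body
outline (largest above-half-max connected component of a reference
image, morphologically closed); correcting the underlying gradient-delay
k-space effect is out of scope. Bone-air detectability is reported as
the symmetric contrast `(mean_a - mean_b)/(mean_a + mean_b)`; note this
ratio degenerates toward 1 when the second region is exactly zero, so
contrast on noiseless synthetic images should be read qualitatively.

## QA bookkeeping

`central_frequency_check()` implements the ACR daily allowance: drift
relative to the previous session below 1.5 ppm (about 64 Hz at a 1.0 T
central frequency of 42,587,276 Hz) and the absolute frequency inside
the manufacturer's window; a service event that legitimately re-centers
the frequency is handled by resetting the baseline argument, mirroring
the ACR provision for explained changes. `slice_thickness_check()`
measures the ramp-band FWHM by linear interpolation at half maximum and
converts with `tan(angle)`; the default +/-0.7 mm tolerance is the ACR
slice-thickness criterion. `laser_tolerance_check()` applies the 2 mm
crosshair and 1 mm laser-motion tolerances of AAPM TG-66 practice.
Transmitter gain and low-contrast detectability are recorded as
pass-through entries: they come from vendor software whose algorithms
are not public, so the package stores and judges but does not compute
them. Reports serialize to JSON (numeric values round-trip to full
double-text precision) with an overall PASS/FAIL/NA status and export
the metric table as CSV.

## Problem sizes and tolerances used by the test-suite

The shipped checks run the full-size capsule grid (2440 markers at 2 mm
voxels, about half a minute), a 31 cm sphere at 3.5 x 3.5 x 5 mm voxels,
4D studies of 2000 s waveforms at 10 ms sampling with 25 slices, and a
60 x 60 x 30 voxel tissue phantom - sizes chosen so each stage's error
budget (0.2 mm shell statistics, 0.02 ppm volume RMS, one-voxel motion
envelopes, 1% Dixon recovery) is dominated by the method, not by
discretization. Centroid accuracy at these settings is about 0.03 mm
against a 0.1 mm requirement; halving the rendering resolution roughly
doubles that error, which is the main scaling knob if larger lattices
are needed.
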