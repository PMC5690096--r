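# mrsimqa

Phantom-based quantitative characterization and routine quality assurance
(QA) for MRI scanners used as dedicated simulators in radiation-therapy
planning (MR-SIM). Geometric fidelity feeds directly into dose delivery, so
an MR-SIM program measures geometric distortion, main-field (B0)
homogeneity, spatial and volumetric accuracy, respiratory-resolved (4D MRI)
acquisition behaviour, and bone-visualizing (UTE/Dixon) sequence
performance on physical phantoms, and tracks a set of daily tolerances.
mrsimqa implements those analyses together with synthetic phantom
generators that carry exact ground truth, so every stage is testable
without a scanner. It is written for medical physicists and imaging
scientists commissioning or auditing an MR-SIM, and for method developers
who need a reproducible oracle for these pipelines.

## What it computes

* **3-D geometric distortion** from a capsule-grid phantom pair
  (reference vs distorted): connected-component marker detection with
  sub-voxel centers of mass, central-region rigid (Kabsch) pre-alignment,
  one-to-one greedy matching, displacement vectors
  `d = measured - reference`, and radial-shell statistics (mean, SD, max
  of `|d|`; fractions in 2-3 mm and >= 3 mm) for the 0-5 cm sphere and
  5-10, 10-15, 15-20 cm annuli.
* **2-D planar distortion** with bilinear dense maps, 2-6 mm isocontours,
  and the daily-QA compliant rectangle: axis-aligned, grown from the
  isocenter while >= 75% of enclosed control points stay under 2 mm.
* **B0 homogeneity** by dual-echo phase difference: wrapped subtraction,
  quality-guided region-growing unwrapping, conversion to ppm about the
  masked mean (`ppm = (dphi - mean) / (2 pi f0 dTE) 1e6`), and volume RMS
  over a chosen diameter of spherical volume (DSV).
* **Spatial and volumetric fidelity**: line-profile peak detection with
  log-parabolic sub-sample refinement against nominal marker spacings;
  half-maximum threshold segmentation with volume and equivalent-diameter
  comparison against stated truths.
* **Amplitude-triggered 4D MRI** simulation: two-cycle trigger
  calibration, bin-center levels with slope tags, slice-by-slice triggered
  acquisition with TR blocking, duty cycle (nominal / overall scan time),
  maximum intensity projections and motion-envelope extents versus phase
  count.
* **UTE/Dixon**: flexible-echo-time two-point water/fat separation with
  joint per-voxel R2* estimation, bone-enhanced image
  `scale * UTE - in_phase` (default scale 1.3), surface-mask halo cleanup,
  and bone-air contrast reports.
* **QA bookkeeping**: central-frequency drift (1.5 ppm daily allowance,
  about 64 Hz at 42,587,276 Hz), crossed-ramp slice thickness
  (`FWHM x tan(angle)`), laser crosshair (2 mm) and motion (1 mm)
  tolerances, JSON/CSV report round-tripping.

Results are tibbles; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods, so everything composes with the tidyverse.

## Worked example

Characterize a scanner whose distortion grows as the cube of the distance
from the isocenter, reaching 2 mm at 150 mm:

```r
library(mrsimqa)

model <- radial_cubic_model(magnitude_mm = 2, at_radius_mm = 150)
pair  <- gen_grid_phantom_pair(lattice_spec(), model, spacing = 2)
res   <- map_distortion_3d(pair$reference, pair$distorted, lattice = pair$truth)
res$summary
#> # A tibble: 4 x 8
#>   r_min r_max     n mean_mm  sd_mm max_mm frac_2_3mm frac_ge_3mm
#>   <dbl> <dbl> <int>   <dbl>  <dbl>  <dbl>      <dbl>       <dbl>
#> 1     0    50    36  0.0679 0.0413  0.111      0           0
#> 2    50   100   216  0.340  0.148   0.611      0           0
#> 3   100   150   588  1.31   0.403   1.99       0           0
#> 4   150   200  1192  3.43   0.824   4.74       0.339       0.661
```

Each row is a radial shell around the isocenter: within 5 cm the mean
displacement of the 36 markers is 0.07 mm, while in the 15-20 cm annulus it
reaches 3.4 mm and 66% of markers are displaced 3 mm or more - the
characteristic outward growth of gradient-nonlinearity distortion, here
recovered to within 0.2 mm of the generator's analytic field.

Field homogeneity from a programmed parabolic inhomogeneity whose
analytic 31 cm-sphere RMS is 0.9 ppm:

```r
pp <- gen_phase_pair(ppm_parabolic(0.9 / sqrt(12 / 175), 155))
fm <- b0_field_map(pp$phase1, pp$phase2)
dsv_rms(fm, diameter_mm = 310)
#> [1] 0.8996212
```

A daily QA report combining a frequency drift and a slice-thickness
measurement:

```r
rep <- qa_report(dplyr::bind_rows(
  central_frequency_check(42587234, 42587276),
  slice_thickness_check(gen_ramp_volume(5, 11)$image, 11, nominal_mm = 5)))
rep
#> <qa_report> 2026-09-20T08:00:00  overall: PASS
#> # A tibble: 5 x 7
#>   metric                             value units      lower    upper pass
#> 1 central_frequency           42587234     Hz    42584000     4.26e7 TRUE
#> 2 central_frequency_drift           42     Hz          NA     6.39e1 TRUE
#> 3 central_frequency_drift_ppm        0.986 ppm         NA     1.5 e0 TRUE
#> 4 ramp_profile_fwhm                 25.6   mm          NA    NA      NA
#> 5 slice_thickness                    4.97  mm           4.3   5.7 e0 TRUE
```

The 42 Hz drift is 0.986 ppm, inside the 1.5 ppm (63.9 Hz) allowance; the
25.6 mm ramp-band FWHM converts through tan(11 deg) to a 4.97 mm slice.

## Vignette

`vignettes/mrsimqa-methods.Rmd` documents the signal models, the trigger
scheme, the numerical choices (rendering, centroiding, unwrapping, R2*
estimation), and the simulator's known limitations.
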