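# stereodcm

Per-pixel correction of fine pincushion distortion in close-up stereo
images, with a fully synthetic validation pipeline.

## The problem

Micro-topographic analysis of the skin surface (wrinkle depth, roughness)
can be done by stereo photogrammetry with a zoomed-in phone camera: two
views separated by a small baseline, depth recovered from disparity. At
working distances of 60–80 mm the lens leaves a *fine, positive-displacement
pincushion distortion*: observed points are pulled a few pixels toward the
image centre, more strongly on one side of the frame than the other.
Invisible to the eye, this shifts stereo correspondences by a few hundred
micrometres on the object — enough to swamp depth signals of tens of
micrometres.

`stereodcm` implements a per-pixel **Distortion Correction Matrix (DCM)**
built from the one-parameter division model. For a point observed at
centre-relative radius `rd` whose ideal radius is `ru`:

```
R = ru / rd                 distortion ratio (R >= 1 for pincushion)
k = (1 - R) / rd^2          second-order division-model coefficient
lambda = (-1 + sqrt(1 + 4 k ru^2)) / (2 k ru^2)
(xn, yn) = lambda * (xd - xc, yd - yc) + (xc, yc)  ≈  (xu, yu)
```

`R` is measured from vertical-line calibration patterns (ideal vs observed
line positions), smoothed as an even polynomial in `rd` — separately for
the left and right half-images, which carry different distortion strengths
— and `lambda` is evaluated at every pixel to form the DCM. Images are
corrected by forward mapping; the sparse hole region this leaves is filled
by nearest-neighbour interpolation.

Because no reference image set is deposited, everything is validated on
synthetic data: a pinhole stereo simulator applies known division-model
distortion to rendered line patterns and depth-stepped scalar bars, and
the package measures how much of that known distortion the DCM removes.

## Worked example

```r
library(stereodcm)

experiment <- run_correction_experiment()   # five distances, ~40 s
summary_table(experiment)
```

```
 working_distance_mm avg_correction_rate_pct max_before_mm max_after_mm
                  60                81.24044     0.1580040   0.02521066
                  65                86.17074     0.1607949   0.02168479
                  70                83.51330     0.1630976   0.02491036
                  75                87.98527     0.1898856   0.01877458
                  80                89.78214     0.1901094   0.02067461
```

Each row is one simulated working distance: 20 corresponding vertical
lines are matched between the two views, before and after correction.
`max_before_mm` is the maximum corresponding-line distance caused by the
distortion (it grows with the field of view, i.e. with working distance);
after correction the residual is below 0.03 mm everywhere, and the average
correction rate — the mean relative reduction of the per-line distances —
is 81–90%.

The trend of distortion against view angle, and a depth-resolving check on
a scalar bar whose 20 lines rise in 50 µm steps:

```r
fit_experiment_trend(experiment)
#> <distortion_trend> working_distance_mm = 445.2 * max_ratio_mm + -6.745
#>                    (R^2 = 0.8308, p = 0.0312, n = 5)

bar <- run_scalar_bar_experiment()
bar$step_estimate_mm   # 0.0516  (true step 0.05 mm)
bar$span_estimate_mm   # 0.9929  (total staircase ~1 mm)
```

A thin CLI over the same functions lives in `inst/cli/stereodcm.R`
(`simulate`, `calibrate`, `correct`, `match`, `regress`, `demo`).

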