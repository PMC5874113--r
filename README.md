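# respitrack

Marker-based optical tracking of respiratory surface motion, with a digital
thorax phantom for end-to-end validation.

## What this is for

Gating thoracic or breast radiotherapy on breathing requires a motion
surrogate. One inexpensive surrogate is a set of high-contrast fiducial
patches on the patient's skin, filmed by fixed cameras and tracked by
computer vision: a lateral camera observes anteroposterior (AP) and
superior–inferior (SI) motion, a ceiling camera LR and SI. `respitrack`
implements that optical chain in R —

* **detection**: threshold → connected components → sub-pixel,
  intensity-weighted marker centroids;
* **initialization**: Shi-Tomasi corners — the minimum eigenvalue
  $\lambda_{\min}(G)$ of the structure tensor
  $G = \sum_w \begin{pmatrix} I_x^2 & I_x I_y \\ I_x I_y & I_y^2 \end{pmatrix}$;
* **tracking**: pyramidal Lucas–Kanade optical flow, iterating
  $G\,\Delta v = b$ with bilinear sub-pixel resampling, coarse-to-fine over
  a binomial image pyramid, with each point's previous flow as the next
  initial guess;
* **calibration**: px → mm at the marker plane, image axes → anatomical
  axes, opt-in radial undistortion;
* **analysis**: displacement from baseline, amplitude-gating alerts,
  modified-sine fits ($R^2$, RMSE), error statistics versus ground truth,
  inter-marker discrepancy, and drift / step-discrepancy failure events.

Because validating such a system needs a motion rig, the package ships a
**digital phantom**: a marker on an arm rotating 0–90° at constant angular
speed with respiratory pauses at the extrema, i.e. a plateau-topped
quarter-sine displacement law

```
d(t) = a sin((pi/2) t / r),  r = (T - 2p)/2,  T = 60 / f_bpm
```

rendered with anti-aliasing, sensor noise and frame-exact sub-pixel ground
truth. All accuracy claims in the package are computed against that truth.

## Worked example

```r
library(respitrack)

# a 10 mm square marker at 10 px/mm, breathing at 30 bpm with 330 ms pauses
scene  <- phantom_scene(c(200, 320), 10,
                        list(marker_spec(c(100, 60), 8, "square")),
                        noise_sd = 0.02)
report <- run_phantom_validation(scene, motion_params(30, 15, 0.33),
                                 fps = 30, duration_s = 6,
                                 camera = camera_model(10), seed = 1)
print(report)
#> Phantom validation: 180 frames at 30 fps (6 s), seed 1
#>   marker 1: mean |err| 0.0033 mm, max |err| 0.0070 mm
#>             sine fit R^2 = 1.00000, RMSE = 0.0021 mm
#>   failure events: 0 -> PASS
```

The report says: over 180 frames the tracked marker position deviated from
the phantom's true position by 3.3 µm on average (7 µm worst case); the
fitted modified-sine law explains the tracked trajectory essentially
perfectly; and no drift (> 1 mm) or successive-image discrepancy (> 0.5 mm)
failure event occurred. On real video the same chain is run with
`read_frames()` + `run_tracking()` + `traces_to_mm()`, and `gate_signal()`
raises amplitude alerts.

A command-line front end is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "respitrack", package = "respitrack"))')
Rscript "$CLI" simulate --bpm 30 --amplitude-mm 25 --duration-s 10 --out-dir sim
Rscript "$CLI" track    --input sim/frames --pixel-scale 10 --out-dir run
Rscript "$CLI" validate --bpm 30 --amplitude-mm 25 --duration-s 10
```

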