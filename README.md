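# retinareg

Curvature-corrected registration of diagnostic retinal OCT surfaces with
instrument-integrated OCT (iiOCT) point clouds, for robot-assisted
vitreoretinal surgery.

## What problem this solves

Preoperative OCT volumes show the retinal anatomy a surgeon plans on
(epiretinal membranes, grasp points), but a surgical robot navigates in its
own coordinate frame using an iiOCT fibre that measures only the distance
from the instrument tip to the retina. Two things stand between the two
data sets:

1. **Curvature distortion.** Diagnostic C-scans render their A-scans in
   parallel, flattening the retina: a sphere fit to the rendered surface
   returns 2–3× the true radius (≈ 20–30 mm instead of ≈ 10 mm).
2. **Frame mismatch.** The diagnostic scan and the robot frame are related
   by an unknown rigid transform.

`retinareg` implements the registration pipeline that bridges both:

* **Feature extraction** — first-reflection surface segmentation of C- and
  M-scans; reconstruction of iiOCT points from probe poses,
  `p_i = x_i + d_i · v_i/‖v_i‖`.
* **Curvature correction (CC)** — geometric least-squares sphere fit
  `argmin_{c,r} Σ (‖p_i − c‖ − r)²` to each cloud; a target sphere with
  the (trusted) iiOCT radius anchored at the fovea; a per-point deformation
  field `ε_i = j_i^target − j_i^OCT` along each point's line towards the
  fitted centre, which corrects curvature while preserving anatomical
  relief exactly.
* **Initial alignment** — exact landmark alignment: foveas coincide,
  fovea-to-centre axes aligned by a Rodrigues rotation, ONH offsets aligned
  by a signed in-plane rotation about the visual axis.
* **Fine registration** — point-to-plane ICP,
  `E(R,t) = Σ ((b − (Ra+t))·n_b)²`, with a k-d tree correspondence search;
  nonrigid coherent point drift (Gaussian-mixture EM with a
  motion-coherence prior) as the nonrigid alternative.
* **Trajectories** — serpentine raster and Archimedean-spiral robot scans,
  sphere projection, greedy spacing subsampling, and the timing model
  `spacing = velocity / frequency`.
* **Evaluation** — mean fiducial marker error (MFME), cylinder-cropped
  Chamfer distance, paired per-point t-tests, distance histograms.
* **Synthetic eye phantom** — a 10 mm spherical retina with foveal pit,
  optic nerve head, vessel ridges and fiducial wires, plus the flattening
  forward model and seeded iiOCT sampling, giving exact ground truth for
  every stage.

## Worked example

```r
library(retinareg)

# a synthetic model eye: true radius 10 mm, flattened diagnostic scan
spec <- eyePhantomSpec()
spec
#> EyePhantomSpec [lankenau]: r = 10.00 mm (apparent 22.00 mm), 4 vessels,
#>   3 wires, noise sd 0.0125 mm, seed 1

# full pipeline on a 10 mm grid trajectory subsampled to 300 um spacing
cfg <- pipelineConfig(seed = 7, trajectory = "T1", spacing = 0.30)
res <- runPipeline(cfg)
str(res$report[c("rOctBefore", "rIioct", "rOctAfter", "mfmeUm", "chamferUm")])
#> List of 5
#>  $ rOctBefore: num 22.9
#>  $ rIioct    : num 10.2
#>  $ rOctAfter : num 10.2
#>  $ mfmeUm    : num 3.39
#>  $ chamferUm : num 55.1

resNo <- runPipeline(pipelineConfig(seed = 7, trajectory = "T1",
                                    spacing = 0.30, cc = FALSE))
sprintf("Chamfer distance: %.1f um with CC vs %.1f um without",
        res$report$chamferUm, resNo$report$chamferUm)
#> "Chamfer distance: 55.1 um with CC vs 101.2 um without"
```

Reading the numbers: the distorted diagnostic scan fits a 22.9 mm sphere;
after correction its fitted radius matches the iiOCT-measured 10.2 mm.
After alignment and ICP the three wire-crossing fiducials land 3.4 µm from
their true robot-frame positions (the phantom's annotations are exact, so
this isolates algorithmic error), and the cylinder-cropped Chamfer distance
is roughly halved by the correction. `runAblation()` repeats this across
trajectories (10 mm grid; 5 mm fovea grid + 2 mm ONH patch), spacings
(50/150/300 µm) and the CC flag, and tabulates the error reductions.

A command-line front end over the same functions is installed at
`inst/scripts/retinareg-cli.R`
(`Rscript retinareg-cli.R <phantom|trajectory|extract|correct|register|evaluate|pipeline|ablation> --key value ...`).

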