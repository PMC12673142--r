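---
title: "Curvature-corrected registration of retinal OCT surfaces: methods and design"
author: "retinareg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature-corrected registration of retinal OCT surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retinareg)
```

## The problem

Robot-assisted vitreoretinal surgery needs preoperative diagnostic OCT
volumes mapped into the robot's intraoperative coordinate frame so that
structures planned on the diagnostic scan (for example epiretinal-membrane
grasping points) can be located by the instrument. Two obstacles stand in
the way. First, the diagnostic C-scan renders its A-scans in parallel, which
flattens the true spherical curvature of the retina: a retina whose true
radius is near 10 mm typically fits a sphere of 20-30 mm in the rendered
volume. Second, the diagnostic scan and the instrument-integrated OCT
(iiOCT) — a single distance-sensing fibre in the surgical tool — live in
unrelated coordinate frames and sample the retina completely differently
(a dense lateral grid of A-scans versus a sparse sequence of
probe-to-tissue distances along a robot trajectory).

`retinareg` implements the full pipeline that resolves both: surface
extraction from each modality, a sphere-fit-based curvature correction of
the diagnostic cloud anchored at the fovea, landmark-based initial
alignment, fine rigid registration by point-to-plane ICP (with nonrigid
coherent point drift as an alternative), robot scan-trajectory generation
with a velocity-frequency timing model, and validation metrics. Because no
deposited experimental data exist for this problem, the package also ships
a synthetic eye-phantom generator with exact ground truth; every
quantitative claim of the package is demonstrated on that phantom.

## Coordinate and unit conventions

All lengths are millimetres internally; micrometres appear only in on-disk
sidecars and in reported metrics (a single canonical unit prevents
1000-fold unit errors). Frames are right-handed with +z pointing from the
retina towards the scanner or probe, so retinal clouds "open upward" and
fitted sphere centres lie above the surface. Voxel indices are 0-based and
a surface point sits at the voxel centre; the axial index maps to -z.

## Surface extraction

For the diagnostic C-scan, the surface of each A-scan is the first pixel
at or above an intensity threshold along the imaging direction
(`segmentCscanSurface`); A-scans with no such pixel are flagged invalid
and omitted, never zero-filled. The default threshold is Otsu's value on a
256-bin histogram of the whole volume — a deterministic replacement for
the manual annotation a human would perform — and an optional 3x3 median
filter on the index map (off by default) adds robustness without changing
the stated first-reflection rule. `surfaceToCloud` scales indices by the
voxel dimensions, with the lateral scale calibratable from fiducial
markers of known distance (`calibrateScanField`), since nominal scan
fields only hold for flat surfaces.

The iiOCT M-scan is segmented per column the same way, and each distance
sample is placed in 3D by advancing the probe-tip position along the
normalised beam direction (`reconstructIioct`):
p_i = x_i + d_i * v_i / ||v_i||. The reconstruction is invariant to the
scale of v_i.

## Curvature correction

`fitSphere` minimises the geometric cost sum_i (||p_i - c|| - r)^2 by
Gauss-Newton refinement of an algebraic (linear least-squares)
initialisation. The algebraic fit alone is biased under noise; the
geometric refinement removes the bias, and the tests pin the result to a
general-purpose optimiser's optimum on small instances.

The correction itself uses two spheres: the sphere fitted to the distorted
diagnostic cloud, and a target sphere with the radius measured by the
iiOCT (whose geometry is trusted, since each distance is a direct
interferometric measurement along a known ray). Because correction runs
before inter-frame alignment, only the *radius* of the iiOCT fit is
well-defined in the OCT frame; `buildTargetSphere` therefore places the
target sphere tangent to the OCT sphere at the fovea: it passes exactly
through the fovea annotation with its centre on the ray from the fovea to
the OCT sphere centre. Distortions are minimal at the fovea (it lies on
the visual axis), which is why the spheres are anchored there.

For each point, a line is drawn towards the OCT sphere centre; the
deformation vector is the difference between the line's intersections
with the target and OCT spheres on the retinal hemisphere, and the
corrected point is the original plus that vector (`correctCurvature`).
Two properties follow directly from the construction and are enforced by
tests:

* the deformation vanishes at the fovea and grows monotonically towards
  the periphery;
* points are *not* projected onto the sphere — each point's offset from
  the spherical base, measured along its own correction line, is
  preserved exactly, so anatomical relief (pit, cup, vessels) survives
  the correction.

"Retinal hemisphere" is operationalised as the intersection j with
(j - c) . u < 0, where u is the fovea-to-centre direction: the hemisphere
containing the fovea. This is the only reading consistent with the
upward-opening orientation convention.

## Initial alignment

With fovea and optic nerve head (ONH) annotated in both clouds,
`initialAlign` is exact and closed-form: (1) translate so the foveas
coincide; (2) rotate the OCT fovea-to-sphere-centre direction onto the
iiOCT one (Rodrigues rotation about the fovea; antiparallel directions
fall back to a 180-degree rotation about any perpendicular axis);
(3) rotate about the common visual axis by the signed angle between the
ONH offsets projected onto the plane perpendicular to that axis. The
in-plane signed angle is computed with atan2 of the cross and dot
products — an unsigned arccos cannot orient the rotation. Restricting
step 3 to the plane perpendicular to the visual axis prevents
re-introducing tilt, because the axial ONH mismatch can remain large even
after curvature correction. A design subtlety: rotating about the global
z axis would zero the in-plane ONH angle but would break the
just-established tilt alignment whenever the iiOCT visual axis is not
exactly z; rotating about the common visual axis preserves both, and the
two coincide in the robot frame convention used here (visual axis = z).

## Fine registration

`icpPointToPlane` alternates nearest-neighbour correspondence (k-d tree,
pairs beyond the correspondence threshold rejected) with the standard
small-angle closed-form minimisation of
E(R, t) = sum ((b - (Ra + t)) . n_b)^2 over matched pairs, where n_b are
target normals from local PCA plane fits (`estimateNormals`, oriented
towards the fitted sphere centre). Termination follows the cap of 100
iterations or a relative RMSE change below 1e-6.

The correspondence threshold deserves a note. The dense-scan default is
20 um, but the nearest-neighbour distance to a target sampled at spacing
S cannot fall below about S/2 even under perfect alignment, so the
pipeline widens the threshold to max(20 um, 2S) for a run at spacing S.
Without that, sparse-trajectory runs find no correspondences at all. Runs
without curvature correction can still diverge at coarse spacing — the
curvature mismatch leaves only a small central band of correspondences,
and the optimiser can walk away from the landmark initialisation. The
pipeline reports such runs with their (large) uncropped Chamfer distance
rather than failing; stabilising exactly this behaviour is one of the
benefits of the curvature-correction step.

### Nonrigid coherent point drift

`cpdNonrigid` implements the standard expectation-maximisation of a
Gaussian-mixture model whose centroids (the source points) drift under a
motion-coherence prior: displacements are G W with
G_ij = exp(-||y_i - y_j||^2 / (2 beta^2)), and the M-step solves
(d(P1) G + alpha sigma^2 I) W = P X - d(P1) Y. The source cloud is
thinned to a 300 um spacing before optimisation (`voxelDownsample`) and
the field is transferred back to the dense cloud by 4-nearest-neighbour
inverse-distance weighting (`densifyDeformation`), which passes sparse
displacements through exactly at coincident points and always stays in
the convex hull of the contributing vectors.

Where no reference dictates a value we use beta = 2 mm, outlier weight
w = 0.1, and an EM cap of 150 iterations. The coherence weight `alpha`
spans three regimes that the tests demonstrate explicitly:

* **Coherent/rigid regime (large alpha, e.g. 2):** on a rigidly perturbed
  pair the recovered field is rigid to within a fraction of a percent
  (residual after subtracting the best-fit rigid motion, relative to the
  raw field magnitude). Driven far enough, the field freezes entirely and
  cannot modify curvature — the Chamfer distance of a
  curvature-mismatched pair stays at its uncorrected level.
* **Flexible regime (small alpha):** the field bends the cloud and
  reduces the curvature mismatch. Note that because the effective
  regulariser weight is alpha * sigma^2 and sigma^2 anneals towards the
  data noise, smooth global bending is cheap for *any* alpha once the
  EM has converged; alpha mainly controls how much local, incoherent
  motion is admitted.
* **Local/discontinuous regime:** with the mixture variance bounded below
  (the `sigma2Floor` control, default off) and alpha chosen so the prior
  dominates where data support vanishes, points without nearby target
  data remain essentially uncorrected while supported regions still fit —
  the behaviour that produces visible discontinuities at cloud corners
  when the target covers only part of the source. The floor exists
  because on partially overlapping clouds the annealing otherwise
  collapses (sigma^2 to 0, regularisation to 0, unsupported points flung
  by the overfit kernel extension); it is off by default since any floor
  introduces a small boundary shrinkage on exactly matching clouds.

In the end-to-end comparison the package reproduces the qualitative
finding that motivates curvature correction: tuned CPD can match the
curvature-corrected rigid pipeline on the global Chamfer distance, but
its fiducial-marker error is an order of magnitude worse — a smooth
deformation field that overlays the surfaces need not place individual
anatomical points correctly.

## Trajectories and timing

`makeGridTrajectory` builds the serpentine raster: parallel lines at the
pitch, sampled at the pitch along-track, consecutive lines joined by a
single transit of one pitch, so consecutive samples are exactly one pitch
apart everywhere. When the pitch divides the field both boundary lines are
included (a 10 mm field at 50 um pitch has 201 lines and a path length of
201 x 10 + 200 x 0.05 = 2020 mm); otherwise lines stop at the last
multiple of the pitch inside the field. This is the unique simple
convention consistent with both printed acquisition times of the dense
10 mm raster (1010 s at 2 mm/s, and about 29 s when rebuilt at 300 um
pitch and 12 mm/s). `makeSpiralTrajectory` resamples an Archimedean
spiral to uniform arc length via the closed-form arc-length function.
`projectToSphere` drops planar patterns onto the retinal sphere with a
standoff along the inward normal (default 1 mm), with beams aimed
radially at the surface. `subsampleSpacing` implements the greedy
arc-length rule used to derive the coarser spacings (150 um, 300 um) from
a dense 50 um scan, and `acquisitionTime` is path length over velocity
with velocity = spacing x frequency when not given (40 Hz default).

The composite trajectory "T2" is modelled as a 5 mm fovea-centred grid
plus a 2 mm ONH patch. Its real-world acquisition times cannot be
reconciled with any simple raster model that also explains the 10 mm grid
times, so no timing claim is attached to it.

## Evaluation

`mfme` is the mean Euclidean distance between matched fiducial markers
after registration — the quantity that tells a surgeon how far a planned
grasp point will land from its true position. `chamferDistance` is the
symmetric mean nearest-neighbour distance (each direction weighted 1/2),
computed with the same k-d tree and pinned against an exhaustive double
loop in the tests. Because non-overlapping margins inflate the Chamfer
distance, `cropCylinder` first crops both clouds to the z-aligned
cylinder of maximal radius fully covered by both, operationalised as the
smaller distance from the axis to each cloud's lateral convex-hull
boundary. With finite point sets this inradius necessarily sits slightly
inside the outermost points, so a thin boundary band (a percent or two of
a disc-shaped cloud) is always trimmed. `pairedCcComparison` runs the
two-sided paired t-test on per-point distances before versus after a
pipeline change; a zero-variance difference is reported as degenerate
rather than dividing by zero. `distanceHistogram` bins the pooled
bidirectional nearest-neighbour distances (25 um default bin width).

## The synthetic phantom and what it does (not) show

`eyePhantomSpec` describes a spherical retina of radius 10 mm — matching
a model eye with realistic geometry — with Gaussian relief features
added to the height field: a 0.2 mm foveal pit, an ONH cup 4 mm from the
fovea, four vessel ridges (50 um high), and a triangle of three 5 mm x
50 um wires in the macular area whose crossings are the validation
points. A porcine mode drops the pit and uses stitched short wires with a
central substitute-fovea wire. The fovea/ONH landmarks mark the feature
centres at the base-sphere reference level — the idealisation of an
annotator clicking the feature centre — which keeps the curvature
anchoring well-defined (anchoring at the pit *bottom* would displace the
whole corrected cloud by the pit depth).

The diagnostic-scan distortion replaces the 10 mm spherical base by a
22 mm one (apparent/true ratio about 2.2, matching reported fitted radii
for model eyes) tangent at the fovea: each point keeps its signed radial
offset to the true sphere, re-applied along the ray from the apparent
centre through the point. No physical ray-tracing model of the scanner
optics is claimed; this forward model is chosen to be *consistent* with
the observed sphere-fit radii and to make distortion-then-correction an
almost exact round trip (residuals of a few micrometres within 3 mm of
the fovea), which provides the quantitative oracle that real data lack.

iiOCT sampling casts each trajectory pose's beam onto the analytic
surface (coarse scan plus 60 bisection steps, accurate to well below a
nanometre), adds seeded Gaussian distance noise (default sd 12.5 um, the
iiOCT axial sampling), and logs tip pose, beam direction, distance and
timestamp; rays that miss the surface are excluded and counted. All
stochastic outputs are reproducible from the seed.

What passing on this phantom does *not* show: performance under real
speckle and signal dropout, annotation error in the landmarks (the
phantom's are exact, so absolute fiducial errors here are micrometres
rather than the hundred-micrometre scale of physical experiments),
non-spherical eye geometry, post-mortem retinal detachment, or motion.
The phantom validates the algorithmic chain, not the physics.

## End-to-end experiment and problem sizes

`runPipeline` wires the stages together: phantom generation, probe-log
reconstruction, optional curvature correction (also applied to the
landmark and marker coordinates), initial alignment, fine registration
(ICP or CPD), cylinder-cropped evaluation. `runAblation` runs matched
seeds across the trajectory/spacing grid with and without correction and
tabulates MFME, Chamfer distance and the percentage error reduction
100 x (without - with) / without.

Default problem sizes were chosen so a full ablation (2 trajectories x 3
spacings x 2 correction settings) completes in a few minutes on one core
while remaining comfortably above the scales at which the algorithms
change behaviour: a 101 x 101 diagnostic grid (10 mm at 0.1 mm spacing,
about 10,000 points), dense robot scans of up to about 40,000 samples
(10 mm at 50 um), and CPD on sources thinned to 300 um. On the default
phantom the corrected pipeline lands the fiducial crossings within a few
tens of micrometres at every spacing, and the Chamfer distance with
correction beats the uncorrected run in every variant — the synthetic
analogue of the uniform improvement reported on physical model eyes.

## Known limitations

* The sphere is a deliberate first-order model of the retina; an
  ellipsoidal fit would capture real eyes better and is out of scope.
* Landmarks are taken as given annotations; no automatic fovea/ONH
  detection is provided.
* The CPD alpha scale is implementation-specific (it multiplies
  sigma^2 in the M-step); comparisons across implementations should be
  made via the regimes described above, not raw alpha values.
* The distortion forward model is an artifact of the phantom, not a
  claim about scanner optics.
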