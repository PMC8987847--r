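---
title: "Turntable photogrammetry for all-around plant modeling: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Turntable photogrammetry for all-around plant modeling: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turnsfm)
```

## The measurement problem

Non-contact 3D measurement of plants at millimeter accuracy can be done with
nothing but cameras: a plant on a turntable is photographed from a full
revolution by one or more fixed cameras, and structure-from-motion recovers
camera geometry and a 3D point cloud. The practical obstacles are (i)
knowing the interior orientation (principal distance, principal point, lens
distortion) and the exterior orientation of every exposure without a
separate calibration session, (ii) recovering metric scale, since image
geometry alone fixes a reconstruction only up to a global similarity, and
(iii) choosing focal lengths, working distances, tilts and camera counts so
the system resolves the traits of interest.

`turnsfm` implements this pipeline end to end, together with a synthetic
studio simulator that stands in for physical hardware, so every stage is
testable against ground truth.

## Resolution model and studio design

For a level camera at photographing distance $H$ with principal distance
$f$ and pixel pitch $\delta_p$, one pixel footprints
$\delta_{xy} = H \delta_p / f$ at the object. Two views separated by a
turntable rotation of $s$ degrees form a stereo pair with baseline
$B = 2 H \sin(s/2)$, giving depth resolution
$\delta_z = H^2 \delta_p / (f B)$. When the camera is tilted by $\Theta$
and the *horizontal* axis distance is $H_0$, the slant distance is
$H = H_0/\cos\Theta$, the optical axis meets the rotation axis
$c = H_0\tan\Theta$ below the mount, and

$$\delta_{xy} = \frac{H_0\,\delta_p}{f\cos\Theta}, \qquad
  \delta_z = \frac{H^2\,\delta_p}{f\,B}
           = \frac{H_0\,\delta_p}{2 f \sin(s/2)\cos\Theta}.$$

Two remarks on conventions, both verifiable with
`studio_geometry()`:

* The effective stereo baseline angle $s$ defaults to 15 degrees — three
  5-degree turntable steps. It is the one free constant in the depth
  formula and it is exposed as a parameter; 15 degrees is the value
  consistent with all of the printed per-camera depth resolutions of the
  mid-size (0.63 mm) and large (0.86 / 0.83 mm) studio settings at once.
* Substituting $H = H_0/\cos\Theta$ *algebraically* into a
  $\delta_z$ expression written with both $H_0$ and $H$ can collapse the
  tilt dependence entirely. The implementation evaluates $\delta_z$ as
  $H^2\delta_p/(fB)$ with the slant distance $H$, which is the form whose
  values match the published per-camera tables; the two printed variants
  of the formula are reconciled this way and the equivalence of the two
  $\delta_z$ forms above is asserted by a property test.

`plan_cameras()` turns these formulas into a vertical camera layout: upper
cameras tilt down, lower cameras tilt up, each upper camera paired with the
lower camera that images the same height band (their ranges overlap so the
per-camera clouds can be merged), with per-camera $\delta_{xy}$ and
$\delta_z$ reported and an explicit "not achievable" message when the
target resolution cannot be met at the chosen geometry. Coverage uses the
full sensor height under a pinhole model — a planning-level approximation
that ignores distortion. Published per-camera mounting heights encode
additional per-band offsets that are not derivable from $c = H_0\tan\Theta$
alone; heights are therefore treated as configuration inputs, not derived
quantities.

## Coordinate conventions

The object frame is right-handed with its origin at the turntable center,
+Z up along the rotation axis, millimeters everywhere. Angles are degrees
at every interface and radians internally. A `camera_pose` maps object
coordinates to camera coordinates, $x_c = R(X - C)$; rotations are stored
as orthonormal matrices and updated during optimization by local axis-angle
increments ($R \leftarrow R\,\exp([\omega]_\times)$), which avoids gauge
redundancy in the parameterization and keeps the update Jacobians simple.
Object rotation and camera orbit are interchangeable by conjugation with
the step rotation; internally everything is modeled as cameras orbiting a
static object, so a single bundle formulation covers both moving-camera and
turntable modalities. Lens distortion is Brown–Conrady
($k_1,k_2,k_3,p_1,p_2$), the de-facto photogrammetric standard; its inverse
is computed by fixed-point iteration and round-trips to $10^{-8}$ within
1.5 times the sensor half-diagonal.

## The synthetic studio

`scene_spec()` + `simulate_capture()` emulate a capture session:

* a **measurement bar**: vertical pillars on the turntable carrying
  circular coded targets at exactly known spacings (the scale reference)
  and a random-dot texture (dense, well-distributed tie points);
* optionally a **parametric plant** (cylindrical stem plus elliptical leaf
  discs at phyllotaxis angles) and **evaluation rulers** — vertical marker
  lines at the table center with known inter-marker distances, the
  length-accuracy protocol;
* per-frame projection of every point through the true intrinsics and
  per-step poses, visibility filtering (behind-camera and sensor bounds),
  Gaussian detection noise, and a fraction of detections replaced by
  uniform mismatches.

Defaults are chosen to match a realistic session: 5-degree steps (72
frames per camera per revolution), detection noise $\sigma = 0.3$ px and
2% mismatches — typical photogrammetric values — a four-pillar bar with
three targets per pillar and 160 dots. Correspondence is simulated as
solved: tracks are given by point identity and corrupted only by noise and
outliers. Re-implementing SIFT-class feature matching is out of scope;
outlier injection emulates its failure modes. Consequently, passing tests
say nothing about matching robustness on real imagery — they validate
geometry, calibration, scaling, filtering and evaluation downstream of
matching. The background mask is likewise analytic (pixels near any
projected scene point are foreground), standing in for a photographed
mask.

The simulator's ground truth is self-consistent by construction
(projecting a true point through true cameras reproduces the noiseless
detection to $10^{-9}$ px) and byte-identical under a fixed seed.

## Coded targets

Raster rendering and detection exist to exercise automatic scale-reference
recovery. Targets are white-on-black: a central disc, a dark gap, and a
12-sector code ring. Rendering is exact inverse mapping — each (supersampled)
pixel is cast as a ray through the camera model and intersected with the
target plane — so ellipse shape and anti-aliased edges are physically
correct.

The ring code is a 12-bit cyclic word; an ID names an equivalence class of
rotations, so decoding is orientation-invariant. The code book keeps words
with minimum cyclic Hamming distance 3 between classes (also against
mirror-order reads, so a reflected sampling direction can never produce a
*different* valid ID), and decoding is exact-match only: any single-bit
corruption is rejected, never mis-read. A proprietary commercial coding
scheme fills this role in practice; any self-consistent scheme does, since
only the IDs and center positions enter the calculation.

Detection: Otsu threshold, connected components, solid-ellipse candidates
(moment-based fill test), intensity-weighted subpixel centroid and moment
ellipse, then ring sampling along the scaled ellipse with local white/black
references from the disc interior and the gap. The centroid of the exact
perspective image of a circle is the ellipse center, which differs from the
projected circle center (perspective eccentricity); at this package's
working geometries — image targets tens of pixels across at principal
distances of $10^4$ px — that bias is below $10^{-2}$ px, an order of
magnitude under the detector's 0.1 px accuracy contract, so no eccentricity
correction is applied. The contract is asserted on noiseless renders up to
70-degree obliquity.

## Self-calibrating bundle adjustment

The calibration core estimates, from image observations alone: per-camera
interior orientation (principal distance in pixels, principal point,
distortion; $k_3$ fixed at zero by default — it is rarely identifiable at
these field angles), one exterior orientation per camera per step, and all
3D points. Key design choices:

* **Per-step poses are free.** Turntable accuracy is never assumed; the
  nominal geometry (mount height, tilt, step angle) only seeds the
  optimizer. The closed loop over a revolution is a *diagnostic*
  (`closed_loop_residual()`: the wrap-around relative rotation compared to
  the chordal mean of the interior step rotations), not a constraint.
* **Shared intrinsics** across all steps of one physical camera (fixed
  focus; autofocus would make interior orientation fluctuate).
* **Robust loss.** Huber with a 2 px scale absorbs mismatches before
  explicit rejection; `reject_outliers()` then prunes detections above a
  residual-norm threshold (the pipeline uses 3.2 times the median norm,
  about 3 times the Rayleigh mean, keeping false pruning below 0.3% on
  clean data) and re-adjusts to a fixed point.
* **Gauge.** The first camera's step-0 pose is frozen; global scale stays
  free until `fit_scale()` anchors it to the known inter-target distances.
* **Numerics.** Analytic sparse Jacobians (checked against central finite
  differences to $10^{-5}$ relative); Levenberg–Marquardt with Nielsen
  gain-ratio damping; normal equations solved by sparse Cholesky with
  fill-reducing ordering from the Matrix package, which eliminates the
  3×3 point blocks first — the same arithmetic as an explicit Schur
  complement on points, with cost per iteration effectively linear in the
  number of points. Convergence: relative cost change below $10^{-10}$,
  an RMS floor of $10^{-8}$ px for noiseless problems, or 300 iterations
  (the perturbed-initialization recovery problem needs roughly 200).
* **Initialization.** Nominal turntable poses, nameplate focal length,
  principal point at the sensor center, zero distortion; initial structure
  by DLT triangulation refined per-point by Gauss–Newton. A 2-degree pose
  error with 2% focal error is well inside the convergence basin.

The reported RMS residual is per-coordinate,
$\sqrt{\sum(\mathrm{d}x^2+\mathrm{d}y^2)/2n}$, so a converged solve on
$\sigma = 0.3$ px data reports just under 0.3 px (a few percent of the
variance is absorbed by the fitted parameters).

## Scale, masking, merging, evaluation

* `fit_scale()` minimizes $\sum_i (s\,d_i^{\mathrm{model}} -
  d_i^{\mathrm{true}})^2$ over reconstructed reference pairs — with one
  pair, the exact ratio — and applies $s$ to points and camera centers.
  Scale is deliberately recovered from coded-target distances on the bar,
  not from the turntable diameter, so all three axes participate.
* `apply_background_mask()` keeps a point iff it projects into foreground
  in at least `min_votes` (default 2) of the frames where it is visible.
  A true surface point is foreground in essentially every frame, so the
  default is conservative for retention while removing floaters; masks are
  stored at 1/8 sensor resolution with a small (8 px) dilation halo.
* `merge_clouds()` concatenates per-camera clouds in the shared scaled
  frame (no ICP — the bundle already placed all cameras in one frame) and
  deduplicates by grid-hashed clustering with radius defaulting to the
  studio's $\delta_{xy}$: resolution-matched deduplication, never moving a
  point farther than the radius.
* `evaluate_lengths()` measures Euclidean distances between marker points
  reconstructed by the bundle itself against their known values — mean,
  mean absolute and standard deviation over pairs — and
  `residual_map()` grids each sensor plane with mean residual vectors,
  flagging cells no calibration observation ever reached. Regions that
  never see the measurement bar cannot be calibrated there; with a bar
  spanning only a fifth of the measured volume this shows up both as
  uncovered cells and as an order-of-magnitude length-error blow-up,
  which is why the bar must surround the measured range.

## Problem sizes and test design

The test suite and the replicated accuracy studies use a two-camera
upper/lower pair at the mid-size working distance (H0 = 2300 mm, 60 mm
lens, 3.91 µm pitch, full 72-step revolutions, a four-pillar bar with 150
dots, about 12,000 observations and 1,300 free parameters per solve).
Mounting heights are chosen so the pair's height bands jointly cover the
bar and rulers — the coverage rule `plan_cameras()` automates. This size
exercises every code path (including a full revolution for the closed-loop
diagnostic) at roughly ten seconds per solve; accuracy conclusions
transfer to the four- and eight-camera layouts because per-camera stages
are independent and the planner pairs cameras band-by-band in exactly the
same way. Replicated protocols (noise consistency, length accuracy) use
ten independent seeds, mirroring a ten-reconstruction repeatability
protocol.

## Known limitations

* No feature matching: observation tracks come either from the simulator
  or from coded-target detections; natural-feature SfM on real images is
  out of scope.
* No dense multi-view stereo: "per-camera clouds" are triangulated tracks,
  a desk-scale stand-in for production MVS densification.
* The plant model is geometric, not photometric; occlusion is modeled only
  through visibility, not texture.
* The analytic background mask is exact with respect to the synthetic
  scene; photographed masks carry segmentation errors this package does
  not emulate.
* Physical accuracy figures from real hardware depend on lenses, lighting
  and print quality; the synthetic studies here validate the algorithms,
  not any specific rig.
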