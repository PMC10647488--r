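---
title: "Methods: multi-camera underwater motion capture"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-camera underwater motion capture}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`hydromocap` reconstructs 3D marker motion underwater from an array of
synchronized consumer cameras and computes joint kinematics from it.
This vignette documents the models, the numerical choices, what the
synthetic test scenes do and do not emulate, and the known limitations.

## Camera model

Each camera is a pinhole with Brown–Conrady distortion. A world point
`X` (mm) is moved into the camera frame by the stored world→camera
rigid transform (optical axis +z, x right, y down), normalized by
depth, distorted on normalized coordinates

$$x_d = x\,(1 + k_1 r^2 + k_2 r^4 + k_3 r^6) + 2p_1 xy + p_2(r^2+2x^2),$$

(and symmetrically for `y_d`), and mapped to pixels by the intrinsics
(`fx`, `fy`, `cx`, `cy`, skew; pixel origin at the top-left corner,
sub-pixel continuous). The polynomial model rather than an
equidistant-fisheye model is a deliberate choice: at the rig's working
distance the wide-angle lens is adequately described by three radial
and two tangential coefficients, and the polynomial inverts cleanly.
With the default coefficients (`k1 = -0.25`, `k2 = 0.05`) the distorted
radius is strictly monotone over the whole sensor, so the inverse map
is well defined everywhere.

Undistortion inverts the polynomial by a damped Newton iteration on
normalized coordinates (analytic 2×2 Jacobian, tolerance 1e-10
normalized units, at most 50 iterations, error on non-convergence). On
the full 2704×1520 image domain the round trip
distort(undistort(p)) is exact to well below 1e-6 px.

All world units are millimetres; all frames are right-handed; frame
indices are 0-based. Camera poses are stored world→camera only; the
inverse is always derived on demand so the two can never drift apart.

## Calibration

**Intrinsics.** Planar checkerboard views (an asymmetric interior-corner
grid; the default board has 7×10 corners of 60 mm, offset inside a
600×480 mm board) give plane→pixel homographies by the normalized DLT.
Homography constraints on the image of the absolute conic yield
closed-form intrinsics, followed by Levenberg–Marquardt refinement
(`minpack.lm::nls.lm`, monotone cost, relative tolerance below 1e-11,
at most 200 iterations) of intrinsics, distortion and per-view board
poses against total squared reprojection error. Three safeguards
matter in practice:

* With strong distortion and pixel noise the closed-form conic solution
  can go non-physical (negative squared focal lengths). The
  initialization then falls back to a linear two-parameter estimate of
  (`fx`, `fy`) with the principal point pinned at the image centre, and
  as a last resort to a generic `f = width/2` guess — the refinement's
  basin of attraction is wide enough (empirically, initial focals from
  0.15× to 1.7× the sensor width converge to the same optimum on the
  default camera).
* Focal length is unobservable from near-parallel board orientations,
  so the orientation spread of the views is probed first and a spread
  below 3° is a hard error rather than a silent garbage fit.
* `k3` is only estimated with at least 10 views, otherwise fixed at 0;
  skew is fixed at 0. Both are ill-conditioned on small view sets.

Reported `rmse_px` is the per-coordinate reprojection RMSE, so with
0.5 px isotropic observation noise a healthy calibration reports about
0.5 px.

**Stereo.** Each camera pair is calibrated from shared board views:
independent board poses per camera (homography decomposition on
undistorted pixels + 6-dof LM refinement), per-view relative transforms
composed through the board frame, robust averaging (chordal quaternion
mean for rotation, componentwise median for translation), a consistency
gate (default 5° / 100 mm spread; exceeding it suggests mis-paired or
mis-synchronized views and is an error), and finally a joint refinement
of the relative pose plus per-view board poses against the reprojection
error in both cameras (at most 20 views enter the refinement, evenly
subsampled, to bound the parameter count). The field protocol
recommends at least 15 shared views; fewer (down to 3) only warns,
because that minimum is protocol advice, not an algorithmic bound.

## Synchronization

Cameras free-run at a nominal common 120 fps, so synchronization is an
integer frame offset per camera. Extinguishing the pool lighting
produces unambiguous global events: per-frame mean luminance drops of
several hundred per cent of the noise level. Events are detected as
excursions below `median − k·MAD` (default `k = 5`; the robust location
and scale ignore the bright moving foreground), with two practical
guards: an excursion must last at least 2 frames (a single-frame noise
outlier below a 5-MAD threshold occurs at a non-negligible rate over
10⁴-frame series, and a real lighting extinction always spans several
frames at 120 fps), and events closer than 0.5 s are merged. Offsets
are differences of first-event frames against the reference camera;
inter-event gaps must agree across cameras within 2 frames (the
acquisition protocol of three extinctions before and one after the
recording makes four events available). Sub-frame synchronization is
out of scope — at 120 fps an offset error of half a frame is 4 ms.

## Reconstruction and frame unification

Triangulation is the classical two-view DLT: the stacked 4×4
homogeneous system solved by the smallest singular vector,
dehomogenized, with the two reprojection residuals and camera depths
returned. A residual above a configurable gate (default 5 px) flags
the point rather than dropping it; a homogeneous scale below 1e-12 is a
point-at-infinity error. Only two views are used per point by design —
the rig is built as three independent stereo pairs, and the joint
angles only need all three markers of a joint from one pair.

Each pair reconstructs in its first camera's local frame. Because
adjacent pairs overlap in view, the samples reconstructed by both give
a rigid "transition matrix" between the pair frames, estimated by the
cross-covariance SVD (Kabsch/Umeyama) with determinant sign correction
and no scale factor. All shared (label, frame) samples enter the fit
(no subsampling), transitions are chained by composition to the first
pair, and duplicated samples are merged by an unweighted average (the
choice is arbitrary; inverse-variance weighting would slightly favour
the nearer pair but the protocol does not define weights).

The pool frame is built from two weighted plumb lines (the up direction
is ball minus weight, i.e. top minus bottom) and waterline floats: z is
the mean unit plumb direction, y the principal waterline direction
orthogonalized against z, x = y × z completes the right-handed
trihedron, and the origin sits at a designated plumb ball. Plumb and
waterline directions within 5° of parallel are an error. Missing
trajectory runs of at most 12 frames (0.1 s at 120 fps) can be filled
by linear interpolation; longer gaps stay missing.

## Joint kinematics

A joint angle is the angle at the vertex marker between the proximal
and distal limb vectors. The unsigned angle lives in [0°, 180°]; the
sign of `(v1 × v2) · lateral` against a medio-lateral reference axis
decides hyperextension, returned as `360° − θ`. This matters only for
the fetlocks, which extend beyond 180°; for every other joint the
motion stays well on the flexion side. The lateral axis defaults to
the pool-frame x axis because the swimming motion is predominantly
sagittal; it is configurable per call, and the unsigned part of the
angle is invariant under any common rigid transform of the markers (the
sign needs the axis transformed along, which the API takes as an
argument). Whether angles are computed before or after frame
unification is immaterial for the same reason.

Maximal flexion is the series minimum, maximal extension the maximum,
ROM their difference — smaller angle means more flexion. Swim cycles
are detected as successive extension peaks separated by at least a
minimum period (default 0.5 s), with a 10%-of-range prominence floor so
constant or near-constant series yield no cycles.

No smoothing is applied by default anywhere in the pipeline. An
optional zero-phase 4th-order Butterworth low-pass at 6 Hz
(`smooth_angle_series`) is provided; it uses odd-reflection padding
because a zero-phase filter without padding has large edge transients.
For noisy reconstructions the filter is the appropriate estimator
before taking series extremes: per-frame extremes of a noisy series are
biased outward by the noise tails, while the limb signal itself lives
far below 6 Hz (a 1.5 s cycle is 0.67 Hz). The parameter-recovery
analysis below uses it for exactly that reason, and reports raw-series
accuracy separately.

## The synthetic scene

The generator is first-class, tested code: every observation it emits
is the exact projection of emitted ground truth before seeded Gaussian
pixel noise, and everything is deterministic given (parameters, seed).

* **Rig** — six cameras 500 mm apart at 1300 mm from the motion plane,
  2704×1520 px, `fx = fy = 800` px (a wide-angle consumer camera),
  `k1 = -0.25`, `k2 = 0.05`, 120 fps. The composite horizontal coverage
  at the working distance exceeds 2.6 m with large pair overlap. The
  spacing and distance are not printed anywhere authoritative; these
  defaults reproduce the printed composite coverage and are
  configurable.
* **Checkerboard sweep** — the validation board follows a smooth
  out-and-back path across the full field of view with gentle yaw
  (±20°), pitch (±12°) and depth (±120 mm) oscillation, 60 s by
  default. The five reference points are emitted as full-rate marker
  tracks; the corner grid is emitted as calibration views every 24
  frames (5 views/s), so a sweep yields both the stereo-calibration
  input and the error-estimation input, as in the real protocol.
* **Swimming limb** — two 5-segment chains (front: scapula 450,
  humerus 350, radius 400, metacarpus 270, digit 150 mm; hind: ilium
  400, femur 450, tibia 450, metatarsus 300, digit 150 mm — realistic
  adult-horse segment lengths) animated by sinusoidal joint
  trajectories `mean + amplitude·sin(2πt/T + φ)` with a 1.5 s default
  period and a proximal-to-distal phase lag of 0.6 rad per joint. The
  means and amplitudes are pinned so that flexion/extension extremes
  equal the published equine swimming ranges (e.g. carpus 69°–168°,
  hind fetlock 109°–203°, hyperextending past 180°). The chain is
  built in the sagittal plane so the planted angles are recovered
  identically by the angle definition above; a 5° wobble about the
  vertical axis through each limb root exercises the 3D code paths
  without changing the planted angles (it is a rigid motion of the
  limb). The roots advance at constant speed with a 50 mm vertical
  bob; the travel window keeps the whole horse (front and hind roots
  1.3 m apart) inside the composite field of view, because markers far
  outside the rig span would be imaged at an obliquity the real
  protocol never measures.
* **Plumb/waterline and luminance** — two vertical plumb lines and
  three waterline floats encode a planted pool pose exactly; luminance
  series are baseline 1 with 6-frame square dips at the scheduled
  extinction events, shifted by planted integer offsets, plus noise.

What the generator does **not** emulate: water turbidity and lighting
inhomogeneity, marker-tracking failure and outliers (a uniform-outlier
option is deliberately left out of the defaults), refraction at any
interface (the rig is fully submerged so the medium is uniform),
occlusion of medial markers by the limb, rolling shutter, and clock
drift within a recording. Passing tests on the synthetic scene
therefore validate the geometry and estimation chain, not the tracking
front end that real videos require.

## Accuracy at the study conditions

With 0.5 px observation noise at the default geometry, single-pair
triangulation error is about 0.8 mm in the image plane and 2–3 mm
along depth (the depth-to-baseline ratio is 2.6). On the 60 s
checkerboard sweep the full pipeline — stereo calibration from the
sweep's own corner views, triangulation, unification — yields median
absolute errors of about 1.7 mm over the eight segments and about 0.3°
over the five angles, comfortably inside the protocol's 10 mm / 1°
bounds; the acceptance script recomputes exactly this. Horizontal
segments are the least precise, vertical the most, because the depth
error projects mostly onto the horizontal segment direction during the
sweep.

For the swim scene the same noise propagates to roughly 0.5° RMSE on
proximal joint angles and 1.5–2° on the fetlocks, whose distal
segments are short (150–270 mm). After the 6 Hz low-pass the per-joint
RMSE drops below 1° and recovered ROMs land within about 2° of the
planted values, though the fetlock ROM remains the most noise-sensitive
readout (series extremes of the heaviest-tailed joints); across seeds
its recovery error fluctuates by roughly ±1.5°.

## Problem sizes in the tests

The test suite exercises the full pipeline at reduced problem sizes
chosen to keep the suite quick while leaving every estimate deep in its
asymptotic regime: 6–12 s sweeps (720–1440 frames, 30–60 calibration
views per pair) instead of the 60 s acceptance run, 20 calibration
views per intrinsic calibration, two swim cycles (360 frames), and 100
random draws for the synchronization recovery property. The acceptance
script runs the full 60 s / 7200-frame protocol.

## Known limitations

* Calibration and triangulation assume a uniform medium; using the
  package with cameras behind a flat port would fold refraction into
  the distortion polynomial and bias depth.
* The transition-matrix chain accumulates error linearly in the number
  of pairs; with three pairs this is negligible, but a much longer
  camera wall would warrant a global (bundle) adjustment, which is
  intentionally out of scope here.
* The hyperextension sign is decided per frame; in a near-straight
  joint with very noisy markers the sign can flip frame-to-frame. The
  low-pass option mitigates this; a temporal hysteresis would be the
  next step if real data showed sustained flipping.
* Integer-frame synchronization bounds the residual timing error at
  ±4 ms (half a frame at 120 fps), which is far below the kinematic
  bandwidth of interest but would matter for impact events.
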