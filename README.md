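# hydromocap

Low-cost multi-camera underwater motion capture in R.

`hydromocap` implements a complete marker-based stereophotogrammetry
pipeline for underwater motion analysis with an array of synchronized
consumer cameras mounted along one pool wall: six wide-angle cameras in
three stereo pairs, 120 fps, 2.7K resolution, covering a composite field
of view of about 2.6 m. It was built around the study of equine swimming
kinematics — reconstructing the 3D motion of the fore- and hindlimb of a
swimming horse from surface markers and reading off joint angles and
ranges of motion — but every stage is generic.

The pipeline stages are:

1. **Synchronization** — each camera's clock is aligned by detecting
   lighting-extinction events in per-frame luminance series (a robust
   `median − k·MAD` threshold, integer-frame offsets).
2. **Calibration** — planar-checkerboard intrinsic calibration
   (homography constraints on the image of the absolute conic, then
   Levenberg–Marquardt refinement of intrinsics + Brown–Conrady
   distortion + per-view poses) and pairwise stereo calibration from
   shared board views (per-view relative poses, robust quaternion/median
   averaging, joint two-camera refinement).
3. **Reconstruction** — two-view DLT triangulation of undistorted marker
   tracks per camera pair. For a point observed at pixels
   `x_a`, `x_b` under projection matrices `P_a = K_a [I | 0]`,
   `P_b = K_b [R | t]`, the homogeneous system
   `[x_a × P_a ; x_b × P_b] X = 0` is solved by the smallest singular
   vector.
4. **Unification** — each pair reconstructs in its first camera's local
   frame; overlapping (label, frame) samples between adjacent pairs give
   a least-squares rigid "transition matrix" (Kabsch/Umeyama
   cross-covariance SVD, no scale), chained so everything lands in
   camera 1's frame, then in a global pool frame built from weighted
   plumb lines (vertical z) and waterline floats (horizontal y).
5. **Kinematics** — eight equine joint angles (shoulder, elbow, carpus,
   front fetlock, hip, stifle, tarsus, hind fetlock) as
   `θ = ∠(p_prox − p_vertex, p_dist − p_vertex)`, with the sign of
   `(v1 × v2) · lateral` deciding hyperextension (`360° − θ`, so fetlock
   extensions above 180° are representable); ROM summaries
   (`rom = max − min`, minimum = maximal flexion) and swim-cycle
   detection from extension peaks.
6. **Error estimation** — the five checkerboard reference points
   TL/TR/ML/BL/BR are reconstructed through the whole pipeline and the
   eight segments (339.4–600 mm) and five angles (33.69°–101.31°) are
   compared with the reference geometry, reported as box-plot summaries.

A fully seeded synthetic-scene generator (`make_default_rig`,
`simulate_checkerboard_pass`, `simulate_swim`,
`simulate_plumb_and_waterline`, `simulate_luminance`) emulates the
six-camera rig, so every stage is testable end to end without any video
data.

Note on the reference angles: the printed table this geometry derives
from attributes 33.69° to the triangle vertex TL and 45.00° to TR, but
the law of cosines applied to the printed side lengths (600.0 / 432.7 /
339.4 mm) puts 45.00° at TL and 33.69° at TR. `reference_geometry()`
pins all angle ground truths to the coordinates solved from the side
lengths, i.e. treats those two vertex labels as swapped.

## Worked example

Simulate a 10 s checkerboard sweep through the default rig with 0.5 px
pixel noise, stereo-calibrate every pair from the corner views,
triangulate, unify, and measure the reconstruction error:

```r
library(hydromocap)

rig <- make_default_rig()          # six cameras, 500 mm apart, 1.3 m range
res <- run_sweep_validation(rig, duration_s = 10, noise_px = 0.5, seed = 42)
res$median_segment_error_mm
#> [1] 1.71
res$median_angle_error_deg
#> [1] 0.297
error_report(res$segment_errors, by = "group")
#>              item    n median    q1   q3 whisker_low whisker_high n_outliers
#> 1  first_diagonal 2400  1.900 0.858 3.48    0.002832         7.40         98
#> 2      horizontal 2400  2.883 1.327 5.15    0.001551        10.88         80
#> 3 second_diagonal 2400  2.248 1.028 4.18    0.001997         8.85         90
#> 4        vertical 2400  0.838 0.392 1.48    0.000425         3.09         64
```

The median absolute errors — a couple of millimetres on segments of
340–600 mm and a third of a degree on angles of 34–101° — sit well
inside the centimetre / one-degree accuracy the protocol targets, with
the horizontal segments noisiest (they are most sensitive to the depth
component of the triangulation error).

Joint kinematics on a synthetic two-cycle swim with the same noise:

```r
sw <- simulate_swim(rig, n_cycles = 2, noise_px = 0.5, seed = 1)
pair_trajs <- lapply(rig$pairs, function(p)
  reconstruct_pair(sw$tracks, rig$stereo[[paste(p, collapse = "-")]],
                   rig$cameras[[p[1]]], rig$cameras[[p[2]]]))
uni <- unify_frames(pair_trajs)
ang <- joint_angle_series(uni, lateral_axis = c(0, 0, -1))
summarize_rom(ang)
#>           joint maximal_flexion maximal_extension    rom
#> 1        carpus           68.07             168.3 100.27
#> 2         elbow           57.18             133.4  76.24
#> ...
#> 8        tarsus           61.50             162.4 100.94
```

The recovered flexion/extension extremes track the planted limb
trajectories (e.g. carpus 69°–168°, hind fetlock hyperextending past
200°) to within the per-frame noise; `smooth_angle_series()` (an
optional zero-phase 6 Hz Butterworth low-pass) tightens the ROM readout
further, and `detect_cycles()` reads the 1.5 s cycle period back from
the extension peaks.

A thin command-line front end wrapping these functions lives at
`inst/cli/hydromocap.R`
(`Rscript inst/cli/hydromocap.R simulate out=scene seed=1`, then
`sync`, `stereo-calibrate`, `run`, `validate-board`, ...).

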