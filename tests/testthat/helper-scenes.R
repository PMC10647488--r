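# shared fixtures, built in code

test_intrinsics <- function(fx = 800, fy = 800) {
  camera_intrinsics(fx, fy, cx = 1352, cy = 760)
}

test_distortion <- function() {
  lens_distortion(k1 = -0.25, k2 = 0.05)
}

random_rigid <- function(scale_t = 100) {
  rigid_transform(rodrigues_to_matrix(rnorm(3)), rnorm(3) * scale_t, "a", "b")
}

# reconstruct every pair of a rig from tracks (true stereo transforms)
# and unify into the first camera's frame
reconstruct_and_unify <- function(tracks, rig) {
  pair_trajs <- list()
  for (p in rig$pairs) {
    key <- paste(p, collapse = "-")
    tr <- suppressWarnings(
      reconstruct_pair(tracks, rig$stereo[[key]],
                       rig$cameras[[p[1]]], rig$cameras[[p[2]]]))
    if (nrow(tr)) pair_trajs[[key]] <- tr
  }
  suppressWarnings(unify_frames(pair_trajs))
}

# low-pass each joint's series with the package's optional filter
filter_angle_series <- function(angles, frame_rate = 120) {
  out <- lapply(split(angles, angles$joint), function(a) {
    a <- a[order(a$frame), ]
    a$angle_deg <- smooth_angle_series(a$angle_deg, frame_rate = frame_rate)
    a
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# join recovered and planted angle series
angle_errors_vs_truth <- function(angles, truth) {
  m <- merge(angles, truth, by = c("frame", "joint"),
             suffixes = c("", "_true"))
  m$err <- m$angle_deg - m$angle_deg_true
  m
}
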