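test_that("joint angle handles flexion, straight joints and hyperextension", {
  expect_equal(joint_angle(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0),
                           lateral_axis = c(0, 0, 1)), 90)
  # collinear markers: straight joint
  expect_equal(joint_angle(c(-2, 0, 0), c(0, 0, 0), c(5, 0, 0),
                           lateral_axis = c(0, 0, 1)), 180)
  # the checkerboard ML triangle vertex
  expect_equal(joint_angle(c(0, 0, 0), c(240, 240, 0), c(600, 0, 0),
                           lateral_axis = c(0, 0, 1)), 101.31,
               tolerance = 0.005)
  # mirrored configuration crosses to the hyperextension side
  expect_equal(joint_angle(c(1, 0, 0), c(0, 0, 0), c(0, -1, 0),
                           lateral_axis = c(0, 0, 1)), 270)
  expect_error(joint_angle(c(0, 0, 0), c(0, 0, 0), c(1, 0, 0)),
               "zero-length")
})

test_that("joint angle is invariant under common rigid motion and scaling", {
  set.seed(77)
  for (i in 1:50) {
    p <- rnorm(3) * 100
    v <- rnorm(3) * 100
    d <- rnorm(3) * 100
    ax <- hydromocap:::unit_vector(rnorm(3))
    a0 <- joint_angle(p, v, d, ax)
    g <- rigid_transform(rodrigues_to_matrix(rnorm(3)), rnorm(3) * 500,
                         "x", "y")
    a1 <- joint_angle(rt_apply(g, p), rt_apply(g, v), rt_apply(g, d),
                      as.numeric(g$rotation %*% ax))
    expect_equal(a1, a0, tolerance = 1e-9)
    # scale invariance in the limb vectors
    s <- runif(1, 0.1, 10)
    a2 <- joint_angle(v + s * (p - v), v, v + s * (d - v), ax)
    expect_equal(a2, a0, tolerance = 1e-9)
  }
})

test_that("angle series follow the planted joint trajectories", {
  rig <- make_default_rig()
  sw <- simulate_swim(rig, n_cycles = 1L, noise_px = 0, seed = 12)
  ang <- joint_angle_series(sw$ground_truth, lateral_axis = c(0, 0, -1))
  m <- angle_errors_vs_truth(ang, sw$ground_truth_angles)
  expect_lt(max(abs(m$err)), 1e-6)
  expect_identical(sort(unique(ang$joint)), sort(joint_definitions()$joint))

  # a marker missing at one frame drops that frame from the series
  gt <- sw$ground_truth
  gt <- gt[!(gt$label == "carpus" & gt$frame == 50L), ]
  ang2 <- joint_angle_series(gt, lateral_axis = c(0, 0, -1))
  expect_false(50L %in% ang2$frame[ang2$joint == "carpus"])
  expect_false(50L %in% ang2$frame[ang2$joint == "elbow"])
  expect_true(50L %in% ang2$frame[ang2$joint == "hip"])

  # missing an entire marker names the affected joint
  gt3 <- sw$ground_truth[sw$ground_truth$label != "front_hoof", ]
  expect_error(joint_angle_series(gt3), "front_fetlock")

  # a common rigid transform leaves every series unchanged
  g <- rigid_transform(rodrigues_to_matrix(c(0.4, -0.2, 0.8)),
                       c(100, 2000, -500), "cam1", "other")
  gt_m <- sw$ground_truth
  xyz <- rt_apply(g, as.matrix(gt_m[, c("x_mm", "y_mm", "z_mm")]))
  gt_m$x_mm <- xyz[, 1]; gt_m$y_mm <- xyz[, 2]; gt_m$z_mm <- xyz[, 3]
  gt_m$coordinate_frame <- "other"
  ang_m <- joint_angle_series(gt_m,
                              lateral_axis = as.numeric(g$rotation %*%
                                                          c(0, 0, -1)))
  expect_equal(ang_m$angle_deg, ang$angle_deg, tolerance = 1e-9)
})

test_that("ROM summaries implement extension minus flexion", {
  s <- summarize_rom(c(110, 102, 115, 119, 104))
  expect_equal(s$maximal_flexion, 102)
  expect_equal(s$maximal_extension, 119)
  expect_equal(s$rom, 17)

  expect_equal(summarize_rom(rep(90, 10))$rom, 0)

  # sinusoid of amplitude A has ROM 2A up to discretization
  t <- seq(0, 3, by = 1 / 120)
  a <- 118.5 + 49.5 * sin(2 * pi * t / 1.5 + 0.3)
  expect_equal(summarize_rom(a)$rom, 99, tolerance = 0.05)

  expect_error(summarize_rom(numeric(0)), "empty")

  df <- data.frame(joint = rep(c("a", "b"), each = 3),
                   angle_deg = c(10, 30, 20, 100, 90, 95))
  out <- summarize_rom(df)
  expect_equal(out$rom[out$joint == "a"], 20)
  expect_equal(out$rom[out$joint == "b"], 10)
})

test_that("cycle detection recovers planted periods from extension peaks", {
  fps <- 120
  t <- seq(0, 3.5, by = 1 / fps)
  x <- 120 + 40 * cos(2 * pi * (t - 0.1) / 1.5)
  cyc <- detect_cycles(x, frames = seq_along(x) - 1L, min_period_s = 0.5,
                       frame_rate = fps)
  expect_length(cyc$durations_s, 2L)
  expect_equal(cyc$durations_s, c(1.5, 1.5), tolerance = 0.01)

  expect_warning(out <- detect_cycles(rep(100, 500)), "no cycles")
  expect_length(out$boundaries, 0L)

  # two different planted periods, recovered within one frame
  t1 <- seq(0, 1.4, by = 1 / fps)
  t2 <- seq(0, 1.6, by = 1 / fps)
  x2 <- c(100 + 30 * cos(2 * pi * t1 / 1.4),
          (100 + 30 * cos(2 * pi * t2 / 1.6))[-1])
  pad <- rep(70, 30)
  x2 <- c(pad, x2, pad)
  cyc2 <- detect_cycles(x2, frames = seq_along(x2) - 1L, min_period_s = 0.5,
                        frame_rate = fps)
  expect_equal(cyc2$durations_s, c(1.4, 1.6), tolerance = 1 / fps + 1e-9)
})

test_that("the low-pass filter tracks a slow signal without edge artefacts", {
  set.seed(88)
  t <- (0:479) / 120
  true <- 118.5 + 49.5 * sin(2 * pi * t / 1.5)
  noisy <- true + rnorm(length(t), 0, 2)
  sm <- smooth_angle_series(noisy, frame_rate = 120, cutoff_hz = 6)
  expect_lt(sqrt(mean((sm - true)^2)), 0.8)
  expect_lt(abs(diff(range(sm)) - 99), 2)
})
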