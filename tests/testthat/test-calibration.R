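test_that("homography estimation reproduces a planar projective map", {
  # numerically equal correspondences give the identity
  xy <- cbind(c(0, 100, 100, 0, 50), c(0, 0, 80, 80, 40))
  H <- estimate_homography(xy, xy)
  expect_equal(H, diag(3), tolerance = 1e-9)

  # a synthetic camera viewing the z = 0 plane
  set.seed(21)
  pose <- rigid_transform(rodrigues_to_matrix(c(0.2, -0.3, 0.1)),
                          c(100, -50, 1200), "world", "c")
  cam <- camera_model("c", test_intrinsics(), lens_distortion(), pose)
  plane <- cbind(runif(30, 0, 540), runif(30, 0, 360))
  px <- project_points(cbind(plane, 0), cam)
  H <- estimate_homography(plane, px)
  proj <- cbind(plane, 1) %*% t(H)
  expect_lt(max(abs(proj[, 1:2] / proj[, 3] - px)), 1e-8)

  expect_error(estimate_homography(xy[1:3, ], xy[1:3, ]), "at least 4")
  coll <- cbind(1:6, 2 * (1:6))
  expect_error(estimate_homography(coll, coll + 1), "collinear")
})

test_that("intrinsic calibration recovers the true camera from noiseless views", {
  cam <- camera_model("cam", test_intrinsics(), test_distortion())
  board <- board_model()
  sim <- simulate_calibration_views(cam, board, n_views = 20, noise_px = 0,
                                    seed = 7)
  cal <- calibrate_intrinsics(sim$observations, board)
  expect_lt(abs(cal$intrinsics$fx - 800) / 800, 0.001)
  expect_lt(abs(cal$intrinsics$fy - 800) / 800, 0.001)
  expect_lt(cal$rmse_px, 1e-6)
  expect_equal(cal$distortion$k1, -0.25, tolerance = 1e-6)
  expect_equal(cal$distortion$k2, 0.05, tolerance = 1e-5)
  # refinement must not be worse than its closed-form initialization
  expect_lte(cal$rmse_px, cal$initial_rmse_px)
  # recovered per-view poses match the generator's
  p1 <- cal$view_poses[["1"]]
  expect_lt(max(abs(p1$translation - sim$poses[[1]]$translation)), 1e-3)
})

test_that("intrinsic calibration degrades gracefully with pixel noise", {
  cam <- camera_model("cam", test_intrinsics(), test_distortion())
  board <- board_model()
  sim <- simulate_calibration_views(cam, board, n_views = 20, noise_px = 0.5,
                                    seed = 19)
  cal <- calibrate_intrinsics(sim$observations, board)
  expect_gt(cal$rmse_px, 0.3)
  expect_lt(cal$rmse_px, 0.7)
  expect_lt(abs(cal$intrinsics$fx - 800) / 800, 0.01)
  expect_lte(cal$rmse_px, cal$initial_rmse_px)
})

test_that("intrinsic calibration rejects under-determined inputs", {
  cam <- camera_model("cam", test_intrinsics(), test_distortion())
  board <- board_model()
  sim <- simulate_calibration_views(cam, board, n_views = 3, noise_px = 0,
                                    seed = 3)
  obs2 <- sim$observations[sim$observations$view_id <= 2, ]
  expect_error(calibrate_intrinsics(obs2, board), "at least 3 views")

  # near-parallel (frontal) board orientations leave the focal length
  # unobservable
  cam0 <- camera_model("cam", test_intrinsics())
  corners <- board_corners(board)
  frontal <- do.call(rbind, lapply(1:5, function(v) {
    pts <- cbind(corners$x_mm - 300 + 50 * v, corners$y_mm - 240 + 30 * v,
                 1300)
    px <- project_points(pts, cam0)
    data.frame(view_id = v, corner_id = corners$corner_id, u_px = px[, 1],
               v_px = px[, 2])
  }))
  expect_error(calibrate_intrinsics(frontal, board), "near-parallel")
})

test_that("board pose estimation matches the generating pose", {
  cam <- camera_model("cam", test_intrinsics(), test_distortion())
  board <- board_model()
  sim <- simulate_calibration_views(cam, board, n_views = 3, noise_px = 0,
                                    seed = 31)
  v1 <- sim$observations[sim$observations$view_id == 1, ]
  pose <- estimate_board_pose(board, v1, cam$intrinsics, cam$distortion)
  truth <- sim$poses[[1]]
  rot_err <- hydromocap:::rotation_angle_deg(t(pose$rotation) %*%
                                               truth$rotation)
  expect_lt(rot_err, 1e-6)
  expect_lt(max(abs(pose$translation - truth$translation)), 1e-3)
  expect_lt(attr(pose, "rmse_px"), 1e-8)

  # board parallel to the image plane at a known depth
  corners <- board_corners(board)
  depth <- 1400
  ctr <- c(mean(range(corners$x_mm)), mean(range(corners$y_mm)))
  t_true <- c(-ctr[1], -ctr[2], depth)
  pts <- cbind(corners$x_mm + t_true[1], corners$y_mm + t_true[2], depth)
  px <- project_points(pts, camera_model("c", cam$intrinsics, cam$distortion))
  det <- data.frame(corner_id = corners$corner_id, u_px = px[, 1],
                    v_px = px[, 2])
  pose2 <- estimate_board_pose(board, det, cam$intrinsics, cam$distortion)
  expect_equal(pose2$translation[3], depth, tolerance = 1e-6)

  # with noise, the reprojection residual stays at the noise level
  set.seed(5)
  det$u_px <- det$u_px + rnorm(nrow(det), 0, 0.5)
  det$v_px <- det$v_px + rnorm(nrow(det), 0, 0.5)
  pose3 <- estimate_board_pose(board, det, cam$intrinsics, cam$distortion)
  expect_lt(attr(pose3, "rmse_px"), 0.65)
})

test_that("stereo calibration recovers a known baseline", {
  rig <- make_default_rig()
  sim <- simulate_checkerboard_pass(rig, duration_s = 8, noise_px = 0,
                                    seed = 42, view_stride = 24)
  obs <- sim$board_observations
  board <- board_model()
  st <- calibrate_stereo(obs[obs$camera_id == "cam1", ],
                         obs[obs$camera_id == "cam2", ],
                         board, rig$cameras$cam1$intrinsics,
                         rig$cameras$cam2$intrinsics,
                         rig$cameras$cam1$distortion,
                         rig$cameras$cam2$distortion,
                         camera_a = "cam1", camera_b = "cam2")
  truth <- rig$stereo[["cam1-cam2"]]
  expect_lt(max(abs(st$transform$translation - truth$translation)), 1e-3)
  expect_lt(hydromocap:::rotation_angle_deg(
    t(st$transform$rotation) %*% truth$rotation), 1e-6)
  # the result is a proper rigid transform
  expect_lt(max(abs(crossprod(st$transform$rotation) - diag(3))), 1e-9)
})

test_that("stereo calibration handles degenerate and sparse protocols", {
  rig <- make_default_rig()
  sim <- simulate_checkerboard_pass(rig, duration_s = 8, noise_px = 0.3,
                                    seed = 9, view_stride = 24)
  obs <- sim$board_observations
  board <- board_model()
  o1 <- obs[obs$camera_id == "cam1", ]
  # a camera paired with itself yields the identity
  st_self <- suppressWarnings(
    calibrate_stereo(o1[o1$view_id <= 240, ], o1[o1$view_id <= 240, ], board,
                     rig$cameras$cam1$intrinsics, rig$cameras$cam1$intrinsics,
                     rig$cameras$cam1$distortion, rig$cameras$cam1$distortion,
                     camera_a = "cam1", camera_b = "cam1"))
  expect_lt(max(abs(st_self$transform$translation)), 1e-6)
  expect_lt(max(abs(st_self$transform$rotation - diag(3))), 1e-9)

  # below the recommended 15 shared views: result with a warning
  o2 <- obs[obs$camera_id == "cam2", ]
  keep <- sort(unique(intersect(o1$view_id, o2$view_id)))[1:10]
  expect_warning(
    calibrate_stereo(o1[o1$view_id %in% keep, ], o2[o2$view_id %in% keep, ],
                     board, rig$cameras$cam1$intrinsics,
                     rig$cameras$cam2$intrinsics,
                     rig$cameras$cam1$distortion, rig$cameras$cam2$distortion,
                     camera_a = "cam1", camera_b = "cam2"),
    "at least 15")

  # fewer than 3 shared views is an error
  expect_error(
    calibrate_stereo(o1[o1$view_id %in% keep[1:2], ],
                     o2[o2$view_id %in% keep[1:2], ], board,
                     rig$cameras$cam1$intrinsics, rig$cameras$cam2$intrinsics),
    "at least 3")

  # mis-paired views (shifted clock) trip the consistency gate
  o2_shift <- o2
  vids <- sort(unique(o2$view_id))
  o2_shift$view_id <- vids[match(o2_shift$view_id, vids) %% length(vids) + 1L]
  expect_error(suppressWarnings(
    calibrate_stereo(o1, o2_shift, board,
                     rig$cameras$cam1$intrinsics, rig$cameras$cam2$intrinsics,
                     rig$cameras$cam1$distortion, rig$cameras$cam2$distortion)),
    "mis-synchronized")
})
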