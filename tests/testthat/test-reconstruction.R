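# midpoint of the common perpendicular of the two back-projected rays:
# an independent triangulation oracle
midpoint_oracle <- function(px_a, px_b, K, stereo) {
  Kinv <- solve(K)
  da <- as.numeric(Kinv %*% c(px_a, 1))
  oa <- c(0, 0, 0)
  Rt <- t(stereo$rotation)
  ob <- as.numeric(-Rt %*% stereo$translation)
  db <- as.numeric(Rt %*% Kinv %*% c(px_b, 1))
  # solve min || (oa + s da) - (ob + u db) ||
  A <- cbind(da, -db)
  su <- solve(crossprod(A), crossprod(A, ob - oa))
  ((oa + su[1] * da) + (ob + su[2] * db)) / 2
}

test_that("DLT triangulation is exact for noiseless two-view geometry", {
  intr <- test_intrinsics()
  K <- intrinsic_matrix(intr)
  stereo <- rigid_transform(rodrigues_to_matrix(c(0, 0.05, 0)),
                            c(-500, 5, -10), "a", "b")
  P_a <- K %*% cbind(diag(3), c(0, 0, 0))
  P_b <- K %*% cbind(stereo$rotation, stereo$translation)
  X <- c(123, -45, 1300)
  ha <- P_a %*% c(X, 1); pa <- ha[1:2] / ha[3]
  hb <- P_b %*% c(X, 1); pb <- hb[1:2] / hb[3]
  tri <- triangulate_dlt(pa, pb, P_a, P_b)
  expect_lt(sqrt(sum((tri$point - X)^2)), 1e-6)
  expect_lt(max(tri$residuals_px), 1e-8)
  expect_false(tri$flagged)

  # a point behind both cameras is flagged
  Xb <- c(0, 0, -1000)
  hb_a <- P_a %*% c(Xb, 1); hb_b <- P_b %*% c(Xb, 1)
  tri_b <- triangulate_dlt(hb_a[1:2] / hb_a[3], hb_b[1:2] / hb_b[3], P_a, P_b)
  expect_true(tri_b$flagged)
  expect_true(all(tri_b$depths <= 0))
})

test_that("DLT agrees with the ray-midpoint oracle under noise", {
  set.seed(33)
  intr <- test_intrinsics()
  K <- intrinsic_matrix(intr)
  stereo <- rigid_transform(rodrigues_to_matrix(c(0.01, 0.08, -0.02)),
                            c(-500, 0, 0), "a", "b")
  P_a <- K %*% cbind(diag(3), c(0, 0, 0))
  P_b <- K %*% cbind(stereo$rotation, stereo$translation)
  d <- numeric(1000)
  for (i in 1:1000) {
    X <- c(runif(1, -800, 1200), runif(1, -500, 500), runif(1, 1000, 1800))
    ha <- P_a %*% c(X, 1); pa <- ha[1:2] / ha[3] + rnorm(2, 0, 0.5)
    hb <- P_b %*% c(X, 1); pb <- hb[1:2] / hb[3] + rnorm(2, 0, 0.5)
    tri <- triangulate_dlt(pa, pb, P_a, P_b)
    d[i] <- sqrt(sum((tri$point - midpoint_oracle(pa, pb, K, stereo))^2))
  }
  expect_lt(median(d), 1)
})

test_that("pair reconstruction recovers a simulated limb and honours visibility", {
  rig <- make_default_rig()
  sw <- simulate_swim(rig, n_cycles = 1L, noise_px = 0, seed = 8)
  tr <- suppressWarnings(
    reconstruct_pair(sw$tracks, rig$stereo[["cam1-cam2"]],
                     rig$cameras$cam1, rig$cameras$cam2))
  gt <- sw$ground_truth
  i <- match(paste(tr$frame, tr$label), paste(gt$frame, gt$label))
  err <- sqrt(rowSums((as.matrix(tr[, c("x_mm", "y_mm", "z_mm")]) -
                         as.matrix(gt[i, c("x_mm", "y_mm", "z_mm")]))^2))
  expect_lt(max(err), 1e-6)
  expect_identical(unique(tr$coordinate_frame), "cam1")

  # a label visible in one camera only yields an empty trajectory
  tracks <- sw$tracks[sw$tracks$label == "carpus", ]
  tracks$visible[tracks$camera_id == "cam2"] <- FALSE
  expect_warning(
    out <- reconstruct_pair(tracks, rig$stereo[["cam1-cam2"]],
                            rig$cameras$cam1, rig$cameras$cam2),
    "no common visible frames")
  expect_identical(nrow(out), 0L)

  # alternating visibility: exactly the common frames survive
  tracks <- sw$tracks[sw$tracks$label == "carpus" &
                        sw$tracks$camera_id %in% c("cam1", "cam2"), ]
  odd <- tracks$frame %% 2L == 1L
  tracks$visible[tracks$camera_id == "cam1" & odd] <- FALSE
  keep3 <- tracks$frame %% 3L == 0L
  tracks$visible[tracks$camera_id == "cam2" & !keep3] <- FALSE
  out <- reconstruct_pair(tracks, rig$stereo[["cam1-cam2"]],
                          rig$cameras$cam1, rig$cameras$cam2)
  expected <- sort(intersect(tracks$frame[tracks$camera_id == "cam1" &
                                            tracks$visible],
                             tracks$frame[tracks$camera_id == "cam2" &
                                            tracks$visible]))
  expect_identical(out$frame, expected)
})

test_that("rigid fit recovers exact motions and guards against reflections", {
  A <- matrix(c(0, 0, 0, 1, 0, 0, 0, 1, 0, 0, 0, 1, 1, 1, 1), 5, 3,
              byrow = TRUE) * 100
  t_id <- estimate_transition(A, A)
  expect_lt(max(abs(t_id$rotation - diag(3))), 1e-12)
  expect_lt(attr(t_id, "rms_mm"), 1e-12)

  set.seed(44)
  for (i in 1:20) {
    P <- matrix(rnorm(150), 50, 3) * 200
    R <- rodrigues_to_matrix(rnorm(3))
    tv <- rnorm(3) * 100
    Q <- P %*% t(R) + matrix(tv, 50, 3, byrow = TRUE)
    fit <- estimate_transition(P, Q)
    expect_lt(max(abs(fit$rotation - R)), 1e-9)
    expect_lt(max(abs(fit$translation - tv)), 1e-6)
    expect_lt(attr(fit, "rms_mm"), 1e-9)
  }

  # reflection-only relation: proper rotation returned, residual large
  P <- matrix(rnorm(60), 20, 3) * 100
  Q <- P
  Q[, 1] <- -Q[, 1]
  fit <- estimate_transition(P, Q)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  expect_gt(attr(fit, "rms_mm"), 1)

  expect_error(estimate_transition(P[1:2, ], Q[1:2, ]), "at least 3")
  L <- cbind(1:10, 2 * (1:10), -1 * (1:10))
  expect_error(estimate_transition(L, L), "collinear")
})

test_that("frame unification chains transitions back to the first camera", {
  set.seed(55)
  # ground truth in the first pair's frame
  n <- 40
  gt <- data.frame(frame = rep(0:9, 4),
                   label = rep(c("p", "q", "r", "s"), each = 10),
                   x_mm = rnorm(n) * 300, y_mm = rnorm(n) * 300,
                   z_mm = rnorm(n) * 300 + 1500)
  t21 <- rigid_transform(rodrigues_to_matrix(c(0, 0.3, 0)), c(-900, 10, 0),
                         "pair2", "pair1")
  t32 <- rigid_transform(rodrigues_to_matrix(c(0.1, 0.4, 0)), c(-950, 0, 20),
                         "pair3", "pair2")
  express_in <- function(gt, t_to_first, frame) {
    xyz <- rt_apply(rt_invert(t_to_first),
                    as.matrix(gt[, c("x_mm", "y_mm", "z_mm")]))
    data.frame(frame = gt$frame, label = gt$label, x_mm = xyz[, 1],
               y_mm = xyz[, 2], z_mm = xyz[, 3], coordinate_frame = frame)
  }
  tr1 <- express_in(gt, rt_identity("pair1"), "pair1")
  tr2 <- express_in(gt[gt$frame >= 3, ], t21, "pair2")
  tr3 <- express_in(gt[gt$frame >= 6, ], rt_compose(t32, t21), "pair3")
  uni <- unify_frames(list(tr1, tr2, tr3))
  i <- match(paste(uni$frame, uni$label), paste(gt$frame, gt$label))
  err <- sqrt(rowSums((as.matrix(uni[, c("x_mm", "y_mm", "z_mm")]) -
                         as.matrix(gt[i, c("x_mm", "y_mm", "z_mm")]))^2))
  expect_lt(max(err), 1e-5)
  # chained transition equals the direct composition of the ground truth
  t31 <- attr(uni, "transitions")[["pair3->pair1"]]
  truth <- rt_compose(t32, t21)
  expect_lt(max(abs(t31$rotation - truth$rotation)), 1e-9)
  expect_lt(max(abs(t31$translation - truth$translation)), 1e-6)

  # single pair passes through unchanged
  solo <- unify_frames(list(tr1))
  expect_identical(solo$frame, tr1$frame)
  expect_equal(solo$x_mm, tr1$x_mm)

  # insufficient overlap is an error naming the pair
  expect_error(unify_frames(list(tr1, tr2[tr2$frame == 3 & tr2$label == "p", ])),
               "insufficient overlap")
})

test_that("pairwise distances survive unification and the pool transform", {
  rig <- make_default_rig()
  sw <- simulate_swim(rig, n_cycles = 1L, noise_px = 0.3, seed = 66)
  uni <- reconstruct_and_unify(sw$tracks, rig)
  f <- uni$frame[100]
  at_f <- uni[uni$frame == f, ]
  d0 <- dist(as.matrix(at_f[, c("x_mm", "y_mm", "z_mm")]))
  pw <- simulate_plumb_and_waterline(rig)
  pose <- build_global_frame(pw$plumb, pw$waterline, source_frame = "cam1")
  moved <- rt_apply(pose, as.matrix(at_f[, c("x_mm", "y_mm", "z_mm")]))
  expect_equal(as.numeric(dist(moved)), as.numeric(d0), tolerance = 1e-9)
})

test_that("the pool frame is built from plumb and waterline markers", {
  # plumb already vertical (+z up), waterline along +y: identity rotation
  plumb <- data.frame(line_id = rep(c("a", "b"), each = 2),
                      x_mm = c(0, 0, 500, 500),
                      y_mm = c(0, 0, 100, 100),
                      z_mm = c(1000, 0, 1000, 0))
  waterline <- data.frame(x_mm = c(10, 10, 10), y_mm = c(0, 400, 800),
                          z_mm = c(900, 900, 900))
  pose <- build_global_frame(plumb, waterline, source_frame = "f")
  expect_lt(max(abs(pose$rotation - diag(3))), 1e-12)
  # origin at the first plumb ball
  expect_equal(rt_apply(pose, c(0, 0, 1000)), c(0, 0, 0), tolerance = 1e-12)

  # synthetic rig markers recover the planted pool pose
  rig <- make_default_rig()
  pw <- simulate_plumb_and_waterline(rig)
  pose <- build_global_frame(pw$plumb, pw$waterline, source_frame = "cam1")
  expect_lt(max(abs(pose$rotation - pw$true_pose$rotation)), 1e-9)
  expect_lt(max(abs(pose$translation - pw$true_pose$translation)), 1e-9)
  expect_equal(det(pose$rotation), 1, tolerance = 1e-12)
  # transformed plumb direction is exactly vertical
  up <- as.numeric(pose$rotation %*% c(0, -1, 0))
  expect_equal(up, c(0, 0, 1), tolerance = 1e-12)

  # waterline parallel to the plumb direction is rejected
  bad_water <- data.frame(x_mm = 10, y_mm = 0, z_mm = c(0, 500, 1000))
  expect_error(build_global_frame(plumb, bad_water, source_frame = "f"),
               "parallel")
})

test_that("gap interpolation fills short runs only", {
  tr <- data.frame(frame = c(0L, 2L, 3L), label = "m",
                   x_mm = c(0, 2, 3), y_mm = c(0, 2, 3), z_mm = c(0, 2, 3),
                   coordinate_frame = "f")
  out <- interpolate_gaps(tr, 12L)
  mid <- out[out$frame == 1L, ]
  expect_equal(c(mid$x_mm, mid$y_mm, mid$z_mm), c(1, 1, 1))
  expect_true(mid$interpolated)

  # no gaps: unchanged frames
  out2 <- interpolate_gaps(tr[2:3, ], 12L)
  expect_identical(out2$frame, c(2L, 3L))

  # gaps longer than the cap stay missing
  tr_long <- data.frame(frame = c(0L, 21L), label = "m",
                        x_mm = c(0, 21), y_mm = 0, z_mm = 0,
                        coordinate_frame = "f")
  out3 <- interpolate_gaps(tr_long, 12L)
  expect_identical(out3$frame, c(0L, 21L))
})
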