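test_that("pinhole projection follows similar-triangle arithmetic", {
  cam <- camera_model("c", camera_intrinsics(1000, 1000, 1352, 760))
  expect_equal(project_points(c(0, 0, 1000), cam), c(1352, 760))
  expect_equal(project_points(c(100, 0, 1000), cam), c(1452, 760))
  expect_equal(project_points(c(0, -76, 1000), cam), c(1352, 760 - 76))
  expect_error(project_points(c(0, 0, -5), cam), "behind camera")
  expect_error(project_points(c(0, 0, 0), cam), "behind camera")
})

test_that("distortion matches a step-by-step Brown-Conrady oracle", {
  # oracle: normalize, apply the polynomial, apply intrinsics, separately
  oracle <- function(p, fx, fy, cx, cy, k1 = 0, k2 = 0, k3 = 0,
                     p1 = 0, p2 = 0) {
    xn <- p[1] / p[3]
    yn <- p[2] / p[3]
    r2 <- xn^2 + yn^2
    radial <- 1 + k1 * r2 + k2 * r2^2 + k3 * r2^3
    xd <- xn * radial + 2 * p1 * xn * yn + p2 * (r2 + 2 * xn^2)
    yd <- yn * radial + p1 * (r2 + 2 * yn^2) + 2 * p2 * xn * yn
    c(fx * xd + cx, fy * yd + cy)
  }
  cam <- camera_model("c", camera_intrinsics(800, 810, 1352, 760),
                      lens_distortion(k1 = -0.2))
  expect_equal(project_points(c(100, 50, 800), cam),
               oracle(c(100, 50, 800), 800, 810, 1352, 760, k1 = -0.2),
               tolerance = 1e-12)
  cam2 <- camera_model("c", camera_intrinsics(800, 810, 1352, 760),
                       lens_distortion(k1 = -0.25, k2 = 0.05, k3 = 0.002,
                                       p1 = 0.01, p2 = -0.004))
  expect_equal(project_points(c(-300, 120, 900), cam2),
               oracle(c(-300, 120, 900), 800, 810, 1352, 760,
                      k1 = -0.25, k2 = 0.05, k3 = 0.002,
                      p1 = 0.01, p2 = -0.004),
               tolerance = 1e-12)
})

test_that("undistortion is the exact inverse of the distortion map", {
  intr <- test_intrinsics()
  # zero distortion: identity
  expect_equal(undistort_pixels(c(123.4, 567.8), intr, lens_distortion()),
               c(123.4, 567.8))
  # principal point is a fixed point for any coefficients
  d <- lens_distortion(k1 = -0.3, k2 = 0.08, p1 = 0.01, p2 = -0.02)
  expect_equal(undistort_pixels(c(1352, 760), intr, d), c(1352, 760))
  # round trip distort(undistort(p)) over the image domain
  set.seed(101)
  px <- cbind(runif(1000, 0, 2704), runif(1000, 0, 1520))
  dist <- test_distortion()
  ud <- undistort_pixels(px, intr, dist)
  yn <- (ud[, 2] - intr$cy) / intr$fy
  xn <- (ud[, 1] - intr$cx) / intr$fx
  dd <- hydromocap:::distort_normalized(xn, yn, dist)
  back <- cbind(intr$fx * dd$x + intr$cx, intr$fy * dd$y + intr$cy)
  expect_lt(max(abs(back - px)), 1e-6)
})

test_that("projection matrix equals K[R|t] and matches project()", {
  intr <- test_intrinsics()
  cam_id <- camera_model("c", intr)
  P <- projection_matrix(cam_id)
  expect_equal(P, cbind(intrinsic_matrix(intr), c(0, 0, 0)))
  expect_equal(qr(P)$rank, 3L)
  set.seed(7)
  pose <- rigid_transform(rodrigues_to_matrix(rnorm(3) * 0.2),
                          c(50, -20, 30), "world", "c")
  cam <- camera_model("c", intr, lens_distortion(), pose)
  P <- projection_matrix(cam)
  pts <- cbind(runif(100, -500, 500), runif(100, -300, 300),
               runif(100, 800, 2000))
  h <- cbind(pts, 1) %*% t(P)
  expect_equal(h[, 1:2] / h[, 3], unname(project_points(pts, cam)),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("rigid transforms compose, invert and guard their frame tags", {
  set.seed(11)
  t_ab <- random_rigid()
  round_trip <- rt_compose(t_ab, rt_invert(t_ab))
  expect_lt(max(abs(round_trip$rotation - diag(3))), 1e-12)
  expect_lt(max(abs(round_trip$translation)), 1e-12)
  expect_identical(round_trip$source_frame, "a")

  t_bc <- rigid_transform(rodrigues_to_matrix(rnorm(3)), rnorm(3) * 10,
                          "b", "c")
  chained <- rt_compose(t_ab, t_bc)
  direct <- rigid_transform(t_bc$rotation %*% t_ab$rotation,
                            as.numeric(t_bc$rotation %*% t_ab$translation) +
                              t_bc$translation, "a", "c")
  p <- rnorm(3) * 100
  expect_equal(rt_apply(chained, p), rt_apply(direct, p), tolerance = 1e-12)
  expect_error(rt_compose(t_bc, t_ab), "frame mismatch")

  ident <- rt_identity("b")
  same <- rt_compose(t_ab, ident)
  expect_equal(same$rotation, t_ab$rotation)
  expect_equal(same$translation, t_ab$translation)
})

test_that("orthonormality survives long composition chains", {
  set.seed(13)
  t_acc <- rt_identity("f")
  for (i in 1:100) {
    step <- rigid_transform(rodrigues_to_matrix(rnorm(3)), rnorm(3) * 50,
                            "f", "f")
    t_acc <- rt_compose(t_acc, step)
  }
  expect_lt(max(abs(crossprod(t_acc$rotation) - diag(3))), 1e-9)
  expect_equal(det(t_acc$rotation), 1, tolerance = 1e-9)
})

test_that("projection is invariant under a common rigid motion of camera and scene", {
  set.seed(17)
  intr <- test_intrinsics()
  pose <- rigid_transform(rodrigues_to_matrix(rnorm(3) * 0.3),
                          rnorm(3) * 100, "world", "c")
  cam <- camera_model("c", intr, test_distortion(), pose)
  pts <- cbind(runif(50, -400, 400), runif(50, -250, 250),
               runif(50, 900, 1800))
  g <- rigid_transform(rodrigues_to_matrix(rnorm(3)), rnorm(3) * 200,
                       "world2", "world")
  cam_moved <- camera_model("c", intr, test_distortion(),
                            rt_compose(g, pose))
  expect_equal(project_points(pts, cam),
               project_points(rt_apply(rt_invert(g), pts), cam_moved),
               tolerance = 1e-9)
})

test_that("constructors enforce their invariants", {
  expect_error(camera_intrinsics(-1, 800, 0, 0), "positive")
  expect_error(rigid_transform(matrix(1, 3, 3), c(0, 0, 0)), "orthonormal")
  expect_error(rigid_transform(diag(c(1, 1, -1)), c(0, 0, 0)), "proper")
  expect_error(lens_distortion(k1 = NA), "finite")
})
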