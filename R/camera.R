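#' Pinhole camera intrinsics
#'
#' Focal lengths and principal point are in pixels; the pixel origin is
#' the top-left image corner with u to the right and v down, sub-pixel
#' continuous. The default image size matches a 2.7K sensor (2704 x 1520).
#'
#' @param fx,fy focal lengths in pixels (> 0).
#' @param cx,cy principal point in pixels.
#' @param skew dimensionless skew term (default 0).
#' @param image_width,image_height image size in pixels.
#' @return an object of class `camera_intrinsics`.
#' @export
camera_intrinsics <- function(fx, fy, cx, cy, skew = 0,
                              image_width = 2704L, image_height = 1520L) {
  if (fx <= 0 || fy <= 0) stop("focal lengths must be positive", call. = FALSE)
  image_width <- as.integer(image_width)
  image_height <- as.integer(image_height)
  if (image_width <= 0L || image_height <= 0L) {
    stop("image size must be positive", call. = FALSE)
  }
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy, skew = skew,
                 image_width = image_width, image_height = image_height),
            class = "camera_intrinsics")
}

#' @export
print.camera_intrinsics <- function(x, ...) {
  cat(sprintf("<camera_intrinsics> fx=%.2f fy=%.2f cx=%.2f cy=%.2f skew=%.3g (%dx%d px)\n",
              x$fx, x$fy, x$cx, x$cy, x$skew, x$image_width, x$image_height))
  invisible(x)
}

#' Intrinsic matrix
#'
#' @param intrinsics a `camera_intrinsics` object.
#' @return the upper-triangular 3x3 intrinsic matrix K.
#' @export
intrinsic_matrix <- function(intrinsics) {
  matrix(c(intrinsics$fx, intrinsics$skew, intrinsics$cx,
           0, intrinsics$fy, intrinsics$cy,
           0, 0, 1), 3, 3, byrow = TRUE)
}

#' Brown-Conrady lens distortion coefficients
#'
#' Radial (k1, k2, k3) and tangential (p1, p2) polynomial coefficients
#' acting on normalized (unit focal length) camera coordinates. The
#' all-zero vector is an ideal pinhole.
#'
#' @param k1,k2,k3 radial coefficients.
#' @param p1,p2 tangential coefficients.
#' @return an object of class `lens_distortion`.
#' @export
lens_distortion <- function(k1 = 0, k2 = 0, k3 = 0, p1 = 0, p2 = 0) {
  coefs <- c(k1 = k1, k2 = k2, k3 = k3, p1 = p1, p2 = p2)
  if (any(!is.finite(coefs))) stop("distortion coefficients must be finite", call. = FALSE)
  structure(as.list(coefs), class = "lens_distortion")
}

#' @export
print.lens_distortion <- function(x, ...) {
  cat(sprintf("<lens_distortion> k1=%.4g k2=%.4g k3=%.4g p1=%.4g p2=%.4g\n",
              x$k1, x$k2, x$k3, x$p1, x$p2))
  invisible(x)
}

# apply the distortion polynomial to normalized coordinates (vectorized)
distort_normalized <- function(xn, yn, d) {
  r2 <- xn^2 + yn^2
  radial <- 1 + d$k1 * r2 + d$k2 * r2^2 + d$k3 * r2^3
  xd <- xn * radial + 2 * d$p1 * xn * yn + d$p2 * (r2 + 2 * xn^2)
  yd <- yn * radial + d$p1 * (r2 + 2 * yn^2) + 2 * d$p2 * xn * yn
  list(x = xd, y = yd)
}

#' Camera model
#'
#' Combines intrinsics, distortion and the camera pose. The pose maps the
#' world (or camera-pair) frame into the camera frame, whose convention is
#' optical axis +z, x right, y down.
#'
#' @param camera_id character identifier; also used as the name of the
#'   camera's local coordinate frame.
#' @param intrinsics a `camera_intrinsics`.
#' @param distortion a `lens_distortion` (default: ideal pinhole).
#' @param pose a `rigid_transform` world -> camera; defaults to the
#'   identity with source frame `"world"`.
#' @return an object of class `camera_model`.
#' @export
camera_model <- function(camera_id, intrinsics,
                         distortion = lens_distortion(),
                         pose = NULL) {
  stopifnot(inherits(intrinsics, "camera_intrinsics"),
            inherits(distortion, "lens_distortion"))
  camera_id <- as.character(camera_id)
  if (is.null(pose)) {
    pose <- rigid_transform(diag(3), c(0, 0, 0), "world", camera_id)
  }
  stopifnot(inherits(pose, "rigid_transform"))
  structure(list(camera_id = camera_id, intrinsics = intrinsics,
                 distortion = distortion, pose = pose),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat(sprintf("<camera_model> '%s' (frame '%s' <- '%s')\n",
              x$camera_id, x$pose$target_frame, x$pose$source_frame))
  print(x$intrinsics)
  print(x$distortion)
  invisible(x)
}

# projection without the positive-depth guard; returns pixels and depths
.project_raw <- function(points, camera) {
  pts <- as_point_matrix(points)
  cam_pts <- rt_apply(camera$pose, pts)
  z <- cam_pts[, 3]
  xn <- cam_pts[, 1] / z
  yn <- cam_pts[, 2] / z
  d <- distort_normalized(xn, yn, camera$distortion)
  K <- camera$intrinsics
  u <- K$fx * d$x + K$skew * d$y + K$cx
  v <- K$fy * d$y + K$cy
  list(pixels = cbind(u = u, v = v), depth = z)
}

#' Project world points to pixel coordinates
#'
#' Applies the camera pose, pinhole projection, the distortion polynomial
#' on normalized coordinates, and finally the intrinsics.
#'
#' @param points a 3-vector or n x 3 matrix of world points in mm.
#' @param camera a `camera_model`.
#' @return an n x 2 matrix of (u, v) pixels (a length-2 vector for a
#'   single point).
#' @export
project_points <- function(points, camera) {
  vec <- is.null(dim(points)) && length(points) == 3L
  pr <- .project_raw(points, camera)
  if (any(pr$depth <= 0)) {
    stop("point(s) behind camera '", camera$camera_id,
         "': non-positive depth", call. = FALSE)
  }
  if (vec) as.numeric(pr$pixels) else pr$pixels
}

#' Undistort pixel coordinates
#'
#' Inverts the Brown-Conrady distortion map by damped Newton iteration on
#' normalized coordinates and returns the ideal-pinhole pixel positions.
#'
#' @param pixels a length-2 vector or n x 2 matrix of (u, v) pixels.
#' @param intrinsics a `camera_intrinsics`.
#' @param distortion a `lens_distortion`.
#' @param tol convergence tolerance in normalized units (default 1e-10).
#' @param max_iter maximum Newton iterations (default 50).
#' @return undistorted pixels, same shape as the input.
#' @export
undistort_pixels <- function(pixels, intrinsics, distortion,
                             tol = 1e-10, max_iter = 50L) {
  vec <- is.null(dim(pixels)) && length(pixels) == 2L
  if (vec) pixels <- matrix(pixels, nrow = 1L)
  pixels <- as.matrix(pixels)
  if (any(!is.finite(pixels))) stop("pixels must be finite", call. = FALSE)
  K <- intrinsics
  yd <- (pixels[, 2] - K$cy) / K$fy
  xd <- (pixels[, 1] - K$cx - K$skew * yd) / K$fx
  x <- xd
  y <- yd
  d <- distortion
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    r2 <- x^2 + y^2
    radial <- 1 + d$k1 * r2 + d$k2 * r2^2 + d$k3 * r2^3
    dr <- d$k1 + 2 * d$k2 * r2 + 3 * d$k3 * r2^2  # d(radial)/d(r2)
    fx_ <- x * radial + 2 * d$p1 * x * y + d$p2 * (r2 + 2 * x^2) - xd
    fy_ <- y * radial + d$p1 * (r2 + 2 * y^2) + 2 * d$p2 * x * y - yd
    if (max(abs(c(fx_, fy_))) < tol) {
      converged <- TRUE
      break
    }
    j11 <- radial + 2 * x^2 * dr + 2 * d$p1 * y + 6 * d$p2 * x
    j12 <- 2 * x * y * dr + 2 * d$p1 * x + 2 * d$p2 * y
    j21 <- 2 * x * y * dr + 2 * d$p1 * x + 2 * d$p2 * y
    j22 <- radial + 2 * y^2 * dr + 6 * d$p1 * y + 2 * d$p2 * x
    det_j <- j11 * j22 - j12 * j21
    det_j[abs(det_j) < 1e-15] <- 1e-15
    x <- x - (j22 * fx_ - j12 * fy_) / det_j
    y <- y - (-j21 * fx_ + j11 * fy_) / det_j
  }
  if (!converged) {
    r2 <- x^2 + y^2
    radial <- 1 + d$k1 * r2 + d$k2 * r2^2 + d$k3 * r2^3
    res <- distort_normalized(x, y, d)
    stop(sprintf(
      "undistortion did not converge in %d iterations (last residual %.3g normalized units)",
      max_iter, max(abs(c(res$x - xd, res$y - yd)))), call. = FALSE)
  }
  u <- K$fx * x + K$skew * y + K$cx
  v <- K$fy * y + K$cy
  out <- cbind(u = u, v = v)
  if (vec) as.numeric(out) else out
}

#' Projection matrix of a camera
#'
#' Builds the 3x4 matrix K [R | t] from the camera's intrinsics and pose.
#' The matrix maps homogeneous world points to homogeneous ideal
#' (distortion-free) pixels, so it must only be used with undistorted
#' observations.
#'
#' @param camera a `camera_model`.
#' @return a 3x4 projection matrix.
#' @export
projection_matrix <- function(camera) {
  stopifnot(inherits(camera, "camera_model"))
  intrinsic_matrix(camera$intrinsics) %*%
    cbind(camera$pose$rotation, camera$pose$translation)
}
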