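#' Planar calibration board model
#'
#' Interior-corner grid of an asymmetric checkerboard lying in the z = 0
#' plane of its own frame. The grid must be asymmetric (different numbers
#' of rows and columns) so that board orientation is unambiguous.
#'
#' @param n_rows,n_cols interior corner counts; must differ.
#' @param square_size square edge length in mm.
#' @param origin_offset length-2 offset (mm) of the first interior corner
#'   from the board-frame origin, useful when the physical board extends
#'   beyond the corner grid.
#' @return an object of class `board_model`.
#' @export
board_model <- function(n_rows = 7L, n_cols = 10L, square_size = 60,
                        origin_offset = c(30, 60)) {
  n_rows <- as.integer(n_rows)
  n_cols <- as.integer(n_cols)
  if (n_rows == n_cols) {
    stop("board must be asymmetric: n_rows must differ from n_cols", call. = FALSE)
  }
  if (square_size <= 0) stop("square_size must be positive", call. = FALSE)
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 square_size = square_size,
                 origin_offset = as.numeric(origin_offset)),
            class = "board_model")
}

#' Board-frame coordinates of the interior corners
#'
#' @param board a `board_model`.
#' @return a data.frame with columns `corner_id`, `x_mm`, `y_mm`
#'   (z = 0 implied).
#' @export
board_corners <- function(board) {
  stopifnot(inherits(board, "board_model"))
  grid <- expand.grid(col = seq_len(board$n_cols), row = seq_len(board$n_rows))
  data.frame(
    corner_id = (grid$row - 1L) * board$n_cols + grid$col,
    x_mm = board$origin_offset[1] + (grid$col - 1L) * board$square_size,
    y_mm = board$origin_offset[2] + (grid$row - 1L) * board$square_size
  )
}

# Hartley similarity normalization for DLT conditioning
.normalizing_transform <- function(xy) {
  ctr <- colMeans(xy)
  d <- sqrt(rowSums((xy - matrix(ctr, nrow(xy), 2, byrow = TRUE))^2))
  s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
  matrix(c(s, 0, -s * ctr[1],
           0, s, -s * ctr[2],
           0, 0, 1), 3, 3, byrow = TRUE)
}

.check_not_collinear <- function(xy, what = "points") {
  ctr <- scale(xy, scale = FALSE)
  sv <- svd(ctr)$d
  if (length(sv) < 2L || sv[2] < 1e-8 * max(sv[1], 1)) {
    stop("degenerate configuration: ", what, " are (nearly) collinear",
         call. = FALSE)
  }
}

#' Estimate a planar homography
#'
#' Normalized direct linear estimate of the 3x3 homography mapping plane
#' coordinates (mm) to pixels, minimizing algebraic error. The result is
#' scaled so its bottom-right entry is 1 when that entry is nonzero.
#'
#' @param plane_xy n x 2 matrix of planar points (mm).
#' @param pixels n x 2 matrix of corresponding pixels.
#' @return a 3x3 homography matrix.
#' @export
estimate_homography <- function(plane_xy, pixels) {
  plane_xy <- as.matrix(plane_xy)
  pixels <- as.matrix(pixels)
  if (nrow(plane_xy) != nrow(pixels)) {
    stop("plane_xy and pixels must have the same number of rows", call. = FALSE)
  }
  n <- nrow(plane_xy)
  if (n < 4L) {
    stop("homography estimation needs at least 4 correspondences, got ", n,
         call. = FALSE)
  }
  .check_not_collinear(plane_xy, "plane points")
  T1 <- .normalizing_transform(plane_xy)
  T2 <- .normalizing_transform(pixels)
  p1 <- cbind(plane_xy, 1) %*% t(T1)
  p2 <- cbind(pixels, 1) %*% t(T2)
  X <- p1[, 1]; Y <- p1[, 2]
  u <- p2[, 1]; v <- p2[, 2]
  A <- rbind(
    cbind(X, Y, 1, 0 * X, 0 * X, 0 * X, -u * X, -u * Y, -u),
    cbind(0 * X, 0 * X, 0 * X, X, Y, 1, -v * X, -v * Y, -v)
  )
  sv <- svd(A)
  if (sv$d[8] < 1e-12 * sv$d[1]) {
    stop("degenerate configuration: homography system is rank deficient",
         call. = FALSE)
  }
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(T2) %*% Hn %*% T1
  if (abs(H[3, 3]) > 1e-12) H <- H / H[3, 3]
  H
}

# split a board-observation data.frame into per-view lists joined with
# the board corner coordinates
.split_views <- function(observations, board) {
  req <- c("view_id", "corner_id", "u_px", "v_px")
  missing_cols <- setdiff(req, names(observations))
  if (length(missing_cols)) {
    stop("board observations missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  corners <- board_corners(board)
  views <- split(observations, observations$view_id)
  lapply(views, function(v) {
    if (anyDuplicated(v$corner_id)) {
      stop("duplicate corner_id within view ", v$view_id[1], call. = FALSE)
    }
    idx <- match(v$corner_id, corners$corner_id)
    if (anyNA(idx)) {
      stop("unknown corner_id in view ", v$view_id[1], call. = FALSE)
    }
    list(view_id = v$view_id[1],
         corner_ids = v$corner_id,
         plane = cbind(corners$x_mm[idx], corners$y_mm[idx]),
         pixels = cbind(v$u_px, v$v_px))
  })
}

# Zhang's closed-form intrinsics from a list of plane->pixel homographies
.intrinsics_from_homographies <- function(H_list, image_width, image_height) {
  vfun <- function(H, i, j) {
    c(H[1, i] * H[1, j],
      H[1, i] * H[2, j] + H[2, i] * H[1, j],
      H[2, i] * H[2, j],
      H[3, i] * H[1, j] + H[1, i] * H[3, j],
      H[3, i] * H[2, j] + H[2, i] * H[3, j],
      H[3, i] * H[3, j])
  }
  V <- do.call(rbind, lapply(H_list, function(H) {
    rbind(vfun(H, 1, 2), vfun(H, 1, 1) - vfun(H, 2, 2))
  }))
  b <- svd(V)$v[, 6]
  B11 <- b[1]; B12 <- b[2]; B22 <- b[3]; B13 <- b[4]; B23 <- b[5]; B33 <- b[6]
  den <- B11 * B22 - B12^2
  v0 <- (B12 * B13 - B11 * B23) / den
  lambda <- B33 - (B13^2 + v0 * (B12 * B13 - B11 * B23)) / B11
  alpha2 <- lambda / B11
  beta2 <- lambda * B11 / den
  if (!is.finite(alpha2) || !is.finite(beta2) || alpha2 <= 0 || beta2 <= 0) {
    # noise (or unmodelled distortion) can push the full conic solution
    # non-physical; fall back to focal lengths only, with the principal
    # point fixed at the image centre and zero skew
    fb <- tryCatch(.focals_centered_fallback(H_list, image_width, image_height),
                   error = function(e) NULL)
    if (!is.null(fb)) return(fb)
    # last resort: a generic wide-angle initialization; the subsequent
    # nonlinear refinement has a broad basin of attraction
    return(camera_intrinsics(fx = image_width / 2, fy = image_width / 2,
                             cx = image_width / 2, cy = image_height / 2,
                             skew = 0, image_width = image_width,
                             image_height = image_height))
  }
  alpha <- sqrt(alpha2)
  beta <- sqrt(beta2)
  gamma <- -B12 * alpha^2 * beta / lambda
  u0 <- gamma * v0 / beta - B13 * alpha^2 / lambda
  camera_intrinsics(fx = alpha, fy = beta, cx = u0, cy = v0, skew = 0,
                    image_width = image_width, image_height = image_height)
}

# linear least-squares estimate of (fx, fy) assuming the principal point
# sits at the image centre: the two rotation-column constraints of every
# homography are linear in (1/fx^2, 1/fy^2)
.focals_centered_fallback <- function(H_list, image_width, image_height) {
  cx0 <- image_width / 2
  cy0 <- image_height / 2
  A <- NULL
  y <- NULL
  for (H in H_list) {
    h1 <- c(H[1, 1] - cx0 * H[3, 1], H[2, 1] - cy0 * H[3, 1], H[3, 1])
    h2 <- c(H[1, 2] - cx0 * H[3, 2], H[2, 2] - cy0 * H[3, 2], H[3, 2])
    A <- rbind(A,
               c(h1[1] * h2[1], h1[2] * h2[2]),
               c(h1[1]^2 - h2[1]^2, h1[2]^2 - h2[2]^2))
    y <- c(y, -h1[3] * h2[3], -(h1[3]^2 - h2[3]^2))
  }
  uv <- tryCatch(as.numeric(solve(crossprod(A), crossprod(A, y))),
                 error = function(e) c(NA_real_, NA_real_))
  if (any(!is.finite(uv)) || any(uv <= 0)) {
    stop("degenerate configuration: board views are too similar ",
         "(near-parallel orientations) for intrinsic calibration", call. = FALSE)
  }
  camera_intrinsics(fx = 1 / sqrt(uv[1]), fy = 1 / sqrt(uv[2]),
                    cx = cx0, cy = cy0, skew = 0,
                    image_width = image_width, image_height = image_height)
}

# initial board->camera pose from a plane->pixel homography and K
.pose_from_homography <- function(H, K) {
  A <- solve(K) %*% H
  l1 <- vnorm(A[, 1])
  l2 <- vnorm(A[, 2])
  lambda <- 2 / (l1 + l2)
  r1 <- A[, 1] * lambda
  r2 <- A[, 2] * lambda
  t <- A[, 3] * lambda
  if (t[3] < 0) {
    r1 <- -r1; r2 <- -r2; t <- -t
  }
  R <- orthonormalize_rotation(cbind(r1, r2, cross3(r1, r2)))
  list(rotation = R, translation = t)
}

# reprojection residuals of board corners for one pose (vectorized)
.board_residuals <- function(plane, pixels, R, t, intr, dist) {
  pts <- cbind(plane, 0) %*% t(R) + matrix(t, nrow(plane), 3, byrow = TRUE)
  z <- pts[, 3]
  xn <- pts[, 1] / z
  yn <- pts[, 2] / z
  d <- distort_normalized(xn, yn, dist)
  u <- intr$fx * d$x + intr$skew * d$y + intr$cx
  v <- intr$fy * d$y + intr$cy
  c(pixels[, 1] - u, pixels[, 2] - v)
}

#' Calibrate camera intrinsics from checkerboard views
#'
#' Closed-form initialization from homography constraints on the image of
#' the absolute conic, followed by damped least-squares (Levenberg-
#' Marquardt) refinement of intrinsics, distortion and per-view board
#' poses against total squared reprojection error.
#'
#' The third radial coefficient k3 is only estimated with at least 10
#' views; with fewer it is fixed at 0 to avoid ill-conditioning. Skew is
#' fixed at 0.
#'
#' @param observations data.frame of corner detections with columns
#'   `view_id`, `corner_id`, `u_px`, `v_px` (one camera).
#' @param board a `board_model`.
#' @param image_width,image_height sensor size in pixels.
#' @param max_iter maximum refinement iterations.
#' @return an object of class `intrinsic_calibration`: a list with
#'   elements `intrinsics`, `distortion`, `view_poses` (list of
#'   `rigid_transform`s board -> camera keyed by view), `rmse_px`
#'   (per-coordinate reprojection RMSE in px),
#'   `initial_rmse_px` and `n_views`.
#' @export
calibrate_intrinsics <- function(observations, board,
                                 image_width = 2704L, image_height = 1520L,
                                 max_iter = 200L) {
  views <- .split_views(observations, board)
  n_views <- length(views)
  if (n_views < 3L) {
    stop("intrinsic calibration needs at least 3 views, got ", n_views,
         call. = FALSE)
  }
  H_list <- lapply(views, function(v) estimate_homography(v$plane, v$pixels))
  # focal length is unobservable from near-parallel board orientations:
  # probe the orientation spread with a generic intrinsic guess
  K_probe <- matrix(c(image_width / 2, 0, image_width / 2,
                      0, image_width / 2, image_height / 2,
                      0, 0, 1), 3, 3, byrow = TRUE)
  rots <- lapply(H_list, function(H) .pose_from_homography(H, K_probe)$rotation)
  spread <- 0
  for (i in seq_along(rots)[-1]) {
    spread <- max(spread, rotation_angle_deg(t(rots[[1]]) %*% rots[[i]]))
  }
  if (spread < 3) {
    stop("degenerate configuration: board views are too similar ",
         "(near-parallel orientations) for intrinsic calibration",
         call. = FALSE)
  }
  intr0 <- .intrinsics_from_homographies(H_list, image_width, image_height)
  K0 <- intrinsic_matrix(intr0)
  poses0 <- lapply(H_list, .pose_from_homography, K = K0)
  estimate_k3 <- n_views >= 10L

  pack <- function(intr, dist, poses) {
    p <- c(intr$fx, intr$fy, intr$cx, intr$cy,
           dist$k1, dist$k2, dist$p1, dist$p2)
    if (estimate_k3) p <- c(p, dist$k3)
    for (ps in poses) p <- c(p, matrix_to_rodrigues(ps$rotation), ps$translation)
    p
  }
  unpack <- function(p) {
    intr <- camera_intrinsics(p[1], p[2], p[3], p[4], skew = 0,
                              image_width = image_width,
                              image_height = image_height)
    dist <- lens_distortion(k1 = p[5], k2 = p[6],
                            k3 = if (estimate_k3) p[9] else 0,
                            p1 = p[7], p2 = p[8])
    off <- if (estimate_k3) 9L else 8L
    poses <- vector("list", n_views)
    for (i in seq_len(n_views)) {
      j <- off + (i - 1L) * 6L
      poses[[i]] <- list(rotation = rodrigues_to_matrix(p[j + 1:3]),
                         translation = p[j + 4:6])
    }
    list(intrinsics = intr, distortion = dist, poses = poses)
  }
  resid_fn <- function(p) {
    st <- unpack(p)
    unlist(lapply(seq_len(n_views), function(i) {
      .board_residuals(views[[i]]$plane, views[[i]]$pixels,
                       st$poses[[i]]$rotation, st$poses[[i]]$translation,
                       st$intrinsics, st$distortion)
    }), use.names = FALSE)
  }

  p0 <- pack(intr0, lens_distortion(), poses0)
  r0 <- resid_fn(p0)
  fit <- minpack.lm::nls.lm(
    par = p0, fn = resid_fn,
    control = minpack.lm::nls.lm.control(
      maxiter = max_iter, ftol = 1e-15, ptol = 1e-12, gtol = 0))
  st <- unpack(fit$par)
  r1 <- resid_fn(fit$par)
  view_ids <- vapply(views, function(v) as.character(v$view_id), character(1))
  view_poses <- setNames(lapply(seq_len(n_views), function(i) {
    rigid_transform(st$poses[[i]]$rotation, st$poses[[i]]$translation,
                    paste0("board_view_", view_ids[i]), "camera")
  }), view_ids)
  structure(list(
    intrinsics = st$intrinsics,
    distortion = st$distortion,
    view_poses = view_poses,
    rmse_px = sqrt(mean(r1^2)),  # per-coordinate RMSE
    initial_rmse_px = sqrt(mean(r0^2)),
    n_views = n_views
  ), class = "intrinsic_calibration")
}

#' @export
print.intrinsic_calibration <- function(x, ...) {
  cat(sprintf("<intrinsic_calibration> %d views | reprojection RMSE %.4g px\n",
              x$n_views, x$rmse_px))
  print(x$intrinsics)
  print(x$distortion)
  invisible(x)
}

#' Estimate the pose of a planar board in front of a calibrated camera
#'
#' Initializes from the homography decomposition on undistorted
#' observations and refines the 6-dof pose by reprojection minimization
#' with the full distortion model.
#'
#' @param board a `board_model`.
#' @param detections data.frame with columns `corner_id`, `u_px`, `v_px`.
#' @param intrinsics a `camera_intrinsics`.
#' @param distortion a `lens_distortion`.
#' @param camera_frame name of the camera frame for the returned
#'   transform.
#' @param refine refine by Levenberg-Marquardt (default TRUE).
#' @return a `rigid_transform` board -> camera with attribute
#'   `rmse_px` (reprojection RMSE).
#' @export
estimate_board_pose <- function(board, detections, intrinsics, distortion,
                                camera_frame = "camera", refine = TRUE) {
  corners <- board_corners(board)
  idx <- match(detections$corner_id, corners$corner_id)
  if (anyNA(idx)) stop("unknown corner_id in detections", call. = FALSE)
  if (nrow(detections) < 4L) {
    stop("board pose estimation needs at least 4 corners", call. = FALSE)
  }
  plane <- cbind(corners$x_mm[idx], corners$y_mm[idx])
  pixels <- cbind(detections$u_px, detections$v_px)
  ideal <- undistort_pixels(pixels, intrinsics, distortion)
  # normalized coordinates: strip the intrinsics
  yn <- (ideal[, 2] - intrinsics$cy) / intrinsics$fy
  xn <- (ideal[, 1] - intrinsics$cx - intrinsics$skew * yn) / intrinsics$fx
  H <- estimate_homography(plane, cbind(xn, yn))
  ps <- .pose_from_homography(H, diag(3))
  if (refine) {
    resid_fn <- function(p) {
      .board_residuals(plane, pixels, rodrigues_to_matrix(p[1:3]), p[4:6],
                       intrinsics, distortion)
    }
    fit <- minpack.lm::nls.lm(
      par = c(matrix_to_rodrigues(ps$rotation), ps$translation),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-15,
                                           ptol = 1e-12, gtol = 0))
    ps <- list(rotation = rodrigues_to_matrix(fit$par[1:3]),
               translation = fit$par[4:6])
  }
  out <- rigid_transform(ps$rotation, ps$translation, "board", camera_frame)
  r <- .board_residuals(plane, pixels, ps$rotation, ps$translation,
                        intrinsics, distortion)
  attr(out, "rmse_px") <- sqrt(mean(r^2))
  out
}

#' Stereo (pairwise extrinsic) calibration from shared checkerboard views
#'
#' Per-view relative poses are composed from independent board-pose
#' estimates in each camera, robustly averaged (rotation: quaternion
#' mean; translation: componentwise median), checked for consistency, and
#' finally jointly refined against the reprojection error in both
#' cameras. The recommended protocol uses at least 15 shared views; fewer
#' (down to 3) produce a result with a warning.
#'
#' @param obs_a,obs_b board observations (columns `view_id`, `corner_id`,
#'   `u_px`, `v_px`) from the two cameras; views are matched by
#'   `view_id`.
#' @param board a `board_model`.
#' @param intrinsics_a,intrinsics_b per-camera `camera_intrinsics`.
#' @param distortion_a,distortion_b per-camera `lens_distortion`.
#' @param camera_a,camera_b frame names of the two cameras.
#' @param max_rotation_spread_deg,max_translation_spread_mm consistency
#'   gates on the per-view relative poses; exceeding either aborts with a
#'   hint that the views may be mis-synchronized.
#' @param max_views cap on the number of views entering the joint
#'   refinement (views are subsampled evenly beyond it).
#' @param max_iter refinement iteration cap.
#' @param refine run the joint refinement (default TRUE).
#' @return an object of class `stereo_calibration`: list with `transform`
#'   (`rigid_transform` camera_a -> camera_b), `rmse_px`, `n_views`,
#'   `rotation_spread_deg`, `translation_spread_mm`.
#' @export
calibrate_stereo <- function(obs_a, obs_b, board, intrinsics_a, intrinsics_b,
                             distortion_a = lens_distortion(),
                             distortion_b = lens_distortion(),
                             camera_a = "camera_a", camera_b = "camera_b",
                             max_rotation_spread_deg = 5,
                             max_translation_spread_mm = 100,
                             max_views = 20L, max_iter = 50L, refine = TRUE) {
  views_a <- .split_views(obs_a, board)
  views_b <- .split_views(obs_b, board)
  shared <- intersect(names(views_a), names(views_b))
  if (length(shared) < 3L) {
    stop("stereo calibration needs at least 3 shared views, got ",
         length(shared), call. = FALSE)
  }
  if (length(shared) < 15L) {
    warning("only ", length(shared),
            " shared checkerboard views; the protocol recommends at least 15",
            call. = FALSE)
  }
  # per-view board poses in each camera, then relative camera_a -> camera_b
  # transforms through the board frame
  rel <- vector("list", length(shared))
  poses_a <- vector("list", length(shared))
  for (i in seq_along(shared)) {
    va <- views_a[[shared[i]]]
    vb <- views_b[[shared[i]]]
    pa <- estimate_board_pose(board,
                              data.frame(corner_id = va$corner_ids,
                                         u_px = va$pixels[, 1],
                                         v_px = va$pixels[, 2]),
                              intrinsics_a, distortion_a, camera_frame = camera_a)
    pb <- estimate_board_pose(board,
                              data.frame(corner_id = vb$corner_ids,
                                         u_px = vb$pixels[, 1],
                                         v_px = vb$pixels[, 2]),
                              intrinsics_b, distortion_b, camera_frame = camera_b)
    poses_a[[i]] <- pa
    rel[[i]] <- rt_compose(rt_invert(pa), pb)
  }
  R_bar <- average_rotations(lapply(rel, `[[`, "rotation"))
  t_mat <- do.call(rbind, lapply(rel, `[[`, "translation"))
  t_bar <- apply(t_mat, 2, median)
  rot_dev <- vapply(rel, function(r) {
    rotation_angle_deg(t(R_bar) %*% r$rotation)
  }, numeric(1))
  t_dev <- sqrt(rowSums((t_mat - matrix(t_bar, nrow(t_mat), 3, byrow = TRUE))^2))
  if (max(rot_dev) > max_rotation_spread_deg ||
      max(t_dev) > max_translation_spread_mm) {
    stop(sprintf(paste0(
      "inconsistent per-view relative poses (rotation spread %.2f deg, ",
      "translation spread %.1f mm): the shared views may be mis-synchronized"),
      max(rot_dev), max(t_dev)), call. = FALSE)
  }

  # joint refinement over the relative pose and per-view board poses
  keep <- seq_along(shared)
  if (length(keep) > max_views) {
    keep <- unique(round(seq(1, length(keep), length.out = max_views)))
  }
  plane_a_k <- lapply(keep, function(i) views_a[[shared[i]]]$plane)
  plane_b_k <- lapply(keep, function(i) views_b[[shared[i]]]$plane)
  pix_a_k <- lapply(keep, function(i) views_a[[shared[i]]]$pixels)
  pix_b_k <- lapply(keep, function(i) views_b[[shared[i]]]$pixels)
  n_k <- length(keep)
  resid_fn <- function(p) {
    R_ab <- rodrigues_to_matrix(p[1:3])
    t_ab <- p[4:6]
    unlist(lapply(seq_len(n_k), function(j) {
      o <- 6L + (j - 1L) * 6L
      R_a <- rodrigues_to_matrix(p[o + 1:3])
      t_a <- p[o + 4:6]
      c(.board_residuals(plane_a_k[[j]], pix_a_k[[j]], R_a, t_a,
                         intrinsics_a, distortion_a),
        .board_residuals(plane_b_k[[j]], pix_b_k[[j]],
                         R_ab %*% R_a, as.numeric(R_ab %*% t_a) + t_ab,
                         intrinsics_b, distortion_b))
    }), use.names = FALSE)
  }
  p0 <- c(matrix_to_rodrigues(R_bar), t_bar)
  for (j in seq_len(n_k)) {
    ps <- poses_a[[keep[j]]]
    p0 <- c(p0, matrix_to_rodrigues(ps$rotation), ps$translation)
  }
  if (refine) {
    fit <- minpack.lm::nls.lm(
      par = p0, fn = resid_fn,
      control = minpack.lm::nls.lm.control(maxiter = max_iter, ftol = 1e-14,
                                           ptol = 1e-11, gtol = 0))
    p_fin <- fit$par
  } else {
    p_fin <- p0
  }
  r_fin <- resid_fn(p_fin)
  transform <- rigid_transform(rodrigues_to_matrix(p_fin[1:3]), p_fin[4:6],
                               camera_a, camera_b)
  structure(list(
    transform = transform,
    rmse_px = sqrt(mean(r_fin^2)),
    n_views = length(shared),
    rotation_spread_deg = max(rot_dev),
    translation_spread_mm = max(t_dev)
  ), class = "stereo_calibration")
}

#' @export
print.stereo_calibration <- function(x, ...) {
  cat(sprintf("<stereo_calibration> %s -> %s | %d views | RMSE %.4g px\n",
              x$transform$source_frame, x$transform$target_frame,
              x$n_views, x$rmse_px))
  print(x$transform)
  invisible(x)
}
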