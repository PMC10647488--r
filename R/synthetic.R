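#' Default six-camera poolside rig
#'
#' Six identical wide-angle cameras along one pool wall, equally spaced,
#' optical axes perpendicular to the motion plane. With the default
#' focal length the composite horizontal coverage at the working
#' distance exceeds 2.6 m with ample overlap within and between the
#' camera pairs (1-2, 3-4, 5-6). The rig's world frame coincides with
#' camera 1's local frame ("cam1").
#'
#' @param n_cameras number of cameras (even; default 6).
#' @param spacing_mm horizontal spacing between adjacent cameras.
#' @param distance_mm distance from the cameras to the motion plane.
#' @param fx,fy focal lengths in px (default 800: wide-angle coverage at
#'   2704 x 1520).
#' @param k1,k2 radial distortion of the default lens.
#' @param image_width,image_height sensor size in px.
#' @param frame_rate frames per second (default 120).
#' @return an object of class `camera_rig`: list with `cameras` (named
#'   list of `camera_model`s), `pairs` (list of camera-id pairs),
#'   `stereo` (named list of ground-truth pair transforms), `frame_rate`,
#'   `spacing_mm`, `distance_mm`.
#' @export
make_default_rig <- function(n_cameras = 6L, spacing_mm = 500,
                             distance_mm = 1300, fx = 800, fy = 800,
                             k1 = -0.25, k2 = 0.05,
                             image_width = 2704L, image_height = 1520L,
                             frame_rate = 120) {
  if (spacing_mm <= 0 || distance_mm <= 0) {
    stop("rig geometry must be positive", call. = FALSE)
  }
  n_cameras <- as.integer(n_cameras)
  if (n_cameras < 2L || n_cameras %% 2L != 0L) {
    stop("n_cameras must be an even number >= 2", call. = FALSE)
  }
  ids <- paste0("cam", seq_len(n_cameras))
  intr <- camera_intrinsics(fx, fy, cx = image_width / 2, cy = image_height / 2,
                            image_width = image_width,
                            image_height = image_height)
  dist <- lens_distortion(k1 = k1, k2 = k2)
  cameras <- setNames(lapply(seq_len(n_cameras), function(i) {
    pose <- rigid_transform(diag(3), c(-(i - 1) * spacing_mm, 0, 0),
                            "cam1", ids[i])
    camera_model(ids[i], intr, dist, pose)
  }), ids)
  pairs <- lapply(seq_len(n_cameras / 2L), function(k) {
    ids[c(2L * k - 1L, 2L * k)]
  })
  stereo <- setNames(lapply(pairs, function(p) {
    rt_compose(rt_invert(cameras[[p[1]]]$pose), cameras[[p[2]]]$pose)
  }), vapply(pairs, paste, character(1), collapse = "-"))
  rig <- structure(list(cameras = cameras, pairs = pairs, stereo = stereo,
                        frame_rate = frame_rate, spacing_mm = spacing_mm,
                        distance_mm = distance_mm),
                   class = "camera_rig")
  cov <- rig_coverage(rig)
  for (p in pairs) {
    a <- cov[[p[1]]]; b <- cov[[p[2]]]
    if (min(a[2], b[2]) <= max(a[1], b[1])) {
      stop("rig geometry yields no field-of-view overlap for pair ",
           paste(p, collapse = "-"), call. = FALSE)
    }
  }
  rig
}

#' @export
print.camera_rig <- function(x, ...) {
  cat(sprintf("<camera_rig> %d cameras, spacing %.0f mm, working distance %.0f mm, %g fps\n",
              length(x$cameras), x$spacing_mm, x$distance_mm, x$frame_rate))
  invisible(x)
}

#' Horizontal ground-plane coverage of each rig camera
#'
#' Samples the line (x, 0, distance) in the rig frame and reports, per
#' camera, the interval of x that projects inside the image.
#'
#' @param rig a `camera_rig`.
#' @param distance_mm evaluation distance (default: the rig's working
#'   distance).
#' @return named list of `c(min, max)` coverage intervals in mm.
#' @export
rig_coverage <- function(rig, distance_mm = rig$distance_mm) {
  span <- rig$spacing_mm * (length(rig$cameras) - 1L)
  xs <- seq(-4 * rig$distance_mm, span + 4 * rig$distance_mm, length.out = 4000L)
  pts <- cbind(xs, 0, distance_mm)
  lapply(rig$cameras, function(cam) {
    pr <- .project_raw(pts, cam)
    vis <- pr$depth > 0 &
      pr$pixels[, 1] >= 0 & pr$pixels[, 1] < cam$intrinsics$image_width &
      pr$pixels[, 2] >= 0 & pr$pixels[, 2] < cam$intrinsics$image_height
    range(xs[vis])
  })
}

# project world points for every camera of a rig into a tracks data.frame
.observe_points <- function(rig, world_pts, frames, labels, noise_px) {
  out <- vector("list", length(rig$cameras))
  for (ci in seq_along(rig$cameras)) {
    cam <- rig$cameras[[ci]]
    pr <- .project_raw(world_pts, cam)
    vis <- pr$depth > 0 &
      pr$pixels[, 1] >= 0 & pr$pixels[, 1] < cam$intrinsics$image_width &
      pr$pixels[, 2] >= 0 & pr$pixels[, 2] < cam$intrinsics$image_height
    u <- pr$pixels[, 1]
    v <- pr$pixels[, 2]
    if (noise_px > 0) {
      u <- u + rnorm(length(u), 0, noise_px)
      v <- v + rnorm(length(v), 0, noise_px)
    }
    u[!vis] <- NA_real_
    v[!vis] <- NA_real_
    out[[ci]] <- data.frame(frame = frames, camera_id = cam$camera_id,
                            label = labels, u_px = u, v_px = v,
                            visible = vis)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Simulate a checkerboard sweep through the rig
#'
#' Moves the validation checkerboard along a smooth out-and-back path
#' across the full composite field of view, with gentle rotation and
#' depth variation, projecting both the five reference points (as
#' full-rate marker tracks) and the interior corner grid (as subsampled
#' calibration views) through every camera with distortion. Pixel
#' observations are perturbed by seeded Gaussian noise; points behind a
#' camera or outside its image are invisible.
#'
#' @param rig a `camera_rig`.
#' @param model a `checkerboard_model` with the five reference points.
#' @param board a `board_model` for the corner grid.
#' @param duration_s sweep duration in seconds (default 60).
#' @param noise_px Gaussian pixel-noise standard deviation (>= 0).
#' @param seed RNG seed; fixed seed gives identical output.
#' @param view_stride frame stride between calibration views (default
#'   24, i.e. 5 views per second at 120 fps).
#' @param min_corners_per_view calibration views with fewer visible
#'   corners are dropped (default 20).
#' @return list with `tracks` (reference-point marker tracks),
#'   `board_observations` (corner views), `ground_truth` (reference-point
#'   trajectories in the rig frame) and `frame_rate`.
#' @export
simulate_checkerboard_pass <- function(rig, model = reference_geometry(),
                                       board = board_model(),
                                       duration_s = 60, noise_px = 0.5,
                                       seed = 1L, view_stride = 24L,
                                       min_corners_per_view = 20L) {
  if (noise_px < 0) stop("noise_px must be >= 0", call. = FALSE)
  set.seed(as.integer(seed))
  fps <- rig$frame_rate
  n_frames <- round(duration_s * fps)
  frames <- seq_len(n_frames) - 1L
  t <- frames / fps
  span <- rig$spacing_mm * (length(rig$cameras) - 1L)

  # smooth out-and-back path covering every camera
  cx <- -400 + (span + 800) * (1 - cos(2 * pi * t / duration_s)) / 2
  cy <- 150 * sin(2 * pi * t / 7.3)
  cz <- rig$distance_mm + 120 * sin(2 * pi * t / 5.1)
  yaw <- 20 * pi / 180 * sin(2 * pi * t / 9.7)
  pitch <- 12 * pi / 180 * sin(2 * pi * t / 6.4)

  ref_pts <- model$points  # board-frame, z = 0
  ref_labels <- rownames(ref_pts)
  corners <- board_corners(board)
  corner_pts <- cbind(corners$x_mm, corners$y_mm, 0)
  center <- c(300, 240, 0)

  rot_of <- function(i) {
    cy_ <- cos(yaw[i]); sy_ <- sin(yaw[i])
    cp_ <- cos(pitch[i]); sp_ <- sin(pitch[i])
    Ry <- matrix(c(cy_, 0, sy_, 0, 1, 0, -sy_, 0, cy_), 3, 3, byrow = TRUE)
    Rx <- matrix(c(1, 0, 0, 0, cp_, -sp_, 0, sp_, cp_), 3, 3, byrow = TRUE)
    Rx %*% Ry
  }

  # world coordinates of the reference points at every frame
  n_ref <- nrow(ref_pts)
  world_ref <- matrix(NA_real_, n_frames * n_ref, 3)
  for (i in seq_len(n_frames)) {
    R <- rot_of(i)
    idx <- (i - 1L) * n_ref + seq_len(n_ref)
    world_ref[idx, ] <- (ref_pts - matrix(center, n_ref, 3, byrow = TRUE)) %*%
      t(R) + matrix(c(cx[i], cy[i], cz[i]), n_ref, 3, byrow = TRUE)
  }
  frame_col <- rep(frames, each = n_ref)
  label_col <- rep(ref_labels, n_frames)
  tracks <- .observe_points(rig, world_ref, frame_col, label_col, noise_px)

  ground_truth <- data.frame(frame = frame_col, label = label_col,
                             x_mm = world_ref[, 1], y_mm = world_ref[, 2],
                             z_mm = world_ref[, 3], coordinate_frame = "cam1")

  # subsampled calibration views of the corner grid
  view_frames <- frames[frames %% view_stride == 0L]
  n_c <- nrow(corner_pts)
  obs <- vector("list", length(view_frames) * length(rig$cameras))
  k <- 0L
  for (f in view_frames) {
    i <- f + 1L
    R <- rot_of(i)
    wp <- (corner_pts - matrix(center, n_c, 3, byrow = TRUE)) %*% t(R) +
      matrix(c(cx[i], cy[i], cz[i]), n_c, 3, byrow = TRUE)
    for (cam in rig$cameras) {
      pr <- .project_raw(wp, cam)
      vis <- pr$depth > 0 &
        pr$pixels[, 1] >= 0 & pr$pixels[, 1] < cam$intrinsics$image_width &
        pr$pixels[, 2] >= 0 & pr$pixels[, 2] < cam$intrinsics$image_height
      if (sum(vis) < min_corners_per_view) next
      u <- pr$pixels[vis, 1]
      v <- pr$pixels[vis, 2]
      if (noise_px > 0) {
        u <- u + rnorm(length(u), 0, noise_px)
        v <- v + rnorm(length(v), 0, noise_px)
      }
      k <- k + 1L
      obs[[k]] <- data.frame(view_id = f, camera_id = cam$camera_id,
                             corner_id = corners$corner_id[vis],
                             u_px = u, v_px = v)
    }
  }
  board_observations <- do.call(rbind, obs[seq_len(k)])
  rownames(board_observations) <- NULL
  list(tracks = tracks, board_observations = board_observations,
       ground_truth = ground_truth, frame_rate = fps)
}

#' Simulate single-camera calibration views of a board
#'
#' Generates fully visible checkerboard views at varied poses in front
#' of one camera, spread across the image (including the periphery so
#' that distortion is observable), with optional pixel noise.
#'
#' @param camera a `camera_model` (its pose is ignored; poses are
#'   board -> camera).
#' @param board a `board_model`.
#' @param n_views number of views (default 20).
#' @param noise_px Gaussian pixel noise sd (default 0).
#' @param seed RNG seed.
#' @return list with `observations` (data.frame `view_id`, `corner_id`,
#'   `u_px`, `v_px`) and `poses` (list of true board -> camera
#'   `rigid_transform`s).
#' @export
simulate_calibration_views <- function(camera, board, n_views = 20L,
                                       noise_px = 0, seed = 1L) {
  set.seed(as.integer(seed))
  corners <- board_corners(board)
  pts <- cbind(corners$x_mm, corners$y_mm, 0)
  center <- colMeans(pts)
  intr <- camera$intrinsics
  cam0 <- camera_model(camera$camera_id, intr, camera$distortion)  # identity pose
  obs <- vector("list", n_views)
  poses <- vector("list", n_views)
  for (v in seq_len(n_views)) {
    ok <- FALSE
    for (attempt in seq_len(100L)) {
      shrink <- 0.85^(attempt - 1L)
      yaw <- runif(1, -30, 30) * shrink * pi / 180
      pitch <- runif(1, -25, 25) * shrink * pi / 180
      roll <- runif(1, -15, 15) * pi / 180
      dz <- runif(1, 900, 1600)
      dx <- runif(1, -1.2, 1.2) * dz * shrink
      dy <- runif(1, -0.55, 0.55) * dz * shrink
      R <- rodrigues_to_matrix(c(0, yaw, 0)) %*%
        rodrigues_to_matrix(c(pitch, 0, 0)) %*%
        rodrigues_to_matrix(c(0, 0, roll))
      t_v <- c(dx, dy, dz) - as.numeric(R %*% center)
      cam_pts <- pts %*% t(R) + matrix(t_v, nrow(pts), 3, byrow = TRUE)
      pr <- .project_raw(cam_pts, cam0)
      vis <- pr$depth > 0 &
        pr$pixels[, 1] >= 0 & pr$pixels[, 1] < intr$image_width &
        pr$pixels[, 2] >= 0 & pr$pixels[, 2] < intr$image_height
      if (all(vis)) {
        u <- pr$pixels[, 1]
        v_px <- pr$pixels[, 2]
        if (noise_px > 0) {
          u <- u + rnorm(length(u), 0, noise_px)
          v_px <- v_px + rnorm(length(v_px), 0, noise_px)
        }
        obs[[v]] <- data.frame(view_id = v, corner_id = corners$corner_id,
                               u_px = u, v_px = v_px)
        poses[[v]] <- rigid_transform(R, t_v, paste0("board_view_", v),
                                      camera$camera_id)
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("could not place calibration view ", v, call. = FALSE)
  }
  list(observations = do.call(rbind, obs), poses = poses)
}

#' Articulated limb model with sinusoidal joint trajectories
#'
#' Five rigid segments per limb joined at four joints; each joint angle
#' follows `mean + amplitude * sin(2 pi t / period + phase)`. The
#' default means and amplitudes are set so that the planted maximal
#' flexion (mean - amplitude) and extension (mean + amplitude) match
#' published equine swimming ranges, including hind-fetlock
#' hyperextension above 180 degrees.
#'
#' @param limb `"front"` or `"hind"`.
#' @return an object of class `limb_model`: list with `limb`, `segments`
#'   (named lengths in mm, proximal to distal), `markers` (6 labels) and
#'   `joints` (data.frame `joint`, `mean_deg`, `amplitude_deg`,
#'   `phase_rad`).
#' @export
limb_model <- function(limb = c("front", "hind")) {
  limb <- match.arg(limb)
  if (limb == "front") {
    segments <- c(scapula = 450, humerus = 350, radius = 400,
                  metacarpus = 270, front_digit = 150)
    markers <- c("scapular_spine", "shoulder", "elbow", "carpus",
                 "front_fetlock", "front_hoof")
    joints <- data.frame(
      joint = c("shoulder", "elbow", "carpus", "front_fetlock"),
      mean_deg = c(110.5, 95.5, 118.5, 163),
      amplitude_deg = c(8.5, 37.5, 49.5, 34)
    )
  } else {
    segments <- c(ilium = 400, femur = 450, tibia = 450,
                  metatarsus = 300, hind_digit = 150)
    markers <- c("tuber_coxae", "hip", "stifle", "tarsus",
                 "hind_fetlock", "hind_hoof")
    joints <- data.frame(
      joint = c("hip", "stifle", "tarsus", "hind_fetlock"),
      mean_deg = c(87, 112, 112, 156),
      amplitude_deg = c(20, 34, 50, 47)
    )
  }
  joints$phase_rad <- -0.6 * (seq_len(nrow(joints)) - 1)
  structure(list(limb = limb, segments = segments, markers = markers,
                 joints = joints),
            class = "limb_model")
}

#' @export
print.limb_model <- function(x, ...) {
  cat(sprintf("<limb_model> %s limb: %d segments, markers %s\n", x$limb,
              length(x$segments), paste(x$markers, collapse = ", ")))
  invisible(x)
}

# marker positions of one limb chain at one instant, in the rig frame.
# In-plane directions d(beta) = (cos beta, -sin beta, 0) so that the
# lateral axis (0, 0, -1) measures hyperextension consistently with
# joint_angle() under the pool frame's x axis.
.limb_chain <- function(limb, theta_deg, root, beta1_deg) {
  beta <- beta1_deg * pi / 180
  pos <- matrix(NA_real_, 6, 3)
  pos[1, ] <- root
  for (k in 1:5) {
    d <- c(cos(beta), -sin(beta), 0)
    pos[k + 1, ] <- pos[k, ] + limb$segments[[k]] * d
    if (k <= 4) beta <- beta + pi + theta_deg[k] * pi / 180
  }
  pos
}

#' Simulate a swimming horse limb scene
#'
#' Animates one front and one hind kinematic chain by the limb models'
#' sinusoidal joint trajectories in the sagittal plane, advances the
#' horse at constant speed across the rig with a vertical bob, applies a
#' small out-of-plane wobble about the vertical axis, and projects the
#' twelve markers through every camera with distortion and seeded pixel
#' noise.
#'
#' @param rig a `camera_rig`.
#' @param front,hind `limb_model`s (defaults: [limb_model()]).
#' @param n_cycles number of swim cycles (>= 1).
#' @param cycle_duration_s cycle period in seconds (default 1.5).
#' @param noise_px Gaussian pixel noise sd.
#' @param seed RNG seed.
#' @param wobble_deg out-of-plane wobble amplitude about the vertical
#'   axis through each limb root (default 5).
#' @param bob_mm vertical root oscillation amplitude (default 50).
#' @param root_height_mm height of the limb roots above the optical-axis
#'   plane, in mm (positive up; default 650).
#' @return list with `tracks`, `ground_truth_angles` (the planted
#'   per-joint series), `ground_truth` (marker trajectories in the rig
#'   frame), `frame_rate`.
#' @export
simulate_swim <- function(rig, front = limb_model("front"),
                          hind = limb_model("hind"),
                          n_cycles = 2L, cycle_duration_s = 1.5,
                          noise_px = 0.5, seed = 1L, wobble_deg = 5,
                          bob_mm = 50, root_height_mm = 650) {
  if (n_cycles < 1L) stop("n_cycles must be >= 1", call. = FALSE)
  set.seed(as.integer(seed))
  fps <- rig$frame_rate
  duration <- n_cycles * cycle_duration_s
  n_frames <- round(duration * fps)
  frames <- seq_len(n_frames) - 1L
  t <- frames / fps
  span <- rig$spacing_mm * (length(rig$cameras) - 1L)

  # the whole horse (front root to hind root, 1.3 m apart) sweeps the
  # composite window at constant speed while staying inside it, so every
  # marker is imaged at moderate obliquity and every pair sees the horse
  body_offset <- 1300
  x_front <- (body_offset - 50) + (span + 100 - body_offset) * t / duration
  y_root <- -root_height_mm + bob_mm * sin(2 * pi * t / cycle_duration_s)
  z_plane <- rig$distance_mm

  limbs <- list(front = front, hind = hind)
  root_x_offset <- c(front = 0, hind = -body_offset)
  beta1 <- c(front = -75, hind = -75)

  theta <- list()
  for (nm in names(limbs)) {
    jl <- limbs[[nm]]$joints
    theta[[nm]] <- vapply(seq_len(nrow(jl)), function(j) {
      jl$mean_deg[j] + jl$amplitude_deg[j] *
        sin(2 * pi * t / cycle_duration_s + jl$phase_rad[j])
    }, numeric(n_frames))
  }

  all_pts <- vector("list", length(limbs))
  all_labels <- vector("list", length(limbs))
  for (li in seq_along(limbs)) {
    nm <- names(limbs)[li]
    lm <- limbs[[nm]]
    pts <- matrix(NA_real_, n_frames * 6L, 3)
    for (i in seq_len(n_frames)) {
      root <- c(x_front[i] + root_x_offset[[nm]], y_root[i], z_plane)
      chain <- .limb_chain(lm, theta[[nm]][i, ], root,
                           beta1_deg = beta1[[nm]] +
                             8 * sin(2 * pi * t[i] / cycle_duration_s))
      # out-of-plane wobble about the vertical (world -y) axis through root
      w_ang <- wobble_deg * pi / 180 * sin(2 * pi * t[i] / cycle_duration_s + 0.7)
      Rw <- rodrigues_to_matrix(c(0, -w_ang, 0))
      chain <- (chain - matrix(root, 6, 3, byrow = TRUE)) %*% t(Rw) +
        matrix(root, 6, 3, byrow = TRUE)
      pts[(i - 1L) * 6L + 1:6, ] <- chain
    }
    all_pts[[li]] <- pts
    all_labels[[li]] <- rep(lm$markers, n_frames)
  }
  world_pts <- do.call(rbind, all_pts)
  labels <- unlist(all_labels)
  frame_col <- rep(rep(frames, each = 6L), length(limbs))

  tracks <- .observe_points(rig, world_pts, frame_col, labels, noise_px)

  vis_by_frame <- tapply(tracks$visible, tracks$frame, any)
  if (any(!vis_by_frame)) {
    warning("limb outside all fields of view in ", sum(!vis_by_frame),
            " of ", n_frames, " frames", call. = FALSE)
  }

  gt_angles <- do.call(rbind, lapply(names(limbs), function(nm) {
    jl <- limbs[[nm]]$joints
    do.call(rbind, lapply(seq_len(nrow(jl)), function(j) {
      data.frame(frame = frames, joint = jl$joint[j],
                 angle_deg = theta[[nm]][, j])
    }))
  }))
  ground_truth <- data.frame(frame = frame_col, label = labels,
                             x_mm = world_pts[, 1], y_mm = world_pts[, 2],
                             z_mm = world_pts[, 3], coordinate_frame = "cam1")
  list(tracks = tracks, ground_truth_angles = gt_angles,
       ground_truth = ground_truth, frame_rate = fps)
}

#' Simulate plumb-line and waterline markers defining the pool frame
#'
#' Two weighted vertical plumb lines (two fluorescent balls each, listed
#' top to bottom) and three waterline floats, expressed in the camera-1
#' frame, together with the planted camera-1 -> pool transform they
#' encode (z up, y along the waterline, x completing the trihedron,
#' origin at the first plumb ball).
#'
#' @param rig a `camera_rig`.
#' @return list with `plumb` (data.frame `line_id`, `position`, `x_mm`,
#'   `y_mm`, `z_mm`), `waterline` (data.frame `x_mm`, `y_mm`, `z_mm`)
#'   and `true_pose` (`rigid_transform` cam1 -> pool).
#' @export
simulate_plumb_and_waterline <- function(rig) {
  span <- rig$spacing_mm * (length(rig$cameras) - 1L)
  z <- rig$distance_mm
  plumb <- data.frame(
    line_id = rep(c("plumb1", "plumb2"), each = 2L),
    position = rep(c("top", "bottom"), 2L),
    x_mm = c(200, 200, span - 200, span - 200),
    y_mm = c(-900, 900, -900, 900),
    z_mm = z
  )
  waterline <- data.frame(
    x_mm = c(0, span / 2, span),
    y_mm = -900,
    z_mm = z
  )
  # pool axes in the rig frame: z up = -y, y along travel = +x, x = y x z
  R <- rbind(c(0, 0, -1),
             c(1, 0, 0),
             c(0, -1, 0))
  p0 <- c(plumb$x_mm[1], plumb$y_mm[1], plumb$z_mm[1])
  true_pose <- rigid_transform(R, as.numeric(-R %*% p0), "cam1", "pool")
  list(plumb = plumb, waterline = waterline, true_pose = true_pose)
}

#' Simulate per-camera luminance series with extinction events
#'
#' A baseline-1 luminance with square dips at the scheduled frames,
#' shifted per camera by its planted integer offset, plus Gaussian
#' noise. The default schedule has three extinctions before the segment
#' of interest and one after.
#'
#' @param offsets named integer vector of planted per-camera frame
#'   offsets (names become camera ids).
#' @param schedule event frames (0-based) in the reference clock.
#' @param n_frames series length.
#' @param dip_depth luminance drop (default 0.8, i.e. dips to 0.2).
#' @param dip_frames dip duration in frames (default 6).
#' @param noise_sd Gaussian noise sd (default 0.02).
#' @param seed RNG seed.
#' @param frame_rate fps (default 120).
#' @return named list of `luminance_series`.
#' @export
simulate_luminance <- function(offsets, schedule = c(100L, 250L, 400L, 900L),
                               n_frames = 1200L, dip_depth = 0.8,
                               dip_frames = 6L, noise_sd = 0.02, seed = 1L,
                               frame_rate = 120) {
  stopifnot(!is.null(names(offsets)))
  if (any(offsets != round(offsets))) stop("offsets must be integers", call. = FALSE)
  set.seed(as.integer(seed))
  out <- list()
  for (id in names(offsets)) {
    x <- rep(1, n_frames)
    for (s in schedule + offsets[[id]]) {
      lo <- max(0L, s)
      hi <- min(n_frames - 1L, s + dip_frames - 1L)
      if (lo <= hi) x[(lo:hi) + 1L] <- 1 - dip_depth
    }
    if (noise_sd > 0) x <- x + rnorm(n_frames, 0, noise_sd)
    out[[id]] <- luminance_series(id, x, frame_rate)
  }
  out
}
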