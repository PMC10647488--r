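#' Two-view DLT triangulation
#'
#' Solves the stacked homogeneous linear system of the two projective
#' camera equations by the smallest singular vector and dehomogenizes.
#' Both projection matrices must be expressed in one common coordinate
#' frame (the first camera of the pair) and the pixels must already be
#' undistorted.
#'
#' @param pixel_a,pixel_b length-2 undistorted pixel observations.
#' @param proj_a,proj_b 3x4 projection matrices sharing one frame.
#' @param residual_gate reprojection-residual gate in px; larger
#'   residuals flag (but do not drop) the point. Default 5.
#' @return list with `point` (3-vector, mm), `residuals_px` (length 2),
#'   `depths` (per camera) and `flagged` (logical).
#' @export
triangulate_dlt <- function(pixel_a, pixel_b, proj_a, proj_b,
                            residual_gate = 5) {
  A <- rbind(
    pixel_a[1] * proj_a[3, ] - proj_a[1, ],
    pixel_a[2] * proj_a[3, ] - proj_a[2, ],
    pixel_b[1] * proj_b[3, ] - proj_b[1, ],
    pixel_b[2] * proj_b[3, ] - proj_b[2, ]
  )
  X <- svd(A)$v[, 4]
  if (abs(X[4]) < 1e-12) {
    stop("triangulated point at infinity (homogeneous w ~ 0)", call. = FALSE)
  }
  p <- X[1:3] / X[4]
  reproj <- function(P) {
    h <- as.numeric(P %*% c(p, 1))
    list(px = h[1:2] / h[3], depth = h[3])
  }
  ra <- reproj(proj_a)
  rb <- reproj(proj_b)
  residuals <- c(vnorm(ra$px - pixel_a), vnorm(rb$px - pixel_b))
  depths <- c(ra$depth, rb$depth)
  flagged <- any(residuals > residual_gate) || all(depths <= 0)
  list(point = p, residuals_px = residuals, depths = depths,
       flagged = flagged)
}

# vectorized-ish triangulation of many correspondences (loop over 4x4 SVDs)
.triangulate_many <- function(px_a, px_b, proj_a, proj_b, residual_gate = 5) {
  n <- nrow(px_a)
  pts <- matrix(NA_real_, n, 3)
  res <- matrix(NA_real_, n, 2)
  flag <- logical(n)
  for (i in seq_len(n)) {
    tr <- triangulate_dlt(px_a[i, ], px_b[i, ], proj_a, proj_b, residual_gate)
    pts[i, ] <- tr$point
    res[i, ] <- tr$residuals_px
    flag[i] <- tr$flagged
  }
  list(points = pts, residuals = res, flagged = flag)
}

#' Reconstruct 3D marker trajectories for one camera pair
#'
#' Raw (distorted) synchronized pixel tracks from the two cameras of a
#' pair are undistorted, and every (label, frame) sample visible in both
#' cameras is triangulated. The result is expressed in the pair-local
#' frame, i.e. the local frame of the first camera of the pair.
#'
#' @param tracks marker-track data.frame (columns `frame`, `camera_id`,
#'   `label`, `u_px`, `v_px`, `visible`) containing both cameras.
#' @param stereo `rigid_transform` camera_a -> camera_b (e.g. from
#'   [calibrate_stereo()]).
#' @param camera_a,camera_b `camera_model`s of the pair (poses are
#'   ignored; the pair-local frame is camera_a's).
#' @param residual_gate reprojection gate in px passed to the
#'   triangulator.
#' @param undistorted set TRUE if the tracks are already undistorted.
#' @return trajectory data.frame with columns `frame`, `label`, `x_mm`,
#'   `y_mm`, `z_mm`, `coordinate_frame` plus a `residual_px` column.
#' @export
reconstruct_pair <- function(tracks, stereo, camera_a, camera_b,
                             residual_gate = 5, undistorted = FALSE) {
  stopifnot(inherits(stereo, "rigid_transform"))
  frame_name <- camera_a$camera_id
  ta <- tracks[tracks$camera_id == camera_a$camera_id & as.logical(tracks$visible), ]
  tb <- tracks[tracks$camera_id == camera_b$camera_id & as.logical(tracks$visible), ]
  proj_a <- intrinsic_matrix(camera_a$intrinsics) %*% cbind(diag(3), c(0, 0, 0))
  proj_b <- intrinsic_matrix(camera_b$intrinsics) %*%
    cbind(stereo$rotation, stereo$translation)
  out <- list()
  for (lab in sort(unique(c(ta$label, tb$label)))) {
    a <- ta[ta$label == lab, ]
    b <- tb[tb$label == lab, ]
    common <- intersect(a$frame, b$frame)
    if (length(common) == 0L) {
      warning("no common visible frames for label '", lab, "' in pair ",
              camera_a$camera_id, "-", camera_b$camera_id, call. = FALSE)
      next
    }
    common <- sort(common)
    ia <- match(common, a$frame)
    ib <- match(common, b$frame)
    px_a <- cbind(a$u_px[ia], a$v_px[ia])
    px_b <- cbind(b$u_px[ib], b$v_px[ib])
    if (!undistorted) {
      px_a <- undistort_pixels(px_a, camera_a$intrinsics, camera_a$distortion)
      px_b <- undistort_pixels(px_b, camera_b$intrinsics, camera_b$distortion)
    }
    tri <- .triangulate_many(px_a, px_b, proj_a, proj_b, residual_gate)
    out[[lab]] <- data.frame(
      frame = common, label = lab,
      x_mm = tri$points[, 1], y_mm = tri$points[, 2], z_mm = tri$points[, 3],
      coordinate_frame = frame_name,
      residual_px = pmax(tri$residuals[, 1], tri$residuals[, 2])
    )
  }
  if (length(out) == 0L) {
    return(data.frame(frame = integer(0), label = character(0),
                      x_mm = numeric(0), y_mm = numeric(0), z_mm = numeric(0),
                      coordinate_frame = character(0),
                      residual_px = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Least-squares rigid fit between two corresponding point sets
#'
#' Estimates the proper rigid motion a -> b (no scale) by the
#' cross-covariance singular decomposition with determinant sign
#' correction, so a reflection-only relation still returns a proper
#' rotation (with a large residual).
#'
#' @param points_a,points_b n x 3 matrices of corresponding points (n >=
#'   3, not collinear).
#' @param source_frame,target_frame frame tags for the result.
#' @return a `rigid_transform` a -> b with attribute `rms_mm` (RMS
#'   residual).
#' @export
estimate_transition <- function(points_a, points_b,
                                source_frame = "a", target_frame = "b") {
  pa <- as_point_matrix(points_a, "points_a")
  pb <- as_point_matrix(points_b, "points_b")
  if (nrow(pa) != nrow(pb)) stop("point sets must match in size", call. = FALSE)
  if (nrow(pa) < 3L) {
    stop("rigid fit needs at least 3 correspondences, got ", nrow(pa),
         call. = FALSE)
  }
  sv_a <- svd(scale(pa, scale = FALSE))$d
  if (sv_a[2] < 1e-9 * max(sv_a[1], 1)) {
    stop("degenerate configuration: points are (nearly) collinear", call. = FALSE)
  }
  ca <- colMeans(pa)
  cb <- colMeans(pb)
  H <- crossprod(pa - matrix(ca, nrow(pa), 3, byrow = TRUE),
                 pb - matrix(cb, nrow(pb), 3, byrow = TRUE))
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  t <- cb - as.numeric(R %*% ca)
  out <- rigid_transform(R, t, source_frame, target_frame)
  resid <- rt_apply(out, pa) - pb
  attr(out, "rms_mm") <- sqrt(mean(rowSums(resid^2)))
  out
}

#' Unify camera-pair trajectories into the first pair's frame
#'
#' Adjacent pairs in the chain must share simultaneously reconstructed
#' (label, frame) samples; a rigid transition is estimated per adjacent
#' pair from those shared samples and chained by composition down to the
#' first pair's frame (the first camera of the rig). Samples
#' reconstructed by several pairs are merged by unweighted averaging
#' after transformation.
#'
#' @param pair_trajectories list of trajectory data.frames (as returned
#'   by [reconstruct_pair()]) in chain order; each must carry a single
#'   `coordinate_frame`.
#' @param min_overlap minimum number of shared samples between adjacent
#'   pairs (default 3).
#' @return a unified trajectory data.frame in the first pair's frame,
#'   with the estimated transitions attached as attribute `transitions`.
#' @export
unify_frames <- function(pair_trajectories, min_overlap = 3L) {
  stopifnot(is.list(pair_trajectories), length(pair_trajectories) >= 1L)
  frames <- vapply(pair_trajectories,
                   function(tr) unique(tr$coordinate_frame)[1], character(1))
  n <- length(pair_trajectories)
  if (n == 1L) {
    out <- pair_trajectories[[1]]
    attr(out, "transitions") <- list()
    return(out)
  }
  to_first <- vector("list", n)
  to_first[[1]] <- rt_identity(frames[1])
  transitions <- list()
  for (i in 2:n) {
    prev <- pair_trajectories[[i - 1]]
    cur <- pair_trajectories[[i]]
    key_prev <- paste(prev$label, prev$frame)
    key_cur <- paste(cur$label, cur$frame)
    shared <- intersect(key_prev, key_cur)
    if (length(shared) < min_overlap) {
      stop("insufficient overlap between pair frames '", frames[i - 1],
           "' and '", frames[i], "': ", length(shared),
           " shared samples (need >= ", min_overlap, ")", call. = FALSE)
    }
    ip <- match(shared, key_prev)
    ic <- match(shared, key_cur)
    t_step <- estimate_transition(
      as.matrix(cur[ic, c("x_mm", "y_mm", "z_mm")]),
      as.matrix(prev[ip, c("x_mm", "y_mm", "z_mm")]),
      source_frame = frames[i], target_frame = frames[i - 1])
    to_first[[i]] <- rt_compose(t_step, to_first[[i - 1]])
    transitions[[paste0(frames[i], "->", frames[1])]] <- to_first[[i]]
  }
  moved <- lapply(seq_len(n), function(i) {
    tr <- pair_trajectories[[i]]
    xyz <- rt_apply(to_first[[i]], as.matrix(tr[, c("x_mm", "y_mm", "z_mm")]))
    tr$x_mm <- xyz[, 1]; tr$y_mm <- xyz[, 2]; tr$z_mm <- xyz[, 3]
    tr$coordinate_frame <- frames[1]
    tr
  })
  all_tr <- do.call(rbind, moved)
  # merge duplicated (label, frame) samples by unweighted average
  key <- paste(all_tr$label, all_tr$frame)
  agg <- aggregate(all_tr[, c("x_mm", "y_mm", "z_mm")],
                   by = list(label = all_tr$label, frame = all_tr$frame),
                   FUN = mean)
  out <- data.frame(frame = agg$frame, label = agg$label,
                    x_mm = agg$x_mm, y_mm = agg$y_mm, z_mm = agg$z_mm,
                    coordinate_frame = frames[1])
  out <- out[order(out$label, out$frame), ]
  rownames(out) <- NULL
  attr(out, "transitions") <- transitions
  out
}

#' Build the camera-to-pool global frame from plumb and waterline markers
#'
#' The pool frame has z vertical (up), y horizontal along the waterline
#' and x completing the right-handed trihedron. The plumb lines are
#' weighted, so each line's points run from the floating ball (top) down
#' to the weight: the up direction is first point minus last point.
#'
#' @param plumb data.frame of plumb-line marker positions in the
#'   camera-1 frame with columns `line_id`, `x_mm`, `y_mm`, `z_mm`,
#'   ordered top (ball) to bottom (weight) within each line; at least 2
#'   points per line.
#' @param waterline data.frame of waterline marker positions (columns
#'   `x_mm`, `y_mm`, `z_mm`); at least 2 points.
#' @param source_frame name of the input (camera-1) frame.
#' @param origin which plumb point becomes the pool origin: a row index
#'   into `plumb` (default 1, the first ball).
#' @param min_angle_deg minimum allowed angle between the plumb and
#'   waterline directions (default 5).
#' @return a `rigid_transform` camera-1 -> pool.
#' @export
build_global_frame <- function(plumb, waterline, source_frame = "cam1",
                               origin = 1L, min_angle_deg = 5) {
  lines <- split(plumb, plumb$line_id)
  if (any(vapply(lines, nrow, integer(1)) < 2L)) {
    stop("every plumb line needs at least 2 points", call. = FALSE)
  }
  if (nrow(waterline) < 2L) {
    stop("waterline needs at least 2 points", call. = FALSE)
  }
  ups <- lapply(lines, function(l) {
    unit_vector(as.numeric(l[1L, c("x_mm", "y_mm", "z_mm")]) -
                as.numeric(l[nrow(l), c("x_mm", "y_mm", "z_mm")]))
  })
  z_dir <- unit_vector(Reduce(`+`, ups) / length(ups))
  w <- as.matrix(waterline[, c("x_mm", "y_mm", "z_mm")])
  w_dir <- svd(scale(w, scale = FALSE))$v[, 1]
  # orient along first -> last waterline point
  span <- as.numeric(w[nrow(w), ] - w[1L, ])
  if (sum(w_dir * span) < 0) w_dir <- -w_dir
  if (acos(clamp(abs(sum(w_dir * z_dir)), 0, 1)) * 180 / pi < min_angle_deg) {
    stop("plumb and waterline directions are within ", min_angle_deg,
         " degrees of parallel", call. = FALSE)
  }
  y_dir <- unit_vector(w_dir - sum(w_dir * z_dir) * z_dir)
  x_dir <- cross3(y_dir, z_dir)
  R <- rbind(x_dir, y_dir, z_dir)
  rownames(R) <- NULL
  p0 <- as.numeric(plumb[origin, c("x_mm", "y_mm", "z_mm")])
  rigid_transform(R, as.numeric(-R %*% p0), source_frame, "pool")
}

#' Fill short gaps in a trajectory by linear interpolation
#'
#' Missing runs of at most `max_gap_frames` between observed frames are
#' filled per label and coordinate; longer gaps are left missing. The
#' default of 12 frames is about 0.1 s at 120 fps.
#'
#' @param trajectory trajectory data.frame (columns `frame`, `label`,
#'   `x_mm`, `y_mm`, `z_mm`, `coordinate_frame`).
#' @param max_gap_frames maximum interior gap length to fill (>= 0).
#' @return the trajectory with interpolated rows added (column
#'   `interpolated` marks them).
#' @export
interpolate_gaps <- function(trajectory, max_gap_frames = 12L) {
  if (max_gap_frames < 0L) stop("max_gap_frames must be >= 0", call. = FALSE)
  pieces <- lapply(split(trajectory, trajectory$label), function(tr) {
    tr <- tr[order(tr$frame), ]
    tr$interpolated <- FALSE
    if (nrow(tr) < 2L || max_gap_frames == 0L) return(tr)
    gaps <- diff(tr$frame) - 1L
    fill_at <- which(gaps >= 1L & gaps <= max_gap_frames)
    if (!length(fill_at)) return(tr)
    new_frames <- unlist(lapply(fill_at, function(i) {
      (tr$frame[i] + 1L):(tr$frame[i + 1L] - 1L)
    }))
    filled <- data.frame(
      frame = new_frames, label = tr$label[1],
      x_mm = approx(tr$frame, tr$x_mm, xout = new_frames)$y,
      y_mm = approx(tr$frame, tr$y_mm, xout = new_frames)$y,
      z_mm = approx(tr$frame, tr$z_mm, xout = new_frames)$y,
      coordinate_frame = tr$coordinate_frame[1],
      interpolated = TRUE
    )
    for (col in setdiff(names(tr), names(filled))) filled[[col]] <- NA
    out <- rbind(tr, filled[, names(tr), drop = FALSE])
    out[order(out$frame), ]
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
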