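#' Canonical equine joint definitions
#'
#' The eight joint angles computed from the six anatomical markers per
#' limb: each joint is defined by a proximal marker, the vertex marker
#' and a distal marker. Front limb: shoulder (scapular spine - shoulder -
#' elbow), elbow, carpus, front fetlock; hind limb: hip (tuber coxae -
#' hip - stifle), stifle, tarsus, hind fetlock.
#'
#' @return data.frame with columns `joint`, `limb`, `proximal`, `vertex`,
#'   `distal`.
#' @export
joint_definitions <- function() {
  data.frame(
    joint = c("shoulder", "elbow", "carpus", "front_fetlock",
              "hip", "stifle", "tarsus", "hind_fetlock"),
    limb = rep(c("front", "hind"), each = 4L),
    proximal = c("scapular_spine", "shoulder", "elbow", "carpus",
                 "tuber_coxae", "hip", "stifle", "tarsus"),
    vertex = c("shoulder", "elbow", "carpus", "front_fetlock",
               "hip", "stifle", "tarsus", "hind_fetlock"),
    distal = c("elbow", "carpus", "front_fetlock", "front_hoof",
               "stifle", "tarsus", "hind_fetlock", "hind_hoof")
  )
}

# vectorized signed joint angle; inputs are n x 3 matrices
.joint_angle_rows <- function(prox, vertex, dist, lateral_axis) {
  v1 <- prox - vertex
  v2 <- dist - vertex
  n1 <- sqrt(rowSums(v1^2))
  n2 <- sqrt(rowSums(v2^2))
  if (any(n1 < 1e-9) || any(n2 < 1e-9)) {
    stop("zero-length limb vector at a joint", call. = FALSE)
  }
  theta <- acos(clamp(rowSums(v1 * v2) / (n1 * n2), -1, 1)) * 180 / pi
  s <- as.numeric(cross3_rows(v1, v2) %*% lateral_axis)
  ifelse(s < 0, 360 - theta, theta)
}

#' Anatomical joint angle with hyperextension handling
#'
#' The unsigned angle between the proximal and distal limb vectors at
#' the vertex lies in \[0, 180\] degrees; the sign of the cross product
#' of the two vectors against a lateral (medio-lateral) reference axis
#' decides whether the joint is hyperextended, in which case 360 minus
#' the unsigned angle is returned. This allows fetlock extensions above
#' 180 degrees. Smaller angles mean more flexion.
#'
#' @param p_prox,p_vertex,p_dist 3-vectors (mm).
#' @param lateral_axis unit 3-vector; defaults to the pool-frame x axis,
#'   appropriate when the motion is mainly sagittal.
#' @return the joint angle in degrees, in (0, 360).
#' @export
joint_angle <- function(p_prox, p_vertex, p_dist, lateral_axis = c(1, 0, 0)) {
  .joint_angle_rows(matrix(p_prox, 1), matrix(p_vertex, 1), matrix(p_dist, 1),
                    as.numeric(lateral_axis))
}

#' Per-frame joint-angle series from marker trajectories
#'
#' Computes each joint's angle at every frame where all three of its
#' markers are present. All trajectories must share one coordinate
#' frame.
#'
#' @param trajectories trajectory data.frame (columns `frame`, `label`,
#'   `x_mm`, `y_mm`, `z_mm`, optionally `coordinate_frame`).
#' @param definitions joint definitions (default [joint_definitions()]);
#'   rows whose markers are entirely absent from the data are skipped
#'   unless `strict`.
#' @param lateral_axis hyperextension reference axis (see
#'   [joint_angle()]).
#' @param strict error (naming the joint) if any marker of a defined
#'   joint is missing from the trajectories (default TRUE).
#' @return long data.frame with columns `frame`, `joint`, `angle_deg`.
#' @export
joint_angle_series <- function(trajectories, definitions = joint_definitions(),
                               lateral_axis = c(1, 0, 0), strict = TRUE) {
  if ("coordinate_frame" %in% names(trajectories)) {
    frames <- unique(trajectories$coordinate_frame)
    if (length(frames) > 1L) {
      stop("trajectories span several coordinate frames: ",
           paste(frames, collapse = ", "), call. = FALSE)
    }
  }
  labs <- unique(trajectories$label)
  out <- list()
  for (i in seq_len(nrow(definitions))) {
    d <- definitions[i, ]
    markers <- c(d$proximal, d$vertex, d$distal)
    if (!all(markers %in% labs)) {
      if (strict) {
        stop("joint '", d$joint, "' is missing marker(s): ",
             paste(setdiff(markers, labs), collapse = ", "), call. = FALSE)
      }
      next
    }
    tp <- trajectories[trajectories$label == d$proximal, ]
    tv <- trajectories[trajectories$label == d$vertex, ]
    td <- trajectories[trajectories$label == d$distal, ]
    common <- sort(intersect(intersect(tp$frame, tv$frame), td$frame))
    if (!length(common)) next
    xyz <- function(tr) as.matrix(tr[match(common, tr$frame),
                                     c("x_mm", "y_mm", "z_mm")])
    out[[d$joint]] <- data.frame(
      frame = common, joint = d$joint,
      angle_deg = .joint_angle_rows(xyz(tp), xyz(tv), xyz(td),
                                    as.numeric(lateral_axis))
    )
  }
  res <- if (length(out)) do.call(rbind, out) else {
    data.frame(frame = integer(0), joint = character(0), angle_deg = numeric(0))
  }
  rownames(res) <- NULL
  res
}

#' Optional low-pass filtering of an angle series
#'
#' Zero-phase 4th-order Butterworth filter; off by default in the
#' pipeline since the reconstruction applies no smoothing.
#'
#' @param angle_deg numeric angle series (regularly sampled).
#' @param frame_rate sampling rate in fps.
#' @param cutoff_hz low-pass cutoff (default 6 Hz).
#' @return the filtered series.
#' @export
smooth_angle_series <- function(angle_deg, frame_rate = 120, cutoff_hz = 6) {
  x <- as.numeric(angle_deg)
  n <- length(x)
  bf <- signal::butter(4, cutoff_hz / (frame_rate / 2), type = "low")
  # odd-reflection padding suppresses the zero-phase filter's edge
  # transients (the same convention as scipy's filtfilt padtype = "odd")
  p <- min(n - 1L, 3L * ceiling(frame_rate / cutoff_hz))
  if (p > 0L) {
    head_pad <- 2 * x[1] - x[(p + 1L):2L]
    tail_pad <- 2 * x[n] - x[(n - 1L):(n - p)]
    xf <- signal::filtfilt(bf, c(head_pad, x, tail_pad))
    as.numeric(xf[(p + 1L):(p + n)])
  } else {
    as.numeric(signal::filtfilt(bf, x))
  }
}

#' Summarize a joint-angle series into flexion, extension and ROM
#'
#' Maximal flexion is the series minimum (smaller angle = more flexed),
#' maximal extension the maximum, and the range of motion their
#' difference.
#'
#' @param series numeric vector of angles in degrees, or a data.frame
#'   with columns `joint` and `angle_deg` (one row per joint is then
#'   returned).
#' @return for a vector: a list with `maximal_flexion`,
#'   `maximal_extension`, `rom` (class `rom_summary`); for a data.frame:
#'   a data.frame with those columns per joint.
#' @export
summarize_rom <- function(series) {
  if (is.data.frame(series)) {
    stopifnot(all(c("joint", "angle_deg") %in% names(series)))
    if (nrow(series) == 0L) stop("empty angle series", call. = FALSE)
    parts <- lapply(split(series$angle_deg, series$joint), function(a) {
      s <- summarize_rom(a)
      data.frame(maximal_flexion = s$maximal_flexion,
                 maximal_extension = s$maximal_extension, rom = s$rom)
    })
    out <- do.call(rbind, parts)
    out <- cbind(joint = rownames(out), out)
    rownames(out) <- NULL
    return(out)
  }
  a <- as.numeric(series)
  if (!length(a)) stop("empty angle series", call. = FALSE)
  structure(list(maximal_flexion = min(a), maximal_extension = max(a),
                 rom = max(a) - min(a)),
            class = "rom_summary")
}

#' @export
print.rom_summary <- function(x, ...) {
  cat(sprintf("<rom_summary> flexion %.2f deg | extension %.2f deg | ROM %.2f deg\n",
              x$maximal_flexion, x$maximal_extension, x$rom))
  invisible(x)
}

#' Detect limb cycles from extension peaks of an angle series
#'
#' Cycle boundaries are successive maxima (extension peaks) separated by
#' at least `min_period_s`; durations are the inter-peak intervals in
#' seconds. Constant or near-constant series yield no cycles.
#'
#' @param angle_deg numeric angle series, regularly sampled.
#' @param frames 0-based frame indices of the samples (default
#'   `seq_along(angle_deg) - 1`).
#' @param min_period_s minimum cycle period in seconds (default 0.5).
#' @param frame_rate sampling rate in fps (default 120).
#' @param min_prominence minimum peak height above the series median as
#'   a fraction of the series range (default 0.1).
#' @return list with `boundaries` (peak frames) and `durations_s`;
#'   fewer than 2 peaks yields empty results with a warning.
#' @export
detect_cycles <- function(angle_deg, frames = seq_along(angle_deg) - 1L,
                          min_period_s = 0.5, frame_rate = 120,
                          min_prominence = 0.1) {
  x <- as.numeric(angle_deg)
  n <- length(x)
  rng <- diff(range(x))
  empty <- list(boundaries = integer(0), durations_s = numeric(0))
  if (n < 3L || rng < 1e-9) {
    warning("no cycles detected (series too short or constant)", call. = FALSE)
    return(empty)
  }
  w <- max(1L, floor(min_period_s * frame_rate / 2))
  height_min <- median(x) + min_prominence * rng
  cand <- which(vapply(seq_len(n), function(i) {
    lo <- max(1L, i - w)
    hi <- min(n, i + w)
    x[i] >= height_min && x[i] == max(x[lo:hi]) &&
      (i == 1L || x[i - 1L] <= x[i])  # take the first sample of plateaus
  }, logical(1)))
  # collapse plateaus: keep the first index of runs of equal height
  if (length(cand) > 1L) {
    keep <- c(TRUE, diff(cand) > 1L | x[cand[-1]] != x[cand[-length(cand)]])
    cand <- cand[keep]
  }
  # enforce separation greedily by peak height
  min_sep <- ceiling(min_period_s * frame_rate)
  accepted <- integer(0)
  for (i in cand[order(-x[cand])]) {
    if (!length(accepted) || all(abs(i - accepted) >= min_sep)) {
      accepted <- c(accepted, i)
    }
  }
  accepted <- sort(accepted)
  if (length(accepted) < 2L) {
    warning("fewer than 2 extension peaks found; no cycles detected",
            call. = FALSE)
    return(empty)
  }
  boundaries <- frames[accepted]
  list(boundaries = as.integer(boundaries),
       durations_s = diff(boundaries) / frame_rate)
}
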