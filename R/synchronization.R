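#' Per-camera luminance time series
#'
#' Mean image luminance per frame (arbitrary units, nominally 0-1), used
#' to detect the lighting-extinction events that synchronize the camera
#' clocks. Frames are 0-based.
#'
#' @param camera_id character identifier.
#' @param values numeric luminance per frame.
#' @param frame_rate frames per second (default 120).
#' @return an object of class `luminance_series`.
#' @export
luminance_series <- function(camera_id, values, frame_rate = 120) {
  values <- as.numeric(values)
  if (length(values) < 1L) stop("luminance series must be non-empty", call. = FALSE)
  if (frame_rate <= 0) stop("frame_rate must be positive", call. = FALSE)
  structure(list(camera_id = as.character(camera_id), values = values,
                 frame_rate = frame_rate),
            class = "luminance_series")
}

#' Detect lighting-extinction events in a luminance series
#'
#' Events are falling edges where the luminance drops below
#' `median - k * MAD` of the whole series. The robust threshold ignores
#' the bright moving foreground; a constant series yields no events. The
#' first frame (0-based) of each low excursion is reported, and events
#' closer than `min_separation_s` to the previous one are merged.
#' Excursions shorter than `min_duration_frames` are treated as noise: a
#' genuine lighting extinction spans several frames at 120 fps.
#'
#' @param series a `luminance_series` (or plain numeric vector).
#' @param k threshold multiplier on the MAD (default 5).
#' @param min_separation_s minimum inter-event separation in seconds
#'   (default 0.5).
#' @param min_duration_frames minimum excursion length in frames
#'   (default 2).
#' @param frame_rate frame rate, used when `series` is a bare vector.
#' @return integer vector of 0-based event frame indices (possibly
#'   empty).
#' @export
detect_extinction_events <- function(series, k = 5, min_separation_s = 0.5,
                                     min_duration_frames = 2L,
                                     frame_rate = 120) {
  if (inherits(series, "luminance_series")) {
    x <- series$values
    frame_rate <- series$frame_rate
  } else {
    x <- as.numeric(series)
  }
  if (length(x) < 10L) stop("luminance series too short (need >= 10 frames)",
                            call. = FALSE)
  thr <- median(x) - k * mad(x)
  below <- x < thr
  if (!any(below)) return(integer(0))
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  long_enough <- r$values & r$lengths >= min_duration_frames
  if (!any(long_enough)) return(integer(0))
  onsets <- starts[long_enough] - 1L  # 0-based
  min_sep <- ceiling(min_separation_s * frame_rate)
  keep <- onsets[1]
  for (f in onsets[-1]) {
    if (f - keep[length(keep)] >= min_sep) keep <- c(keep, f)
  }
  as.integer(keep)
}

#' Synchronization result
#'
#' @param reference_camera_id camera whose clock is the common reference.
#' @param offsets named integer vector of per-camera frame offsets
#'   (reference camera has offset 0).
#' @param events named list of per-camera detected event frames.
#' @return an object of class `sync_result`.
#' @export
sync_result <- function(reference_camera_id, offsets, events) {
  if (offsets[[reference_camera_id]] != 0L) {
    stop("reference camera must have offset 0", call. = FALSE)
  }
  structure(list(reference_camera_id = reference_camera_id,
                 offsets = offsets, events = events),
            class = "sync_result")
}

#' @export
print.sync_result <- function(x, ...) {
  cat("<sync_result> reference:", x$reference_camera_id, "\n")
  for (id in names(x$offsets)) {
    cat(sprintf("  %s: offset %+d (events: %s)\n", id, x$offsets[[id]],
                paste(x$events[[id]], collapse = ", ")))
  }
  invisible(x)
}

#' Synchronize camera clocks from detected extinction events
#'
#' Each camera's integer frame offset is the difference between its first
#' event frame and the reference camera's. All cameras must report the
#' same number of events, and the inter-event gaps must agree across
#' cameras within `gap_tolerance` frames — with 4 events this matches the
#' three-extinctions-before / one-after acquisition pattern. If more than
#' 4 events are present, the first window of 4 whose gaps are consistent
#' across all cameras is used.
#'
#' @param events named list of integer event-frame vectors, one per
#'   camera.
#' @param reference_camera_id camera defining the common clock (default:
#'   the first in `events`).
#' @param gap_tolerance allowed inter-event gap disagreement in frames
#'   (default 2).
#' @return a `sync_result`.
#' @export
synchronize <- function(events, reference_camera_id = names(events)[1],
                        gap_tolerance = 2L) {
  if (is.null(names(events)) || any(names(events) == "")) {
    stop("events must be a named list keyed by camera_id", call. = FALSE)
  }
  if (!reference_camera_id %in% names(events)) {
    stop("unknown reference camera '", reference_camera_id, "'", call. = FALSE)
  }
  counts <- vapply(events, length, integer(1))
  if (any(counts < 1L)) {
    stop("camera(s) with no detected events: ",
         paste(names(events)[counts < 1L], collapse = ", "), call. = FALSE)
  }
  if (length(unique(counts)) != 1L) {
    bad <- names(events)[counts != counts[[reference_camera_id]]]
    stop("mismatched event counts; offending camera(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- counts[[1]]
  if (n > 4L) {
    # use the first window of 4 with gaps consistent across all cameras
    ref <- events[[reference_camera_id]]
    found <- FALSE
    for (s in seq_len(n - 3L)) {
      win <- s:(s + 3L)
      gaps_ref <- diff(ref[win])
      ok <- all(vapply(events, function(e) {
        all(abs(diff(e[win]) - gaps_ref) <= gap_tolerance)
      }, logical(1)))
      if (ok) {
        events <- lapply(events, function(e) e[win])
        found <- TRUE
        break
      }
    }
    if (!found) {
      stop("no window of 4 events with consistent gaps across cameras",
           call. = FALSE)
    }
  }
  ref_events <- events[[reference_camera_id]]
  gaps_ref <- diff(ref_events)
  bad <- names(events)[vapply(events, function(e) {
    length(gaps_ref) > 0L && any(abs(diff(e) - gaps_ref) > gap_tolerance)
  }, logical(1))]
  if (length(bad)) {
    stop("inconsistent inter-event gaps for camera(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  offsets <- vapply(events, function(e) as.integer(e[1] - ref_events[1]),
                    integer(1))
  sync_result(reference_camera_id, offsets, events)
}

#' Re-base marker tracks onto the common synchronized clock
#'
#' Subtracts each camera's offset from its frame indices. Frames that
#' fall before the start of the common clock (index < 0) are marked
#' invisible.
#'
#' @param tracks marker-track data.frame with columns `frame`,
#'   `camera_id`, `label`, `u_px`, `v_px`, `visible`.
#' @param sync a `sync_result` covering every camera present in `tracks`.
#' @return the tracks with shifted `frame` indices.
#' @export
apply_offsets <- function(tracks, sync) {
  stopifnot(inherits(sync, "sync_result"))
  unknown <- setdiff(unique(tracks$camera_id), names(sync$offsets))
  if (length(unknown)) {
    stop("camera_id(s) not present in sync result: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  tracks$frame <- tracks$frame - unname(sync$offsets[tracks$camera_id])
  tracks$visible <- tracks$visible & tracks$frame >= 0L
  tracks
}
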