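# CSV dialects used throughout the pipeline. All frame indices are
# 0-based; numeric fields round-trip at full double precision.

.write_csv_precise <- function(df, path) {
  fm <- df
  for (col in names(fm)) {
    if (is.double(fm[[col]])) {
      v <- sprintf("%.17g", fm[[col]])
      v[is.na(fm[[col]])] <- NA
      fm[[col]] <- v
    }
  }
  utils::write.table(fm, path, sep = ",", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}

.read_checked <- function(path, required, numeric_cols, what) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop(what, " file is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  extra <- setdiff(names(df), required)
  if (length(extra)) {
    warning("ignoring unknown column(s) in ", what, " file: ",
            paste(extra, collapse = ", "), call. = FALSE)
    df <- df[required]
  }
  for (col in intersect(numeric_cols, names(df))) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df
}

#' Read and write 2D marker tracks
#'
#' Columns: `frame` (int, 0-based), `camera_id`, `label`, `u_px`,
#' `v_px`, `visible` (0/1). Duplicate (camera_id, label, frame) rows are
#' rejected.
#'
#' @param path CSV file path.
#' @return the tracks data.frame (with logical `visible`).
#' @export
read_tracks <- function(path) {
  df <- .read_checked(path, c("frame", "camera_id", "label", "u_px", "v_px",
                              "visible"),
                      c("u_px", "v_px"), "tracks")
  df$frame <- as.integer(df$frame)
  df$visible <- as.logical(as.integer(df$visible))
  if (anyDuplicated(df[c("camera_id", "label", "frame")])) {
    stop("duplicate (camera_id, label, frame) rows in tracks file",
         call. = FALSE)
  }
  df
}

#' @rdname read_tracks
#' @param tracks tracks data.frame.
#' @export
write_tracks <- function(tracks, path) {
  out <- tracks[c("frame", "camera_id", "label", "u_px", "v_px", "visible")]
  out$visible <- as.integer(as.logical(out$visible))
  .write_csv_precise(out, path)
}

#' Read and write 3D trajectories
#'
#' Columns: `frame`, `label`, `x_mm`, `y_mm`, `z_mm`,
#' `coordinate_frame`.
#'
#' @param path CSV file path.
#' @return trajectory data.frame.
#' @export
read_trajectories <- function(path) {
  df <- .read_checked(path, c("frame", "label", "x_mm", "y_mm", "z_mm",
                              "coordinate_frame"),
                      c("x_mm", "y_mm", "z_mm"), "trajectory")
  df$frame <- as.integer(df$frame)
  df
}

#' @rdname read_trajectories
#' @param trajectories trajectory data.frame.
#' @export
write_trajectories <- function(trajectories, path) {
  .write_csv_precise(trajectories[c("frame", "label", "x_mm", "y_mm", "z_mm",
                                    "coordinate_frame")], path)
}

#' Read and write joint-angle series
#'
#' Columns: `frame`, `joint`, `angle_deg`.
#'
#' @param path CSV file path.
#' @return angle data.frame.
#' @export
read_angles <- function(path) {
  df <- .read_checked(path, c("frame", "joint", "angle_deg"), "angle_deg",
                      "angles")
  df$frame <- as.integer(df$frame)
  df
}

#' @rdname read_angles
#' @param angles angle data.frame.
#' @export
write_angles <- function(angles, path) {
  .write_csv_precise(angles[c("frame", "joint", "angle_deg")], path)
}

#' Read and write luminance series
#'
#' Columns: `camera_id`, `frame`, `luminance`.
#'
#' @param path CSV file path.
#' @param frame_rate frame rate attached to the returned series.
#' @return a named list of `luminance_series`.
#' @export
read_luminance <- function(path, frame_rate = 120) {
  df <- .read_checked(path, c("camera_id", "frame", "luminance"), "luminance",
                      "luminance")
  df <- df[order(df$camera_id, df$frame), ]
  lapply(split(df, df$camera_id), function(d) {
    luminance_series(d$camera_id[1], d$luminance, frame_rate)
  })
}

#' @rdname read_luminance
#' @param series named list of `luminance_series`.
#' @export
write_luminance <- function(series, path) {
  df <- do.call(rbind, lapply(series, function(s) {
    data.frame(camera_id = s$camera_id,
               frame = seq_along(s$values) - 1L,
               luminance = s$values)
  }))
  .write_csv_precise(df, path)
}

#' Read and write checkerboard corner observations
#'
#' Columns: `view_id`, `camera_id`, `corner_id`, `u_px`, `v_px`.
#'
#' @param path CSV file path.
#' @return board-observation data.frame.
#' @export
read_board_observations <- function(path) {
  df <- .read_checked(path, c("view_id", "camera_id", "corner_id", "u_px",
                              "v_px"),
                      c("u_px", "v_px"), "board observations")
  df
}

#' @rdname read_board_observations
#' @param observations board-observation data.frame.
#' @export
write_board_observations <- function(observations, path) {
  .write_csv_precise(observations[c("view_id", "camera_id", "corner_id",
                                    "u_px", "v_px")], path)
}

#' Read and write a rig configuration file
#'
#' YAML (or JSON, by extension) description of the rig: a `frame_rate`
#' field, a `cameras` list keyed by camera_id with fields `intrinsics`
#' (fx, fy, cx, cy, skew, image_width, image_height), `distortion`
#' (k1, k2, k3, p1, p2) and optional `pose` (`rotation`: 9 values
#' row-major, `translation`: 3 values mm, `source_frame`), and a
#' `stereo` list keyed `"<a>-<b>"` with `rotation`, `translation` for
#' each calibrated camera pair.
#'
#' @param path file path (`.yaml`/`.yml` or `.json`).
#' @return a list with `cameras` (named list of `camera_model`),
#'   `stereo` (named list of `rigid_transform`), `frame_rate`.
#' @export
read_rig_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  cameras <- list()
  for (id in names(cfg$cameras)) {
    cc <- cfg$cameras[[id]]
    intr <- do.call(camera_intrinsics, cc$intrinsics)
    dist <- do.call(lens_distortion, cc$distortion %||% list())
    pose <- NULL
    if (!is.null(cc$pose)) {
      pose <- rigid_transform(matrix(unlist(cc$pose$rotation), 3, 3,
                                     byrow = TRUE),
                              unlist(cc$pose$translation),
                              cc$pose$source_frame %||% "world", id)
    }
    cameras[[id]] <- camera_model(id, intr, dist, pose)
  }
  stereo <- list()
  for (key in names(cfg$stereo)) {
    st <- cfg$stereo[[key]]
    ids <- strsplit(key, "-", fixed = TRUE)[[1]]
    stereo[[key]] <- rigid_transform(matrix(unlist(st$rotation), 3, 3,
                                            byrow = TRUE),
                                     unlist(st$translation), ids[1], ids[2])
  }
  list(cameras = cameras, stereo = stereo,
       frame_rate = cfg$frame_rate %||% 120)
}

#' @rdname read_rig_config
#' @param rig a `camera_rig` or a list with `cameras`, `stereo`,
#'   `frame_rate`.
#' @export
write_rig_config <- function(rig, path) {
  cfg <- list(frame_rate = rig$frame_rate %||% 120, cameras = list(),
              stereo = list())
  for (cam in rig$cameras) {
    cfg$cameras[[cam$camera_id]] <- list(
      intrinsics = cam$intrinsics[c("fx", "fy", "cx", "cy", "skew",
                                    "image_width", "image_height")],
      distortion = cam$distortion[c("k1", "k2", "k3", "p1", "p2")],
      pose = list(rotation = as.numeric(t(cam$pose$rotation)),
                  translation = cam$pose$translation,
                  source_frame = cam$pose$source_frame)
    )
  }
  for (key in names(rig$stereo)) {
    st <- rig$stereo[[key]]
    cfg$stereo[[key]] <- list(rotation = as.numeric(t(st$rotation)),
                              translation = st$translation)
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(cfg, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(cfg, path, precision = 17)
  }
  invisible(path)
}

#' Write a synchronization result as JSON
#'
#' @param sync a `sync_result`.
#' @param path output path.
#' @export
write_sync_result <- function(sync, path) {
  jsonlite::write_json(list(reference_camera_id = sync$reference_camera_id,
                            offsets = as.list(sync$offsets),
                            events = sync$events),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_sync_result
#' @return `read_sync_result` returns a `sync_result`.
#' @export
read_sync_result <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  sync_result(x$reference_camera_id,
              vapply(x$offsets, as.integer, integer(1)),
              lapply(x$events, as.integer))
}

#' Export marker trajectories to a TRC motion-capture file
#'
#' Tab-delimited TRC with the standard five header lines, marker names,
#' and X/Y/Z columns per marker. Coordinates are written in mm at the
#' given rate; frames missing a marker get blank fields.
#'
#' @param trajectories trajectory data.frame.
#' @param path output `.trc` path.
#' @param frame_rate data and camera rate in Hz (default 120).
#' @param units coordinate units string (default "mm").
#' @export
write_trc <- function(trajectories, path, frame_rate = 120, units = "mm") {
  markers <- sort(unique(trajectories$label))
  frames <- sort(unique(trajectories$frame))
  n <- length(frames)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("PathFileType\t4\t(X/Y/Z)\t%s", basename(path)), con)
  writeLines(paste("DataRate", "CameraRate", "NumFrames", "NumMarkers",
                   "Units", "OrigDataRate", "OrigDataStartFrame",
                   "OrigNumFrames", sep = "\t"), con)
  writeLines(sprintf("%g\t%g\t%d\t%d\t%s\t%g\t%d\t%d",
                     frame_rate, frame_rate, n, length(markers), units,
                     frame_rate, 1L, n), con)
  hdr <- c("Frame#", "Time",
           unlist(lapply(markers, function(m) c(m, "", ""))))
  writeLines(paste(hdr, collapse = "\t"), con)
  sub <- c("", "", unlist(lapply(seq_along(markers), function(i) {
    paste0(c("X", "Y", "Z"), i)
  })))
  writeLines(paste(sub, collapse = "\t"), con)
  wide <- lapply(markers, function(m) {
    tr <- trajectories[trajectories$label == m, ]
    idx <- match(frames, tr$frame)
    cbind(tr$x_mm[idx], tr$y_mm[idx], tr$z_mm[idx])
  })
  for (i in seq_len(n)) {
    vals <- unlist(lapply(wide, function(w) w[i, ]))
    txt <- sprintf("%.6f", vals)
    txt[is.na(vals)] <- ""
    writeLines(paste(sprintf("%d", i), sprintf("%.6f", frames[i] / frame_rate),
                     paste(txt, collapse = "\t"), sep = "\t"), con)
  }
  invisible(path)
}
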