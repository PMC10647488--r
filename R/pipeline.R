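#' Pipeline configuration
#'
#' Bundles the file paths and tolerances of a full processing run. Only
#' `rig_config`, `tracks` and `output_dir` are mandatory; stages whose
#' inputs are absent are skipped.
#'
#' @param rig_config path to the rig configuration (YAML/JSON).
#' @param tracks path to the marker-tracks CSV.
#' @param output_dir directory for all outputs (created if needed).
#' @param luminance optional luminance CSV for synchronization.
#' @param sync optional pre-computed sync JSON (overrides `luminance`).
#' @param plumb,waterline optional CSVs of plumb-line points (`line_id`,
#'   `x_mm`, `y_mm`, `z_mm`, top-to-bottom within each line) and
#'   waterline points (`x_mm`, `y_mm`, `z_mm`) for the pool frame.
#' @param sync_required error if neither `sync` nor `luminance` is given
#'   (default FALSE: offsets are then assumed 0).
#' @param sync_k MAD multiplier for event detection.
#' @param gap_max_frames maximum trajectory gap filled by interpolation.
#' @param min_overlap minimum shared samples for frame unification.
#' @param residual_gate triangulation reprojection gate in px.
#' @param lateral_axis hyperextension reference axis for the joint
#'   angles, in the frame the trajectories end up in. Default NULL: the
#'   pool-frame x axis `c(1, 0, 0)` when a pool frame is built, else the
#'   rig-frame equivalent `c(0, 0, -1)`.
#' @param seed master seed (recorded in outputs; the pipeline itself is
#'   deterministic).
#' @return an object of class `pipeline_config`.
#' @export
pipeline_config <- function(rig_config, tracks, output_dir,
                            luminance = NULL, sync = NULL,
                            plumb = NULL, waterline = NULL,
                            sync_required = FALSE,
                            sync_k = 5, gap_max_frames = 12L,
                            min_overlap = 3L, residual_gate = 5,
                            lateral_axis = NULL,
                            seed = 1L) {
  if (sync_k <= 0 || residual_gate <= 0 || min_overlap <= 0 ||
      gap_max_frames < 0) {
    stop("tolerances must be positive", call. = FALSE)
  }
  structure(list(rig_config = rig_config, tracks = tracks,
                 output_dir = output_dir, luminance = luminance,
                 sync = sync, plumb = plumb, waterline = waterline,
                 sync_required = sync_required, sync_k = sync_k,
                 gap_max_frames = gap_max_frames,
                 min_overlap = min_overlap, residual_gate = residual_gate,
                 lateral_axis = lateral_axis, seed = seed),
            class = "pipeline_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full reconstruction pipeline
#'
#' Synchronization (from luminance events), per-pair DLT reconstruction,
#' unification into the first camera's frame, optional transformation
#' into the pool frame, gap interpolation, joint angles and ROM
#' summaries, and (when the five checkerboard reference points are among
#' the labels) the board validation report. Intermediate artifacts are
#' written to the output directory; per-stage counts are logged via
#' `message()`.
#'
#' @param config a `pipeline_config`.
#' @return (invisibly) a list with `trajectories`, `angles`, `rom`,
#'   `sync`, `board_validation` (NULL where skipped).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  rig <- .stage("rig-config", read_rig_config(config$rig_config))
  tracks <- .stage("tracks", read_tracks(config$tracks))

  sync <- NULL
  if (!is.null(config$sync)) {
    sync <- .stage("sync", read_sync_result(config$sync))
  } else if (!is.null(config$luminance)) {
    sync <- .stage("sync", {
      series <- read_luminance(config$luminance, rig$frame_rate)
      events <- lapply(series, detect_extinction_events, k = config$sync_k)
      synchronize(events)
    })
  } else if (config$sync_required) {
    stop("pipeline stage 'sync' failed: synchronization required but no ",
         "sync or luminance input given", call. = FALSE)
  }
  if (!is.null(sync)) {
    write_sync_result(sync, file.path(config$output_dir, "sync.json"))
    tracks <- apply_offsets(tracks, sync)
    message("sync: offsets ", paste(sprintf("%s=%+d", names(sync$offsets),
                                            sync$offsets), collapse = ", "))
  }

  pair_trajs <- .stage("reconstruct", {
    out <- list()
    for (key in names(rig$stereo)) {
      ids <- strsplit(key, "-", fixed = TRUE)[[1]]
      tr <- reconstruct_pair(tracks, rig$stereo[[key]],
                             rig$cameras[[ids[1]]], rig$cameras[[ids[2]]],
                             residual_gate = config$residual_gate)
      message("reconstruct ", key, ": ", nrow(tr), " samples")
      if (nrow(tr)) out[[key]] <- tr
    }
    if (!length(out)) stop("no pair produced any reconstruction")
    out
  })

  unified <- .stage("unify", {
    u <- unify_frames(pair_trajs, min_overlap = config$min_overlap)
    message("unify: ", nrow(u), " samples in frame '",
            u$coordinate_frame[1], "'")
    u
  })

  if (!is.null(config$plumb) && !is.null(config$waterline)) {
    unified <- .stage("global-frame", {
      plumb <- read.csv(config$plumb)
      waterline <- read.csv(config$waterline)
      pose <- build_global_frame(plumb, waterline,
                                 source_frame = unified$coordinate_frame[1])
      xyz <- rt_apply(pose, as.matrix(unified[, c("x_mm", "y_mm", "z_mm")]))
      unified$x_mm <- xyz[, 1]; unified$y_mm <- xyz[, 2]
      unified$z_mm <- xyz[, 3]
      unified$coordinate_frame <- "pool"
      message("global-frame: trajectories re-expressed in the pool frame")
      unified
    })
  }

  unified <- .stage("interpolate", {
    before <- nrow(unified)
    u <- interpolate_gaps(unified, config$gap_max_frames)
    message("interpolate: ", nrow(u) - before, " gap frames filled")
    u
  })
  write_trajectories(unified, file.path(config$output_dir, "trajectories.csv"))

  defs <- joint_definitions()
  have <- vapply(seq_len(nrow(defs)), function(i) {
    all(c(defs$proximal[i], defs$vertex[i], defs$distal[i]) %in%
          unified$label)
  }, logical(1))
  angles <- NULL
  rom <- NULL
  lateral <- config$lateral_axis %||%
    (if (identical(unified$coordinate_frame[1], "pool")) c(1, 0, 0)
     else c(0, 0, -1))
  if (any(have)) {
    angles <- .stage("angles", {
      a <- joint_angle_series(unified, defs[have, ], lateral_axis = lateral)
      message("angles: ", length(unique(a$joint)), " joints, ",
              nrow(a), " samples")
      a
    })
    write_angles(angles, file.path(config$output_dir, "angles.csv"))
    rom <- summarize_rom(angles)
    jsonlite::write_json(rom, file.path(config$output_dir, "rom_summary.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }

  board <- NULL
  if (all(rownames(reference_geometry()$points) %in% unified$label)) {
    board <- .stage("validate-board", validate_board(unified))
    jsonlite::write_json(board,
                         file.path(config$output_dir, "board_validation.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    message("validate-board: median segment error ",
            sprintf("%.3f", median(board$segments$median)), " mm")
  }

  invisible(list(trajectories = unified, angles = angles, rom = rom,
                 sync = sync, board_validation = board))
}

#' Checkerboard sweep validation experiment
#'
#' The full error-estimation protocol on a synthetic sweep: simulate a
#' checkerboard pass through the rig, stereo-calibrate every camera pair
#' from the corner views, triangulate the five reference points per
#' pair with the calibrated transforms, unify all pairs into the first
#' camera's frame, and measure per-frame segment and angle errors
#' against the reference geometry.
#'
#' @param rig a `camera_rig` (default [make_default_rig()]).
#' @param duration_s sweep duration in seconds (default 60).
#' @param noise_px pixel noise sd (default 0.5).
#' @param seed RNG seed for the simulation.
#' @param view_stride calibration-view stride in frames.
#' @param board a `board_model`.
#' @param model a `checkerboard_model`.
#' @return list with `median_segment_error_mm`, `median_angle_error_deg`,
#'   `segment_errors`, `angle_errors`, `trajectories`, `stereo`
#'   (calibrated pair transforms) and `n_frames`.
#' @export
run_sweep_validation <- function(rig = make_default_rig(), duration_s = 60,
                                 noise_px = 0.5, seed = 42L,
                                 view_stride = 24L, board = board_model(),
                                 model = reference_geometry()) {
  sim <- simulate_checkerboard_pass(rig, model = model, board = board,
                                    duration_s = duration_s,
                                    noise_px = noise_px, seed = seed,
                                    view_stride = view_stride)
  obs <- sim$board_observations
  pair_trajs <- list()
  stereo <- list()
  for (p in rig$pairs) {
    key <- paste(p, collapse = "-")
    cam_a <- rig$cameras[[p[1]]]
    cam_b <- rig$cameras[[p[2]]]
    st <- calibrate_stereo(obs[obs$camera_id == p[1], ],
                           obs[obs$camera_id == p[2], ],
                           board, cam_a$intrinsics, cam_b$intrinsics,
                           cam_a$distortion, cam_b$distortion,
                           camera_a = p[1], camera_b = p[2])
    stereo[[key]] <- st
    tr <- reconstruct_pair(sim$tracks, st$transform, cam_a, cam_b)
    if (nrow(tr)) pair_trajs[[key]] <- tr
  }
  unified <- unify_frames(pair_trajs)
  se <- segment_errors(unified, model)
  ae <- angle_errors(unified, model)
  list(median_segment_error_mm = median(se$error_mm),
       median_angle_error_deg = median(ae$error_deg),
       segment_errors = se, angle_errors = ae,
       trajectories = unified, stereo = stereo,
       n_frames = length(unique(unified$frame)))
}

#' Checkerboard validation report for reconstructed reference points
#'
#' @param trajectories trajectories containing the labels TL, TR, ML,
#'   BL, BR.
#' @param model a `checkerboard_model`.
#' @return list with `segments` and `angles` box-plot summaries (per
#'   item) plus `pooled_segments` / `pooled_angles` (per symmetric
#'   group).
#' @export
validate_board <- function(trajectories, model = reference_geometry()) {
  se <- segment_errors(trajectories, model)
  ae <- angle_errors(trajectories, model)
  list(segments = error_report(se, by = "segment"),
       pooled_segments = error_report(se, by = "group"),
       angles = error_report(ae, by = "angle"),
       pooled_angles = error_report(ae, by = "group"))
}
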