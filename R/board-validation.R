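#' Reference geometry of the five checkerboard validation points
#'
#' The error-estimation protocol tracks five physical points on the
#' calibration board: TL (top left), TR (top right), ML (middle left),
#' BL (bottom left) and BR (bottom right). Their planar model
#' coordinates are fixed by the printed side lengths: the outer
#' rectangle is 600.0 x 480.0 mm, and ML is the intersection of circles
#' of radius 339.4 mm around TL and 432.7 mm around TR (which lands at
#' (240, 240) mm to within the print precision). Segment and angle
#' ground truths are derived from these coordinates, so that exact
#' reconstructions have exactly zero error.
#'
#' @return an object of class `checkerboard_model`: list with `points`
#'   (5 x 3 matrix, mm, z = 0), `segments` (data.frame of the 8 reference
#'   segments with ground-truth lengths) and `angles` (data.frame of the
#'   5 reference angles with ground-truth values in degrees).
#' @export
reference_geometry <- function() {
  width <- 600.0
  height <- 480.0
  d1 <- 339.4   # TL-ML and BL-ML
  d2 <- 432.7   # TR-ML and BR-ML
  ml_x <- (d1^2 - d2^2 + width^2) / (2 * width)
  ml_y <- sqrt(d1^2 - ml_x^2)
  points <- rbind(
    TL = c(0, 0, 0),
    TR = c(width, 0, 0),
    ML = c(ml_x, ml_y, 0),
    BL = c(0, height, 0),
    BR = c(width, height, 0)
  )
  colnames(points) <- c("x_mm", "y_mm", "z_mm")
  seg_def <- data.frame(
    segment = c("TL-TR", "BL-BR", "TL-BL", "TR-BR",
                "TL-ML", "BL-ML", "TR-ML", "BR-ML"),
    group = c("horizontal", "horizontal", "vertical", "vertical",
              "first_diagonal", "first_diagonal",
              "second_diagonal", "second_diagonal"),
    from = c("TL", "BL", "TL", "TR", "TL", "BL", "TR", "BR"),
    to = c("TR", "BR", "BL", "BR", "ML", "ML", "ML", "ML")
  )
  seg_def$length_mm <- sqrt(rowSums(
    (points[seg_def$from, ] - points[seg_def$to, ])^2))
  ang_def <- data.frame(
    angle = c("TL-ML-TR", "ML-TL-TR", "TL-TR-ML", "TR-TL-BL", "TR-BR-BL"),
    group = c("corner_triangle_ML", "corner_triangle_TL",
              "corner_triangle_TR", "corner_checkerboard",
              "corner_checkerboard"),
    p1 = c("TL", "ML", "TL", "TR", "TR"),
    vertex = c("ML", "TL", "TR", "TL", "BR"),
    p2 = c("TR", "TR", "ML", "BL", "BL")
  )
  ang_def$angle_deg <- vapply(seq_len(nrow(ang_def)), function(i) {
    v1 <- points[ang_def$p1[i], ] - points[ang_def$vertex[i], ]
    v2 <- points[ang_def$p2[i], ] - points[ang_def$vertex[i], ]
    acos(clamp(sum(v1 * v2) / (vnorm(v1) * vnorm(v2)), -1, 1)) * 180 / pi
  }, numeric(1))
  structure(list(points = points, segments = seg_def, angles = ang_def),
            class = "checkerboard_model")
}

#' @export
print.checkerboard_model <- function(x, ...) {
  cat("<checkerboard_model> 5 reference points, 8 segments, 5 angles\n")
  cat(sprintf("  ML at (%.3f, %.3f) mm\n", x$points["ML", 1], x$points["ML", 2]))
  invisible(x)
}

# wide per-frame matrix of one label's coordinates, frames x 3
.label_positions <- function(trajectories, label, frames) {
  tr <- trajectories[trajectories$label == label, ]
  as.matrix(tr[match(frames, tr$frame), c("x_mm", "y_mm", "z_mm")])
}

.frames_with_all_labels <- function(trajectories, labels) {
  frames <- Reduce(intersect, lapply(labels, function(l) {
    trajectories$frame[trajectories$label == l]
  }))
  sort(frames)
}

#' Per-frame absolute errors of the eight reference segments
#'
#' @param trajectories reconstructed trajectories of the five reference
#'   points (columns `frame`, `label`, `x_mm`, `y_mm`, `z_mm`), with
#'   labels TL, TR, ML, BL, BR.
#' @param model a `checkerboard_model` (default [reference_geometry()]).
#' @param signed also keep the signed error column (default FALSE keeps
#'   it anyway as `signed_error_mm`; absolute error is `error_mm`).
#' @return long data.frame with columns `frame`, `segment`, `group`,
#'   `length_mm`, `error_mm`, `signed_error_mm`. Frames lacking any of
#'   the five labels are skipped; the number skipped is attached as
#'   attribute `n_skipped_frames`.
#' @export
segment_errors <- function(trajectories, model = reference_geometry(),
                           signed = FALSE) {
  labels <- rownames(model$points)
  frames <- .frames_with_all_labels(trajectories, labels)
  all_frames <- sort(unique(trajectories$frame))
  n_skipped <- length(all_frames) - length(frames)
  if (!length(frames)) stop("no frames with all five reference points",
                            call. = FALSE)
  pos <- lapply(setNames(labels, labels), .label_positions,
                trajectories = trajectories, frames = frames)
  out <- do.call(rbind, lapply(seq_len(nrow(model$segments)), function(i) {
    s <- model$segments[i, ]
    len <- sqrt(rowSums((pos[[s$from]] - pos[[s$to]])^2))
    data.frame(frame = frames, segment = s$segment, group = s$group,
               length_mm = len,
               error_mm = abs(len - s$length_mm),
               signed_error_mm = len - s$length_mm)
  }))
  rownames(out) <- NULL
  attr(out, "n_skipped_frames") <- n_skipped
  out
}

#' Per-frame absolute errors of the five reference angles
#'
#' @inheritParams segment_errors
#' @return long data.frame with columns `frame`, `angle`, `group`,
#'   `angle_deg`, `error_deg`, `signed_error_deg`; skipped-frame count in
#'   attribute `n_skipped_frames`.
#' @export
angle_errors <- function(trajectories, model = reference_geometry()) {
  labels <- rownames(model$points)
  frames <- .frames_with_all_labels(trajectories, labels)
  all_frames <- sort(unique(trajectories$frame))
  n_skipped <- length(all_frames) - length(frames)
  if (!length(frames)) stop("no frames with all five reference points",
                            call. = FALSE)
  pos <- lapply(setNames(labels, labels), .label_positions,
                trajectories = trajectories, frames = frames)
  out <- do.call(rbind, lapply(seq_len(nrow(model$angles)), function(i) {
    a <- model$angles[i, ]
    v1 <- pos[[a$p1]] - pos[[a$vertex]]
    v2 <- pos[[a$p2]] - pos[[a$vertex]]
    ang <- acos(clamp(rowSums(v1 * v2) /
                        (sqrt(rowSums(v1^2)) * sqrt(rowSums(v2^2))), -1, 1)) *
      180 / pi
    data.frame(frame = frames, angle = a$angle, group = a$group,
               angle_deg = ang,
               error_deg = abs(ang - a$angle_deg),
               signed_error_deg = ang - a$angle_deg)
  }))
  rownames(out) <- NULL
  attr(out, "n_skipped_frames") <- n_skipped
  out
}

#' Box-plot style summaries of reconstruction errors
#'
#' Five-number summaries with the 1.5 IQR whisker convention, per item
#' and (optionally) pooled over the symmetric item pairs of each group.
#'
#' @param errors data.frame from [segment_errors()] or [angle_errors()].
#' @param value column to summarize (default the absolute error column
#'   present in the input).
#' @param by grouping column (`"segment"`, `"angle"` or `"group"`).
#' @return data.frame with columns `item`, `n`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `n_outliers`.
#' @export
error_report <- function(errors,
                         value = intersect(c("error_mm", "error_deg"),
                                           names(errors))[1],
                         by = intersect(c("segment", "angle"),
                                        names(errors))[1]) {
  if (is.na(value) || is.null(errors[[value]])) {
    stop("no error column found to summarize", call. = FALSE)
  }
  parts <- lapply(split(errors[[value]], errors[[by]]), function(x) {
    bs <- boxplot.stats(x)
    data.frame(n = length(x),
               median = bs$stats[3], q1 = bs$stats[2], q3 = bs$stats[4],
               whisker_low = bs$stats[1], whisker_high = bs$stats[5],
               n_outliers = length(bs$out))
  })
  out <- do.call(rbind, parts)
  out <- cbind(item = rownames(out), out)
  rownames(out) <- NULL
  out
}
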