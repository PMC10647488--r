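#' Rigid transform between two named coordinate frames
#'
#' A proper rigid motion `x_target = R x_source + t` tagged with the names
#' of the frames it maps between. Frame tags are carried through
#' composition and inversion so that mismatched chains are caught early.
#' Translations are in millimetres throughout the package.
#'
#' @param rotation 3x3 proper rotation matrix (orthonormal, det +1 within
#'   `tol`).
#' @param translation numeric length-3 translation in mm.
#' @param source_frame,target_frame character frame identifiers.
#' @param tol orthonormality tolerance used by the validity check.
#' @return an object of class `rigid_transform`.
#' @examples
#' t_ab <- rigid_transform(diag(3), c(100, 0, 0), "a", "b")
#' rt_apply(t_ab, c(0, 0, 0))
#' @export
rigid_transform <- function(rotation, translation, source_frame = "source",
                            target_frame = "target", tol = 1e-9) {
  rotation <- as.matrix(rotation)
  translation <- as.numeric(translation)
  if (!all(dim(rotation) == c(3L, 3L))) {
    stop("rotation must be a 3x3 matrix", call. = FALSE)
  }
  if (length(translation) != 3L || any(!is.finite(translation))) {
    stop("translation must be a finite 3-vector", call. = FALSE)
  }
  if (max(abs(crossprod(rotation) - diag(3))) > tol) {
    stop("rotation is not orthonormal within tolerance ", tol, call. = FALSE)
  }
  if (abs(det(rotation) - 1) > tol) {
    stop("rotation must be proper (det +1); got det = ", det(rotation),
         call. = FALSE)
  }
  structure(
    list(rotation = rotation, translation = translation,
         source_frame = as.character(source_frame),
         target_frame = as.character(target_frame)),
    class = "rigid_transform"
  )
}

#' Identity rigid transform
#'
#' @param frame frame name used for both source and target.
#' @return a `rigid_transform` with identity rotation and zero translation.
#' @export
rt_identity <- function(frame = "world") {
  rigid_transform(diag(3), c(0, 0, 0), frame, frame)
}

#' @export
print.rigid_transform <- function(x, ...) {
  ang <- rotation_angle_deg(x$rotation)
  cat(sprintf("<rigid_transform> %s -> %s | rotation %.3f deg | t = (%.2f, %.2f, %.2f) mm\n",
              x$source_frame, x$target_frame, ang,
              x$translation[1], x$translation[2], x$translation[3]))
  invisible(x)
}

#' Compose two rigid transforms
#'
#' `rt_compose(t_ab, t_bc)` yields the transform a -> c. The target frame
#' of the first argument must equal the source frame of the second.
#'
#' @param t_ab,t_bc `rigid_transform` objects.
#' @return the composed `rigid_transform` a -> c.
#' @export
rt_compose <- function(t_ab, t_bc) {
  stopifnot(inherits(t_ab, "rigid_transform"), inherits(t_bc, "rigid_transform"))
  if (!identical(t_ab$target_frame, t_bc$source_frame)) {
    stop("frame mismatch in composition: first transform targets '",
         t_ab$target_frame, "' but second starts at '", t_bc$source_frame, "'",
         call. = FALSE)
  }
  rigid_transform(t_bc$rotation %*% t_ab$rotation,
                  as.numeric(t_bc$rotation %*% t_ab$translation) + t_bc$translation,
                  t_ab$source_frame, t_bc$target_frame)
}

#' Invert a rigid transform
#'
#' @param t a `rigid_transform`.
#' @return the inverse transform with source/target frames swapped.
#' @export
rt_invert <- function(t) {
  stopifnot(inherits(t, "rigid_transform"))
  Rt <- t(t$rotation)
  rigid_transform(Rt, as.numeric(-Rt %*% t$translation),
                  t$target_frame, t$source_frame)
}

#' Apply a rigid transform to points
#'
#' @param t a `rigid_transform`.
#' @param points a 3-vector or n x 3 matrix of points (mm) in the source
#'   frame.
#' @return points in the target frame, same shape as the input.
#' @export
rt_apply <- function(t, points) {
  stopifnot(inherits(t, "rigid_transform"))
  vec <- is.null(dim(points)) && length(points) == 3L
  pts <- as_point_matrix(points)
  out <- pts %*% t(t$rotation) +
    matrix(t$translation, nrow(pts), 3L, byrow = TRUE)
  if (vec) as.numeric(out) else out
}
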