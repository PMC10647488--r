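`%||%` <- function(a, b) if (is.null(a)) b else a

vnorm <- function(v) sqrt(sum(v^2))

unit_vector <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a (near-)zero vector", call. = FALSE)
  v / n
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# row-wise cross product of two n x 3 matrices
cross3_rows <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

as_point_matrix <- function(x, what = "points") {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop(what, " must be a 3-vector or an n x 3 matrix", call. = FALSE)
    x <- matrix(x, nrow = 1L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop(what, " must have 3 columns", call. = FALSE)
  storage.mode(x) <- "double"
  x
}

skew_matrix <- function(v) {
  matrix(c(0, -v[3], v[2],
           v[3], 0, -v[1],
           -v[2], v[1], 0), 3, 3, byrow = TRUE)
}

#' Convert a Rodrigues rotation vector to a rotation matrix
#'
#' The vector's direction is the rotation axis and its norm the rotation
#' angle in radians. The zero vector maps to the identity.
#'
#' @param rvec numeric length-3 rotation vector (radians).
#' @return a 3x3 rotation matrix.
#' @export
rodrigues_to_matrix <- function(rvec) {
  stopifnot(length(rvec) == 3L)
  theta <- vnorm(rvec)
  if (theta < 1e-12) {
    K <- skew_matrix(rvec)
    return(diag(3) + K)  # first-order; exact at theta = 0
  }
  k <- rvec / theta
  K <- skew_matrix(k)
  diag(3) + sin(theta) * K + (1 - cos(theta)) * (K %*% K)
}

#' Convert a rotation matrix to a Rodrigues rotation vector
#'
#' @param R a 3x3 rotation matrix.
#' @return numeric length-3 axis-angle vector (radians).
#' @export
matrix_to_rodrigues <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  cos_theta <- clamp((sum(diag(R)) - 1) / 2, -1, 1)
  theta <- acos(cos_theta)
  if (theta < 1e-9) {
    # near identity: skew part is theta * axis to first order
    return(c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / 2)
  }
  if (theta > pi - 1e-6) {
    # near pi: axis from the symmetric part
    B <- (R + diag(3)) / 2
    axis <- sqrt(pmax(diag(B), 0))
    # fix signs using off-diagonal terms
    i <- which.max(axis)
    if (axis[i] > 0) {
      axis <- B[, i] / axis[i]
      axis <- axis / vnorm(axis)
    }
    return(axis * theta)
  }
  axis <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2]) / (2 * sin(theta))
  axis * theta
}

rotation_angle_deg <- function(R) {
  acos(clamp((sum(diag(R)) - 1) / 2, -1, 1)) * 180 / pi
}

is_rotation_matrix <- function(R, tol = 1e-9) {
  is.matrix(R) && all(dim(R) == c(3L, 3L)) &&
    max(abs(crossprod(R) - diag(3))) <= tol &&
    abs(det(R) - 1) <= tol
}

# nearest rotation matrix (polar decomposition with determinant guard)
orthonormalize_rotation <- function(M) {
  s <- svd(M)
  R <- s$u %*% t(s$v)
  if (det(R) < 0) R <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R
}

rotation_to_quaternion <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s,
           (R[3, 2] - R[2, 3]) / s,
           (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    if (i == 1) {
      s <- sqrt(1 + R[1, 1] - R[2, 2] - R[3, 3]) * 2
      q <- c((R[3, 2] - R[2, 3]) / s, 0.25 * s,
             (R[1, 2] + R[2, 1]) / s, (R[1, 3] + R[3, 1]) / s)
    } else if (i == 2) {
      s <- sqrt(1 + R[2, 2] - R[1, 1] - R[3, 3]) * 2
      q <- c((R[1, 3] - R[3, 1]) / s, (R[1, 2] + R[2, 1]) / s,
             0.25 * s, (R[2, 3] + R[3, 2]) / s)
    } else {
      s <- sqrt(1 + R[3, 3] - R[1, 1] - R[2, 2]) * 2
      q <- c((R[2, 1] - R[1, 2]) / s, (R[1, 3] + R[3, 1]) / s,
             (R[2, 3] + R[3, 2]) / s, 0.25 * s)
    }
  }
  q / vnorm(q)
}

quaternion_to_rotation <- function(q) {
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# chordal L2 mean of unit quaternions (principal eigenvector of sum q q')
average_rotations <- function(R_list) {
  qs <- lapply(R_list, rotation_to_quaternion)
  q0 <- qs[[1]]
  M <- matrix(0, 4, 4)
  for (q in qs) {
    if (sum(q * q0) < 0) q <- -q
    M <- M + tcrossprod(q)
  }
  q_bar <- eigen(M, symmetric = TRUE)$vectors[, 1]
  quaternion_to_rotation(q_bar)
}

# deterministic child seeds below 2^31 derived from one master seed
derive_seed <- function(seed, k) {
  (as.integer(seed) + 99991L * as.integer(k)) %% 2147483647L
}
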