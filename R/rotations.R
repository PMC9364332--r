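#' Compose a rotation matrix from an XZ'Y'' Euler angle triple
#'
#' Builds the orientation of the humerus frame relative to the thorax frame
#' from intrinsic Tait-Bryan angles applied in the order X (frontal plane,
#' abduction/adduction), then the rotated Z' (sagittal plane, vertical
#' flexion/extension), then the twice-rotated Y'' (transverse plane,
#' rotation / horizontal movements). Sign conventions: positive X =
#' abduction, positive Z = vertical flexion, positive Y = external rotation
#' / horizontal extension.
#'
#' @param x_deg,z_deg,y_deg Euler angles in degrees (vectors of equal
#'   length are accepted).
#' @return A 3x3 rotation matrix, or a `3 x 3 x n` array when the inputs
#'   have length `n > 1`.
#' @seealso [euler_from_rotation()] for the inverse decomposition.
#' @export
#' @examples
#' rotation_from_euler(30, 0, 0)
rotation_from_euler <- function(x_deg, z_deg, y_deg) {
  stopifnot(is.finite(x_deg), is.finite(z_deg), is.finite(y_deg))
  n <- length(x_deg)
  stopifnot(length(z_deg) == n, length(y_deg) == n)
  x <- x_deg * pi / 180
  z <- z_deg * pi / 180
  y <- y_deg * pi / 180
  cx <- cos(x); sx <- sin(x)
  cz <- cos(z); sz <- sin(z)
  cy <- cos(y); sy <- sin(y)
  # closed-form entries of Rx %*% Rz %*% Ry (intrinsic X -> Z' -> Y'')
  r <- array(0, dim = c(3L, 3L, n))
  r[1, 1, ] <- cz * cy
  r[1, 2, ] <- -sz
  r[1, 3, ] <- cz * sy
  r[2, 1, ] <- cx * sz * cy + sx * sy
  r[2, 2, ] <- cx * cz
  r[2, 3, ] <- cx * sz * sy - sx * cy
  r[3, 1, ] <- sx * sz * cy - cx * sy
  r[3, 2, ] <- sx * cz
  r[3, 3, ] <- sx * sz * sy + cx * cy
  if (n == 1L) r[, , 1L] else r
}

#' Decompose a rotation into XZ'Y'' Euler angles
#'
#' Inverse of [rotation_from_euler()]. The middle angle z' is confined to
#' \[-90, 90\] degrees (asin branch); x and y lie in (-180, 180\]. Within
#' 0.1 degree of the gimbal-lock condition |z'| = 90 the x/y split is
#' indeterminate; the tie-break sets y'' = 0, folds the indeterminate sum
#' into x, and flags the sample in the `gimbal` column.
#'
#' @param r A 3x3 rotation matrix or `3 x 3 x n` array of rotation
#'   matrices. Matrices must be orthonormal with determinant +1 (checked
#'   to 1e-6 unless `check = FALSE`).
#' @param check Validate orthonormality of the input.
#' @return A data.frame with columns `x_deg`, `z_deg`, `y_deg` and logical
#'   `gimbal`.
#' @export
#' @examples
#' euler_from_rotation(rotation_from_euler(20, 40, 10))
euler_from_rotation <- function(r, check = TRUE) {
  if (is.matrix(r)) r <- array(r, dim = c(3L, 3L, 1L))
  stopifnot(is.array(r), length(dim(r)) == 3L, dim(r)[1:2] == c(3L, 3L))
  if (check) {
    i <- c(1L, if (dim(r)[3] > 1L) dim(r)[3])  # spot-check first/last
    for (k in i) {
      m <- r[, , k]
      if (max(abs(crossprod(m) - diag(3))) > 1e-6 || abs(det(m) - 1) > 1e-6)
        stop("input is not a proper rotation matrix (orthonormal, det +1)")
    }
  }
  s <- pmin(1, pmax(-1, -r[1, 2, ]))
  z <- asin(s)
  gimbal <- abs(abs(z) - pi / 2) < (0.1 * pi / 180)
  x <- atan2(r[3, 2, ], r[2, 2, ])
  y <- atan2(r[1, 3, ], r[1, 1, ])
  if (any(gimbal)) {
    # fold the indeterminate x/y sum into x, set y'' = 0
    sgn <- sign(s[gimbal])
    x[gimbal] <- atan2(-r[2, 3, gimbal], sgn * r[2, 1, gimbal])
    y[gimbal] <- 0
  }
  data.frame(x_deg = x * 180 / pi, z_deg = z * 180 / pi,
             y_deg = y * 180 / pi, gimbal = gimbal)
}

#' Rotation matrix from a rotation vector (axis-angle)
#'
#' Rodrigues' formula. Used to express small fixed sensor-frame
#' misalignments (e.g. a tilted sternum sensor) as a rotation applied to
#' the measured segment orientation.
#'
#' @param rotvec_deg Length-3 rotation vector in degrees; its direction is
#'   the rotation axis and its norm the rotation angle.
#' @return A 3x3 rotation matrix.
#' @export
rotation_from_rotvec <- function(rotvec_deg) {
  stopifnot(length(rotvec_deg) == 3, is.finite(rotvec_deg))
  v <- rotvec_deg * pi / 180
  theta <- sqrt(sum(v^2))
  if (theta < 1e-12) return(diag(3))
  k <- v / theta
  kx <- matrix(c(0, k[3], -k[2], -k[3], 0, k[1], k[2], -k[1], 0), 3, 3)
  diag(3) + sin(theta) * kx + (1 - cos(theta)) * (kx %*% kx)
}

#' Re-select Euler branches for channel continuity
#'
#' The asin-based XZ'Y'' decomposition confines z' to \[-90, 90\] and folds
#' trajectories that pass beyond it (x and y jump by 180 degrees, z
#' reflects). For time series this picks, sample by sample, between the two
#' algebraic solutions `(x, z, y)` and `(x + 180, 180 - z, y + 180)` the one
#' closest to a constant-velocity prediction from the two previous samples,
#' then unwraps x and y modulo 360, yielding continuous channels for
#' movements whose sagittal excursion exceeds 90 degrees (e.g. vertical
#' flexion). Slope continuation, rather than plain nearest-previous-sample
#' selection, also carries trajectories across a *near*-gimbal passage
#' (e.g. a large sagittal movement seen through a slightly misaligned
#' sensor), where the principal branch folds without the two branches ever
#' touching; one small residual step at the branch switch is unavoidable
#' there because the folded geometry has no exactly continuous
#' representation.
#'
#' @param e data.frame as returned by [euler_from_rotation()].
#' @return data.frame of the same shape with continuous channels; the
#'   indices where the alternate branch was entered or left are attached
#'   as attribute `"branch_switches"`.
#' @export
euler_unwrap <- function(e) {
  n <- nrow(e)
  if (n < 2L) return(e)
  x <- e$x_deg; z <- e$z_deg; y <- e$y_deg
  near <- function(a, ref) a + 360 * round((ref - a) / 360)
  on_b <- FALSE
  switches <- integer(0)
  for (i in 2:n) {
    # constant-velocity prediction per channel
    px <- if (i > 2) 2 * x[i - 1] - x[i - 2] else x[i - 1]
    pz <- if (i > 2) 2 * z[i - 1] - z[i - 2] else z[i - 1]
    py <- if (i > 2) 2 * y[i - 1] - y[i - 2] else y[i - 1]
    # candidate A: principal branch; candidate B: alternate solution
    xa <- near(x[i], px); za <- z[i]; ya <- near(y[i], py)
    xb <- near(x[i] + 180, px); zb <- 180 - z[i]
    zb <- zb - 360 * round((zb - pz) / 360)
    yb <- near(y[i] + 180, py)
    da <- max(abs(xa - px), abs(za - pz), abs(ya - py))
    db <- max(abs(xb - px), abs(zb - pz), abs(yb - py))
    if (db < da) {
      x[i] <- xb; z[i] <- zb; y[i] <- yb
      if (!on_b) { switches <- c(switches, i); on_b <- TRUE }
    } else {
      x[i] <- xa; z[i] <- za; y[i] <- ya
      if (on_b) { switches <- c(switches, i); on_b <- FALSE }
    }
  }
  out <- data.frame(x_deg = x, z_deg = z, y_deg = y, gimbal = e$gimbal)
  attr(out, "branch_switches") <- switches
  out
}
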