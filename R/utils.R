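#' @keywords internal
"_PACKAGE"

DEG2RAD <- pi / 180

deg2rad <- function(x) x * DEG2RAD
rad2deg <- function(x) x / DEG2RAD

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues' formula; rotates by `angle` radians about `axis` (right-handed).
#'
#' @param axis length-3 numeric, need not be unit length.
#' @param angle rotation angle in radians.
#' @return 3x3 orthonormal rotation matrix.
#' @keywords internal
rotation_about_axis <- function(axis, angle) {
  k <- unit(axis)
  K <- matrix(c(0, k[3], -k[2],
                -k[3], 0, k[1],
                k[2], -k[1], 0), 3, 3)
  diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
}

# Rotation carrying unit vector `from` onto unit vector `to`.
rotation_between <- function(from, to) {
  f <- unit(from); t <- unit(to)
  c_ <- sum(f * t)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # opposite vectors: rotate pi about any axis orthogonal to f
    ref <- if (abs(f[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    return(rotation_about_axis(cross3(f, ref), pi))
  }
  rotation_about_axis(cross3(f, t), acos(c_))
}

# Uniform random rotation matrix (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
           2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
           2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)),
         3, 3)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
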