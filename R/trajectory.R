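#' Time-stamped 3D trajectory of one hop
#'
#' Holds per-frame world positions (cm) of the snout and cloaca landmarks at
#' a uniform frame rate. `aligned = TRUE` marks trajectories that have been
#' rotated into the standard jump plane (x = travel, y = lateral, z = up,
#' take-off cloaca at the origin).
#'
#' @param time numeric vector of timestamps (s), strictly increasing with a
#'   constant step of 1/`frame_rate`.
#' @param snout,cloaca n x 3 matrices of positions (cm).
#' @param frame_rate frames per second.
#' @param aligned logical flag.
#' @param interpolated logical vector marking frames filled by gap
#'   interpolation (default all FALSE).
#' @param truth optional list of ground-truth quantities attached by the
#'   synthetic generator.
#' @return An object of class `trajectory3d`.
#' @export
trajectory3d <- function(time, snout, cloaca, frame_rate, aligned = FALSE,
                         interpolated = NULL, truth = NULL) {
  snout <- as.matrix(snout); cloaca <- as.matrix(cloaca)
  n <- length(time)
  if (n < 2L) stop("a trajectory needs at least 2 frames")
  if (nrow(snout) != n || nrow(cloaca) != n || ncol(snout) != 3L ||
      ncol(cloaca) != 3L)
    stop("'snout' and 'cloaca' must be n x 3 with n = length(time)")
  dt <- diff(time)
  if (any(dt <= 0)) stop("timestamps must be strictly increasing")
  if (diff(range(dt)) > 1e-9 * max(dt))
    stop("timestamps must have a constant step")
  if (abs(dt[1] - 1 / frame_rate) > 1e-9 / frame_rate)
    stop("timestamp step must equal 1/frame_rate")
  blen <- sqrt(rowSums((snout - cloaca)^2))
  if (any(blen <= 0)) stop("snout-cloaca distance must be positive at every frame")
  if (is.null(interpolated)) interpolated <- rep(FALSE, n)
  structure(list(time = time, snout = snout, cloaca = cloaca,
                 frame_rate = frame_rate, aligned = isTRUE(aligned),
                 interpolated = interpolated, truth = truth),
            class = "trajectory3d")
}

#' @export
print.trajectory3d <- function(x, ...) {
  cat("<trajectory3d> ", length(x$time), " frames @ ", x$frame_rate,
      " fps", if (x$aligned) ", aligned" else ", raw", "\n", sep = "")
  if (!is.null(x$truth))
    cat("  ground truth: distance ", round(x$truth$distance, 2),
        " cm, height ", round(x$truth$height, 2), " cm\n", sep = "")
  invisible(x)
}

n_frames <- function(traj) length(traj$time)

# Apply a rigid transform x -> R x + t to every landmark.
transform_trajectory <- function(traj, R = diag(3), t = c(0, 0, 0)) {
  tr <- function(m) sweep(m %*% t(R), 2, -t)
  trajectory3d(traj$time, tr(traj$snout), tr(traj$cloaca), traj$frame_rate,
               aligned = FALSE, interpolated = traj$interpolated,
               truth = traj$truth)
}

#' Convert a trajectory to / from a data frame
#'
#' @param x a `trajectory3d`.
#' @param ... unused.
#' @return `as.data.frame`: columns `t`, `snout_x/y/z`, `cloaca_x/y/z`,
#'   `interpolated`.
#' @export
as.data.frame.trajectory3d <- function(x, ...) {
  data.frame(t = x$time,
             snout_x = x$snout[, 1], snout_y = x$snout[, 2],
             snout_z = x$snout[, 3],
             cloaca_x = x$cloaca[, 1], cloaca_y = x$cloaca[, 2],
             cloaca_z = x$cloaca[, 3],
             interpolated = x$interpolated)
}
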