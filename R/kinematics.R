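#' Align a trajectory to the standard jump plane
#'
#' Rigidly rotates and translates a raw trajectory so that the known
#' vertical direction maps to +z, the take-off cloaca position is the
#' origin, and the hop travels along +x: the horizontal heading is the
#' principal axis of the cloaca's horizontal displacements (relative to the
#' take-off point), which minimizes the least-squares norm of the lateral
#' (y) cloaca coordinates, with the sign fixed so net displacement is
#' positive. Being rigid, the transform preserves all inter-landmark and
#' inter-frame distances.
#'
#' @param raw a [trajectory3d()] with at least 3 frames.
#' @param vertical_axis known world up direction (from the calibration rig),
#'   default `c(0, 0, 1)`.
#' @return An aligned [trajectory3d()] (`aligned = TRUE`).
#' @export
align_trajectory <- function(raw, vertical_axis = c(0, 0, 1)) {
  stopifnot(inherits(raw, "trajectory3d"))
  if (n_frames(raw) < 3L) stop("alignment needs at least 3 frames")
  R1 <- rotation_between(vertical_axis, c(0, 0, 1))
  cl <- raw$cloaca %*% t(R1)
  sn <- raw$snout %*% t(R1)
  origin <- cl[1, ]
  cl <- sweep(cl, 2, origin); sn <- sweep(sn, 2, origin)
  H <- cl[, 1:2, drop = FALSE]
  net <- H[nrow(H), ]
  if (vnorm(net) < 1e-6 && vnorm(H[which.max(rowSums(H^2)), ]) < 1e-6)
    stop("heading undefined: no net horizontal displacement (vertical hop)")
  e <- eigen(crossprod(H), symmetric = TRUE)$vectors[, 1]
  ref <- if (vnorm(net) >= 1e-6) net else H[which.max(rowSums(H^2)), ]
  if (sum(e * ref) < 0) e <- -e
  R2 <- rbind(c(e[1], e[2], 0), c(-e[2], e[1], 0), c(0, 0, 1))
  trajectory3d(raw$time, sn %*% t(R2), cl %*% t(R2), raw$frame_rate,
               aligned = TRUE, interpolated = raw$interpolated,
               truth = raw$truth)
}

#' Detect take-off and landing frames
#'
#' On an aligned trajectory containing a single hop, take-off is the last
#' frame before the cloaca's height exceeds the baseline (the first frame's
#' cloaca z) by more than `epsilon` and stays above it for at least
#' `min_run` consecutive frames; landing is the first frame at or after the
#' apex whose cloaca height is back within `epsilon` of the baseline.
#'
#' @param aligned an aligned [trajectory3d()].
#' @param epsilon height threshold, cm (default 0.1).
#' @param min_run frames the height must stay above threshold.
#' @return List with integer indices `takeoff` and `landing` (1-based into
#'   the trajectory frames) and `apex`.
#' @export
detect_takeoff_landing <- function(aligned, epsilon = 0.1, min_run = 3L) {
  z <- aligned$cloaca[, 3]
  baseline <- z[1]
  above <- z > baseline + epsilon
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  good <- which(r$values & r$lengths >= min_run)
  if (length(good) == 0L)
    stop("no jump detected: cloaca never rises more than ", epsilon,
         " cm above baseline for ", min_run, "+ frames", call. = FALSE)
  flight_start <- starts[good[1]]
  takeoff <- max(flight_start - 1L, 1L)
  apex <- takeoff + which.max(z[seq(takeoff, length(z))]) - 1L
  after <- seq(apex, length(z))
  land_rel <- which(z[after] <= baseline + epsilon)
  if (length(land_rel) == 0L)
    stop("no landing detected: cloaca never returns to baseline",
         call. = FALSE)
  list(takeoff = takeoff, landing = after[land_rel[1]], apex = apex)
}

#' Per-hop kinematic variables
#'
#' Container for the six variables extracted from one hop. Angles are the
#' signed elevation of the cloaca-to-snout body axis above the horizontal
#' plane (positive = snout above cloaca), degrees.
#'
#' @param mean_velocity,max_velocity cm/s; `max_velocity >= mean_velocity > 0`.
#' @param distance,height cm, non-negative.
#' @param angle_takeoff,angle_landing degrees, within [-90, 90].
#' @param trial_id,animal_id optional identifiers.
#' @return An object of class `jump_kinematics`.
#' @export
jump_kinematics <- function(mean_velocity, max_velocity, distance, height,
                            angle_takeoff, angle_landing, trial_id = NA,
                            animal_id = NA) {
  if (!(max_velocity >= mean_velocity && mean_velocity > 0))
    stop("need max_velocity >= mean_velocity > 0")
  if (distance < 0 || height < 0) stop("distance and height must be >= 0")
  if (abs(angle_takeoff) > 90 || abs(angle_landing) > 90)
    stop("body-axis angles must lie in [-90, 90] degrees")
  structure(list(mean_velocity = mean_velocity, max_velocity = max_velocity,
                 distance = distance, height = height,
                 angle_takeoff = angle_takeoff,
                 angle_landing = angle_landing,
                 trial_id = trial_id, animal_id = animal_id),
            class = "jump_kinematics")
}

#' @export
print.jump_kinematics <- function(x, ...) {
  cat(sprintf(paste0("<jump_kinematics> distance %.1f cm, height %.1f cm, ",
                     "v mean/max %.0f/%.0f cm/s, angles %.1f / %.1f deg\n"),
              x$distance, x$height, x$mean_velocity, x$max_velocity,
              x$angle_takeoff, x$angle_landing))
  invisible(x)
}

#' @export
as.data.frame.jump_kinematics <- function(x, ...) {
  data.frame(animal_id = x$animal_id, trial_id = x$trial_id,
             mean_velocity = x$mean_velocity, max_velocity = x$max_velocity,
             distance = x$distance, height = x$height,
             angle_takeoff = x$angle_takeoff, angle_landing = x$angle_landing)
}

#' Extract kinematic variables from an aligned hop
#'
#' Cloaca speed is computed by central differences (optionally smoothed by a
#' 5-frame moving average); mean and maximum velocity are taken over the
#' take-off-to-landing bracket. Distance is the horizontal (x) cloaca
#' displacement from take-off to landing; height is the maximum cloaca
#' elevation above the take-off baseline; the take-off and landing angles
#' are the signed elevation of the cloaca-to-snout vector at the bracket
#' end frames.
#'
#' @param aligned an aligned [trajectory3d()].
#' @param takeoff_frame,landing_frame 1-based frame indices (from
#'   [detect_takeoff_landing()]).
#' @param smooth apply a 5-frame moving average to the speed series.
#' @param trial_id,animal_id identifiers carried into the result.
#' @return A [jump_kinematics()].
#' @export
extract_kinematics <- function(aligned, takeoff_frame, landing_frame,
                               smooth = FALSE, trial_id = NA, animal_id = NA) {
  n <- n_frames(aligned)
  if (landing_frame - takeoff_frame + 1L < 3L)
    stop("insufficient frames: bracket must span at least 3 frames")
  if (takeoff_frame < 1L || landing_frame > n)
    stop("frame bracket outside the trajectory")
  cl <- aligned$cloaca
  dt <- 1 / aligned$frame_rate
  vel <- matrix(NA_real_, n, 3)
  vel[2:(n - 1), ] <- (cl[3:n, ] - cl[1:(n - 2), ]) / (2 * dt)
  vel[1, ] <- (cl[2, ] - cl[1, ]) / dt
  vel[n, ] <- (cl[n, ] - cl[n - 1, ]) / dt
  speed <- sqrt(rowSums(vel^2))
  if (smooth) speed <- stats::filter(speed, rep(1 / 5, 5), sides = 2) |>
      (\(s) ifelse(is.na(s), speed, as.numeric(s)))()
  bracket <- seq(takeoff_frame, landing_frame)
  axis_angle <- function(i) {
    v <- aligned$snout[i, ] - cl[i, ]
    rad2deg(asin(v[3] / vnorm(v)))
  }
  jump_kinematics(
    mean_velocity = mean(speed[bracket]),
    max_velocity = max(speed[bracket]),
    distance = cl[landing_frame, 1] - cl[takeoff_frame, 1],
    height = max(cl[bracket, 3]) - cl[takeoff_frame, 3],
    angle_takeoff = axis_angle(takeoff_frame),
    angle_landing = axis_angle(landing_frame),
    trial_id = trial_id, animal_id = animal_id)
}

#' Select an animal's best jump
#'
#' Performance analyses use a single value per animal: the hop with the
#' greatest distance. Exact ties are broken deterministically in favour of
#' the earliest trial id.
#'
#' @param kin_list non-empty list of [jump_kinematics()] for one animal.
#' @return The selected [jump_kinematics()].
#' @export
select_best_jump <- function(kin_list) {
  if (length(kin_list) == 0L) stop("no jump data for this animal")
  d <- vapply(kin_list, function(k) k$distance, 1)
  ids <- vapply(kin_list, function(k) as.character(k$trial_id), "")
  best <- which(d == max(d))
  if (length(best) > 1L) best <- best[order(ids[best])][1]
  kin_list[[best]]
}
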