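#' Parameters of a planted ballistic hop
#'
#' The forward model behind every synthetic hop: the cloaca is a point mass
#' launched at `takeoff_speed` with the velocity vector elevated
#' `takeoff_elevation` degrees above horizontal along `azimuth`; the snout
#' sits `body_length_axis` cm from the cloaca along a body axis whose
#' elevation interpolates linearly in time from `body_angle_takeoff` to
#' `body_angle_landing` over the flight. Body-axis angles and the velocity
#' elevation are deliberately distinct quantities: observed take-off angles
#' of real animals refer to body posture, not to the velocity vector.
#'
#' @param takeoff_speed launch speed of the cloaca, cm/s (> 0).
#' @param takeoff_elevation velocity-vector elevation above horizontal,
#'   degrees, in (0, 90].
#' @param azimuth heading, degrees (0 = +x).
#' @param takeoff_point length-3 position of the cloaca at launch, cm.
#' @param body_length_axis snout-cloaca distance, cm (> 0).
#' @param body_angle_takeoff,body_angle_landing signed body-axis elevation at
#'   the first and last flight frame, degrees.
#' @param gravity cm/s^2, default 981.
#' @return An object of class `jump_params`.
#' @export
jump_params <- function(takeoff_speed, takeoff_elevation, azimuth = 0,
                        takeoff_point = c(0, 0, 0), body_length_axis = 11,
                        body_angle_takeoff = 30, body_angle_landing = -25,
                        gravity = 981) {
  stopifnot_scalar_number(takeoff_speed, "takeoff_speed", positive = TRUE)
  stopifnot_scalar_number(takeoff_elevation, "takeoff_elevation")
  if (takeoff_elevation <= 0 || takeoff_elevation > 90)
    stop("'takeoff_elevation' must be in (0, 90] degrees")
  stopifnot_scalar_number(body_length_axis, "body_length_axis", positive = TRUE)
  stopifnot_scalar_number(gravity, "gravity", positive = TRUE)
  structure(list(takeoff_speed = takeoff_speed,
                 takeoff_elevation = takeoff_elevation,
                 azimuth = azimuth,
                 takeoff_point = as.numeric(takeoff_point),
                 body_length_axis = body_length_axis,
                 body_angle_takeoff = body_angle_takeoff,
                 body_angle_landing = body_angle_landing,
                 gravity = gravity),
            class = "jump_params")
}

#' @export
print.jump_params <- function(x, ...) {
  cat("<jump_params> v0 ", round(x$takeoff_speed, 1), " cm/s @ ",
      round(x$takeoff_elevation, 1), "deg, body ",
      round(x$body_angle_takeoff, 1), " -> ",
      round(x$body_angle_landing, 1), " deg\n", sep = "")
  invisible(x)
}

#' Simulate one ballistic hop
#'
#' Generates a ground-truthed [trajectory3d()]: the cloaca follows point-mass
#' projectile motion c(t) = c0 + v0 t - (0, 0, g/2) t^2 from launch until it
#' returns to take-off height (flat ground), sampled at 1/fps. `pad_frames`
#' stationary frames are prepended at the take-off point and appended at the
#' landing point so take-off/landing detection sees the animal at rest on
#' either side of the flight. Closed-form ground truth (range
#' v0^2 sin(2 theta)/g, apex v0^2 sin^2(theta)/(2g), flight time 2 v0z/g and
#' the planted body angles) is attached to the result.
#'
#' @param params a [jump_params()].
#' @param fps sampling rate, frames/s (> 0).
#' @param pad_frames stationary frames before launch and after landing.
#' @return A [trajectory3d()] with a `truth` list.
#' @examples
#' traj <- simulate_jump(jump_params(300, 45), fps = 240)
#' traj$truth$distance   # 300^2 * sin(90 deg) / 981
#' @export
simulate_jump <- function(params, fps = 240, pad_frames = 6L) {
  if (!inherits(params, "jump_params")) params <- do.call(jump_params, params)
  stopifnot_scalar_number(fps, "fps", positive = TRUE)
  g <- params$gravity
  el <- deg2rad(params$takeoff_elevation)
  az <- deg2rad(params$azimuth)
  v0 <- params$takeoff_speed *
    c(cos(el) * cos(az), cos(el) * sin(az), sin(el))
  flight_time <- 2 * v0[3] / g
  c0 <- params$takeoff_point
  heading <- c(cos(az), sin(az), 0)
  landing_point <- c0 + c(v0[1], v0[2], 0) * flight_time

  t_start <- pad_frames / fps
  n_post <- pad_frames
  n <- pad_frames + ceiling(flight_time * fps) + n_post + 1L
  tt <- (seq_len(n) - 1L) / fps
  tf <- pmin(pmax(tt - t_start, 0), flight_time)     # time within flight
  cloaca <- matrix(rep(c0, each = n), n, 3)
  cloaca <- cloaca + outer(tf, v0) - cbind(0, 0, g / 2 * tf^2)
  # clamp to the landing point once flight is over (flat-ground assumption)
  landed <- tt - t_start >= flight_time
  cloaca[landed, ] <- matrix(rep(landing_point, each = sum(landed)),
                             sum(landed), 3)

  frac <- if (flight_time > 0) tf / flight_time else tf * 0
  beta <- deg2rad(params$body_angle_takeoff +
                    frac * (params$body_angle_landing -
                              params$body_angle_takeoff))
  axis <- cbind(cos(beta) * heading[1], cos(beta) * heading[2], sin(beta))
  snout <- cloaca + params$body_length_axis * axis

  truth <- list(
    distance = params$takeoff_speed^2 * sin(2 * el) / g,
    height = params$takeoff_speed^2 * sin(el)^2 / (2 * g),
    flight_time = flight_time,
    takeoff_speed = params$takeoff_speed,
    takeoff_elevation = params$takeoff_elevation,
    body_angle_takeoff = params$body_angle_takeoff,
    body_angle_landing = params$body_angle_landing,
    azimuth = params$azimuth)
  trajectory3d(tt, snout, cloaca, fps, truth = truth)
}
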