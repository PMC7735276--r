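#' Projective camera model
#'
#' A finite projective camera: a 3x4 homogeneous projection matrix mapping
#' world coordinates (cm) to pixel coordinates, plus the sensor size in
#' pixels. Pixel origin is the top-left corner; frame indices throughout the
#' package are 0-based.
#'
#' @param projection 3x4 numeric matrix of rank 3 whose leading 3x3 block is
#'   nonsingular.
#' @param image_size integer vector `c(width, height)` in pixels.
#' @return An object of class `camera_model`.
#' @examples
#' cam <- make_camera(position = c(0, -100, 10), target = c(0, 0, 10))
#' project_points(cam, matrix(c(0, 0, 10), 1, 3))
#' @export
camera_model <- function(projection, image_size = c(1920L, 1080L)) {
  projection <- as.matrix(projection)
  if (!all(dim(projection) == c(3L, 4L)))
    stop("'projection' must be a 3x4 matrix")
  if (qr(projection)$rank < 3L)
    stop("'projection' must have rank 3")
  if (abs(det(projection[, 1:3])) < .Machine$double.eps)
    stop("leading 3x3 block of 'projection' must be nonsingular")
  structure(list(projection = projection,
                 image_size = as.numeric(image_size)),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat("<camera_model> ", x$image_size[1], "x", x$image_size[2], " px\n", sep = "")
  print(round(x$projection, 4))
  invisible(x)
}

#' Build a pinhole camera from a pose
#'
#' Convenience constructor: a camera at `position` looking at `target`, with
#' square pixels, focal length `focal_px` and principal point at the image
#' centre.
#'
#' @param position,target world coordinates (cm).
#' @param focal_px focal length in pixels.
#' @param image_size `c(width, height)` pixels.
#' @param up approximate up direction used to fix camera roll.
#' @return A [camera_model()].
#' @export
make_camera <- function(position, target, focal_px = 1400,
                        image_size = c(1920L, 1080L), up = c(0, 0, 1)) {
  zc <- unit(target - position)          # optical axis
  xc <- unit(cross3(zc, up))             # image x (rightward)
  yc <- cross3(zc, xc)                   # image y (downward if up = +z)
  R <- rbind(xc, yc, zc)
  t <- -R %*% position
  K <- matrix(c(focal_px, 0, 0,
                0, focal_px, 0,
                image_size[1] / 2, image_size[2] / 2, 1), 3, 3)
  camera_model(K %*% cbind(R, t), image_size)
}

#' Project world points through a camera
#'
#' @param camera a [camera_model()].
#' @param points n x 3 matrix of world coordinates (cm).
#' @return A data.frame with columns `u`, `v` (pixels), `depth` (the
#'   homogeneous scale; positive in front of the camera) and `visible`
#'   (in front of the camera and inside the sensor).
#' @export
project_points <- function(camera, points) {
  points <- rbind(t(as.matrix(points)), 1)
  h <- camera$projection %*% points
  depth <- h[3, ]
  u <- h[1, ] / depth
  v <- h[2, ] / depth
  visible <- depth > 0 &
    u >= 0 & u <= camera$image_size[1] &
    v >= 0 & v <= camera$image_size[2]
  data.frame(u = u, v = v, depth = depth, visible = visible)
}

#' Two-camera high-speed recording rig
#'
#' Describes the stereo filming geometry: two non-identical cameras, a frame
#' rate, an integer synchronization offset between the right and left frame
#' counters, and the pixel noise level of landmark digitization. The physical
#' layout defaults follow a field rig with cameras on 10 cm tripods 20 cm
#' apart; `convergence_angle` records the tripod-head angle of that layout
#' and is descriptive metadata (the projective geometry is fully determined
#' by the two `camera_model`s).
#'
#' @param left,right [camera_model()] objects; must differ.
#' @param fps frames per second (> 0), default 240.
#' @param sync_offset_frames integer frame offset of the right camera
#'   relative to the left (right event frame = left event frame + offset).
#' @param convergence_angle degrees, metadata.
#' @param tripod_height,baseline cm, metadata describing the layout.
#' @param pixel_noise_sd standard deviation (pixels) of additive isotropic
#'   Gaussian landmark noise applied when rendering observations.
#' @return An object of class `stereo_rig`.
#' @export
stereo_rig <- function(left, right, fps = 240, sync_offset_frames = 0L,
                       convergence_angle = 140, tripod_height = 10,
                       baseline = 20, pixel_noise_sd = 0) {
  stopifnot(inherits(left, "camera_model"), inherits(right, "camera_model"))
  stopifnot_scalar_number(fps, "fps", positive = TRUE)
  if (pixel_noise_sd < 0) stop("'pixel_noise_sd' must be >= 0")
  if (isTRUE(all.equal(left$projection, right$projection)))
    stop("left and right cameras must not be identical")
  structure(list(left = left, right = right, fps = fps,
                 sync_offset_frames = as.integer(sync_offset_frames),
                 convergence_angle = convergence_angle,
                 tripod_height = tripod_height, baseline = baseline,
                 pixel_noise_sd = pixel_noise_sd),
            class = "stereo_rig")
}

#' @export
print.stereo_rig <- function(x, ...) {
  cat("<stereo_rig> ", x$fps, " fps, baseline ", x$baseline,
      " cm, sync offset ", x$sync_offset_frames, " frames, pixel noise sd ",
      x$pixel_noise_sd, " px\n", sep = "")
  invisible(x)
}

#' Default synthetic filming rig
#'
#' Two verging cameras 20 cm apart on 10 cm tripods, standing off from the
#' jump arena and aimed at its centre, filming at 240 fps. The jump arena is
#' the region around the world origin with travel along +x and ground at
#' z = 0.
#'
#' @param fps frames per second.
#' @param baseline camera separation, cm.
#' @param tripod_height camera height, cm.
#' @param standoff distance from the arena centreline (cm) at which the
#'   tripods stand.
#' @param target world point both cameras are aimed at.
#' @param focal_px,image_size sensor model passed to [make_camera()].
#' @param pixel_noise_sd landmark digitization noise, pixels.
#' @param sync_offset_frames planted right-camera frame offset.
#' @return A [stereo_rig()].
#' @export
default_stereo_rig <- function(fps = 240, baseline = 20, tripod_height = 10,
                               standoff = 150, target = c(60, 0, 15),
                               focal_px = 1400, image_size = c(1920L, 1080L),
                               pixel_noise_sd = 0, sync_offset_frames = 0L) {
  pl <- c(target[1] - baseline / 2, -standoff, tripod_height)
  pr <- c(target[1] + baseline / 2, -standoff, tripod_height)
  stereo_rig(
    left  = make_camera(pl, target, focal_px, image_size),
    right = make_camera(pr, target, focal_px, image_size),
    fps = fps, sync_offset_frames = sync_offset_frames,
    tripod_height = tripod_height, baseline = baseline,
    pixel_noise_sd = pixel_noise_sd)
}
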