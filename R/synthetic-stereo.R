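#' Checkerboard calibration view
#'
#' One synchronized stereo image pair of the planar calibration board:
#' the board-frame corner grid, its rigid pose in the world, and the pixel
#' positions of every inner corner in both cameras.
#'
#' @param board_id identifier.
#' @param square_size square edge, cm.
#' @param rows,cols inner-corner grid size.
#' @param pose list with rotation `R` (3x3) and translation `t` (cm) mapping
#'   board-frame points to world points.
#' @param corners_3d (rows*cols) x 3 board-frame coordinates (z = 0).
#' @param corners_px_left,corners_px_right (rows*cols) x 2 pixel coordinates.
#' @return An object of class `checkerboard_view`.
#' @export
checkerboard_view <- function(board_id, square_size, rows, cols, pose,
                              corners_3d, corners_px_left, corners_px_right) {
  corners_3d <- as.matrix(corners_3d)
  if (nrow(corners_3d) != rows * cols)
    stop("corner count must equal rows * cols")
  if (max(abs(corners_3d[, 3])) > 1e-9)
    stop("board-frame corners must be coplanar (z = 0)")
  structure(list(board_id = board_id, square_size = square_size,
                 rows = rows, cols = cols, pose = pose,
                 corners_3d = corners_3d,
                 corners_px_left = as.matrix(corners_px_left),
                 corners_px_right = as.matrix(corners_px_right)),
            class = "checkerboard_view")
}

# World-frame corner coordinates of a view (precomputed attribute when the
# view was read from a correspondence table).
corners_world <- function(view) {
  cw <- attr(view, "corners_world")
  if (!is.null(cw)) return(cw)
  sweep(view$corners_3d %*% t(view$pose$R), 2, -view$pose$t)
}

# Corner-grid width of the board, cm (used to normalize QC discrepancies).
board_width <- function(view) (view$cols - 1) * view$square_size

#' Render a trajectory through a stereo rig
#'
#' Projects the snout and cloaca of a ground-truth trajectory through both
#' cameras, adds isotropic Gaussian pixel noise (`rig$pixel_noise_sd`),
#' shifts the right camera's frame counter by `rig$sync_offset_frames`, and
#' produces the per-camera brightness traces used for flash
#' synchronization: flat at `base_brightness` with a single spike at
#' `flash_frame` (shifted on the right camera). Points behind a camera or
#' outside its sensor are kept in the table flagged `visible = FALSE`.
#'
#' @param truth a [trajectory3d()].
#' @param rig a [stereo_rig()].
#' @param flash_frame 0-based left-camera frame index of the flash.
#' @param trial_id identifier copied into the landmark table.
#' @param base_brightness,flash_brightness brightness trace levels.
#' @return A list: `landmarks` (data.frame `trial_id`, `camera`, `frame`,
#'   `landmark`, `u`, `v`, `visible`), `brightness` (list of numeric traces
#'   `left`, `right` indexed by frame + 1), and `rig`.
#' @export
render_stereo <- function(truth, rig, flash_frame = 2L, trial_id = "trial",
                          base_brightness = 100, flash_brightness = 255) {
  stopifnot(inherits(truth, "trajectory3d"), inherits(rig, "stereo_rig"))
  n <- n_frames(truth)
  off <- rig$sync_offset_frames
  one_cam <- function(cam, cam_name, frame_shift) {
    do.call(rbind, lapply(c("snout", "cloaca"), function(lm) {
      pr <- project_points(cam, truth[[lm]])
      noise <- if (rig$pixel_noise_sd > 0)
        matrix(stats::rnorm(2 * n, 0, rig$pixel_noise_sd), n, 2)
      else matrix(0, n, 2)
      data.frame(trial_id = trial_id, camera = cam_name,
                 frame = seq_len(n) - 1L + frame_shift, landmark = lm,
                 u = pr$u + noise[, 1], v = pr$v + noise[, 2],
                 visible = pr$visible, stringsAsFactors = FALSE)
    }))
  }
  landmarks <- rbind(one_cam(rig$left, "left", 0L),
                     one_cam(rig$right, "right", off))
  mk_trace <- function(spike_at) {
    b <- rep(base_brightness, n + abs(off) + 4L)
    idx <- spike_at + 1L
    if (idx >= 1 && idx <= length(b)) b[idx] <- flash_brightness
    b
  }
  list(landmarks = landmarks,
       brightness = list(left = mk_trace(flash_frame),
                         right = mk_trace(flash_frame + off)),
       rig = rig)
}

#' Generate checkerboard calibration views
#'
#' Places a planar checkerboard at `n_poses` random positions and
#' orientations inside the jump volume and projects its inner corners
#' through both cameras of the rig (with the rig's pixel noise).
#' `corruption` plants quality-control failures: entry i displaces view i's
#' corners in 3D by a Gaussian perturbation with per-axis sd
#' `corruption[i] * board width` before projection, so both cameras see a
#' consistently wrong board and the planted relative inaccuracy scales with
#' `corruption[i]`. The perturbation pattern for a view is drawn once and
#' scaled, so increasing `corruption` monotonically increases the planted
#' discrepancy.
#'
#' @param rig a [stereo_rig()].
#' @param n_poses number of board placements (the field protocol uses
#'   10-20).
#' @param seed integer seed.
#' @param rows,cols inner-corner grid, default 6 x 8.
#' @param square_size cm, default 2.5.
#' @param corruption numeric vector (recycled to `n_poses`) of planted
#'   corner-displacement fractions; 0 = clean view.
#' @param volume list with `x`, `y`, `z` ranges (cm) in which board centres
#'   are placed.
#' @return A list of [checkerboard_view()] objects.
#' @export
generate_checkerboard_views <- function(rig, n_poses = 12L, seed = NULL,
                                        rows = 6L, cols = 8L,
                                        square_size = 2.5, corruption = 0,
                                        volume = list(x = c(20, 100),
                                                      y = c(-15, 15),
                                                      z = c(8, 30))) {
  if (n_poses < 1) stop("'n_poses' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  corruption <- rep_len(corruption, n_poses)
  gx <- (seq_len(cols) - (cols + 1) / 2) * square_size
  gy <- (seq_len(rows) - (rows + 1) / 2) * square_size
  corners <- cbind(rep(gx, times = rows), rep(gy, each = cols), 0)
  bw <- (cols - 1) * square_size
  lapply(seq_len(n_poses), function(i) {
    centre <- c(stats::runif(1, volume$x[1], volume$x[2]),
                stats::runif(1, volume$y[1], volume$y[2]),
                stats::runif(1, volume$z[1], volume$z[2]))
    # board roughly facing the cameras (-y), with random tilt
    R <- rotation_between(c(0, 0, 1), unit(c(stats::runif(1, -0.3, 0.3), -1,
                                             stats::runif(1, -0.3, 0.3))))
    R <- R %*% rotation_about_axis(c(0, 0, 1), stats::runif(1, -pi, pi))
    world <- sweep(corners %*% t(R), 2, -centre)
    if (corruption[i] > 0) {
      pattern <- matrix(stats::rnorm(length(world)), nrow(world), 3)
      world <- world + corruption[i] * bw * pattern
    }
    noise <- function() {
      if (rig$pixel_noise_sd > 0)
        matrix(stats::rnorm(2 * nrow(world), 0, rig$pixel_noise_sd),
               nrow(world), 2)
      else 0
    }
    pl <- project_points(rig$left, world)
    pr <- project_points(rig$right, world)
    checkerboard_view(board_id = i, square_size = square_size,
                      rows = rows, cols = cols,
                      pose = list(R = R, t = centre),
                      corners_3d = corners,
                      corners_px_left = cbind(pl$u, pl$v) + noise(),
                      corners_px_right = cbind(pr$u, pr$v) + noise())
  })
}
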