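#' Estimate the camera synchronization offset from flash spikes
#'
#' Both cameras record a single flash; the integer frame offset between the
#' two recordings is the difference of the spike positions:
#' `offset = argmax(right) - argmax(left)`. A spike must stand out from the
#' trace baseline (median) by at least `min_prominence` brightness units in
#' both traces.
#'
#' @param brightness_left,brightness_right numeric brightness traces, one
#'   value per frame (frame 0 first).
#' @param min_prominence required spike height above the trace median.
#' @return Integer frame offset of the right camera relative to the left.
#' @examples
#' l <- c(rep(100, 10), 255, rep(100, 10))
#' r <- c(rep(100, 13), 255, rep(100, 7))
#' estimate_sync_offset(l, r)  # 3
#' @export
estimate_sync_offset <- function(brightness_left, brightness_right,
                                 min_prominence = 10) {
  spike <- function(b, side) {
    prom <- max(b) - stats::median(b)
    if (!is.finite(prom) || prom < min_prominence)
      stop("synchronization failure: no flash spike with prominence >= ",
           min_prominence, " in the ", side, " trace", call. = FALSE)
    which.max(b) - 1L
  }
  spike(brightness_right, "right") - spike(brightness_left, "left")
}

# Isotropic normalization (Hartley) for DLT conditioning: translate the
# centroid to the origin and scale mean distance to sqrt(d).
.normalizing_transform <- function(pts) {
  d <- ncol(pts)
  centroid <- colMeans(pts)
  centred <- sweep(pts, 2, centroid)
  md <- mean(sqrt(rowSums(centred^2)))
  s <- if (md > 0) sqrt(d) / md else 1
  Tm <- diag(c(rep(s, d), 1))
  Tm[seq_len(d), d + 1] <- -s * centroid
  Tm
}

#' Resect a camera from 3D-2D correspondences
#'
#' Normalized direct-linear-transform estimation of a 3x4 projection matrix
#' from known world points and their pixel positions, minimizing algebraic
#' error; correspondences may span several calibration-board poses, giving
#' the non-coplanar point cloud the estimate requires.
#'
#' @param points_3d n x 3 world coordinates (cm), n >= 6, not all coplanar.
#' @param points_2d n x 2 pixel coordinates.
#' @param image_size sensor size passed to [camera_model()].
#' @return A [camera_model()] with attribute `rms_reprojection_px`.
#' @export
resect_camera <- function(points_3d, points_2d, image_size = c(1920L, 1080L)) {
  points_3d <- as.matrix(points_3d); points_2d <- as.matrix(points_2d)
  n <- nrow(points_3d)
  if (n < 6L || nrow(points_2d) != n)
    stop("degenerate geometry: need >= 6 matched 3D-2D correspondences")
  sv <- svd(sweep(points_3d, 2, colMeans(points_3d)))$d
  if (sv[3] < 1e-6 * sv[1])
    stop("degenerate geometry: 3D points are (near-)coplanar; ",
         "include correspondences from multiple board poses")
  T3 <- .normalizing_transform(points_3d)
  T2 <- .normalizing_transform(points_2d)
  X <- T3 %*% rbind(t(points_3d), 1)
  x <- T2 %*% rbind(t(points_2d), 1)
  A <- matrix(0, 2 * n, 12)
  for (i in seq_len(n)) {
    Xi <- X[, i]
    A[2 * i - 1, ] <- c(Xi, rep(0, 4), -x[1, i] * Xi)
    A[2 * i, ]     <- c(rep(0, 4), Xi, -x[2, i] * Xi)
  }
  p <- svd(A, nu = 0)$v[, 12]
  P <- solve(T2) %*% matrix(p, 3, 4, byrow = TRUE) %*% T3
  P <- P / sqrt(sum(P^2))
  if (det(P[, 1:3]) < 0) P <- -P     # keep points in front at positive depth
  cam <- camera_model(P, image_size)
  pr <- project_points(cam, points_3d)
  attr(cam, "rms_reprojection_px") <-
    sqrt(mean((pr$u - points_2d[, 1])^2 + (pr$v - points_2d[, 2])^2))
  cam
}

#' Triangulate one point from a stereo observation
#'
#' Homogeneous linear least-squares (DLT) intersection of the two viewing
#' rays. Reliability is judged from the conditioning of the 4x4 design
#' matrix: identical cameras or near-parallel rays leave the solution
#' under-determined and raise an error rather than returning an arbitrary
#' point.
#'
#' @param left_px,right_px length-2 pixel coordinates.
#' @param left,right [camera_model()] objects.
#' @param conditioning_tol minimum acceptable ratio of the third to first
#'   singular value of the design matrix.
#' @return Length-3 world point (cm) with attribute `reprojection_error_px`
#'   (RMS over the two views).
#' @export
triangulate_point <- function(left_px, right_px, left, right,
                              conditioning_tol = 1e-9) {
  row_pair <- function(px, P) {
    rbind(px[1] * P[3, ] - P[1, ],
          px[2] * P[3, ] - P[2, ])
  }
  A <- rbind(row_pair(left_px, left$projection),
             row_pair(right_px, right$projection))
  A <- A / max(abs(A))
  s <- svd(A)
  if (s$d[3] / s$d[1] < conditioning_tol)
    stop("unreliable triangulation: viewing rays are (near-)parallel ",
         "or the cameras coincide", call. = FALSE)
  Xh <- s$v[, 4]
  X <- Xh[1:3] / Xh[4]
  rl <- project_points(left, matrix(X, 1)); rr <- project_points(right, matrix(X, 1))
  attr(X, "reprojection_error_px") <-
    sqrt(mean(c((rl$u - left_px[1])^2 + (rl$v - left_px[2])^2,
                (rr$u - right_px[1])^2 + (rr$v - right_px[2])^2)))
  X
}

# Vectorized triangulation of matched pixel matrices (n x 2 each).
triangulate_points <- function(left_px, right_px, left, right, ...) {
  t(vapply(seq_len(nrow(left_px)), function(i) {
    as.numeric(triangulate_point(left_px[i, ], right_px[i, ], left, right, ...))
  }, numeric(3)))
}

# Rigid (rotation + translation) least-squares fit of point set A onto B
# (Kabsch). Returns the RMS residual after the fit.
rigid_fit_rms <- function(A, B) {
  ca <- colMeans(A); cb <- colMeans(B)
  H <- t(sweep(A, 2, ca)) %*% sweep(B, 2, cb)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- sweep(sweep(A, 2, ca) %*% t(R), 2, -cb)
  sqrt(mean(rowSums((fitted - B)^2)))
}

#' Quality control of calibration views
#'
#' For each checkerboard view, triangulates every inner corner from the two
#' pixel sets, rigidly fits the known board-frame corner model onto the
#' reconstruction, and expresses the RMS corner discrepancy relative to the
#' corner-grid width of the board. Views whose relative stereo inaccuracy
#' exceeds `threshold` (default 1%) are rejected.
#'
#' @param views list of [checkerboard_view()] objects.
#' @param left,right [camera_model()] objects.
#' @param threshold maximum acceptable relative inaccuracy.
#' @return A data.frame (class `calibration_qc_report`) with one row per
#'   view: `board_id`, `inaccuracy`, `threshold`, `accepted`, `reason`.
#' @export
stereo_qc <- function(views, left, right, threshold = 0.01) {
  rows <- lapply(views, function(v) {
    if (is.null(v$corners_px_left) || is.null(v$corners_px_right) ||
        nrow(v$corners_px_left) == 0L || nrow(v$corners_px_right) == 0L)
      return(data.frame(board_id = v$board_id, inaccuracy = NA_real_,
                        threshold = threshold, accepted = FALSE,
                        reason = "view visible in one camera only"))
    recon <- triangulate_points(v$corners_px_left, v$corners_px_right,
                                left, right)
    inacc <- rigid_fit_rms(v$corners_3d, recon) / board_width(v)
    data.frame(board_id = v$board_id, inaccuracy = inacc,
               threshold = threshold, accepted = inacc <= threshold,
               reason = if (inacc <= threshold) "" else
                 "relative stereo inaccuracy above threshold")
  })
  out <- do.call(rbind, rows)
  class(out) <- c("calibration_qc_report", class(out))
  out
}

#' Calibrate a stereo camera pair from checkerboard views
#'
#' Resects both cameras from the pooled world-frame corner correspondences,
#' runs the 1% stereo quality control, and re-resects using only the
#' accepted views.
#'
#' @param views list of [checkerboard_view()] objects.
#' @param image_size sensor size.
#' @param qc_threshold relative-inaccuracy threshold, default 0.01.
#' @return List with `left`, `right` ([camera_model()]), `qc`
#'   (the QC report) and `n_views_used`.
#' @export
calibrate_stereo <- function(views, image_size = c(1920L, 1080L),
                             qc_threshold = 0.01) {
  pool <- function(vs) {
    w <- do.call(rbind, lapply(vs, corners_world))
    l <- do.call(rbind, lapply(vs, function(v) v$corners_px_left))
    r <- do.call(rbind, lapply(vs, function(v) v$corners_px_right))
    list(w = w, l = l, r = r)
  }
  p <- pool(views)
  left <- resect_camera(p$w, p$l, image_size)
  right <- resect_camera(p$w, p$r, image_size)
  qc <- stereo_qc(views, left, right, qc_threshold)
  keep <- which(qc$accepted)
  if (length(keep) == 0L)
    stop("calibration failed: every view rejected by stereo QC")
  if (length(keep) < length(views)) {
    p <- pool(views[keep])
    left <- resect_camera(p$w, p$l, image_size)
    right <- resect_camera(p$w, p$r, image_size)
    qc <- stereo_qc(views, left, right, qc_threshold)
  }
  list(left = left, right = right, qc = qc, n_views_used = length(keep))
}

#' Reconstruct a 3D trajectory from stereo landmark tracks
#'
#' Applies the synchronization offset to the right camera's frame counter,
#' pairs frames observed in both views, triangulates snout and cloaca per
#' frame, and timestamps frames at `frame/fps`. Frames missing from either
#' view (or flagged invisible) form gaps: gaps of at most `max_gap` frames
#' are filled by linear interpolation and flagged; longer gaps reject the
#' trajectory.
#'
#' @param landmarks data.frame with columns `trial_id`, `camera`
#'   (`"left"`/`"right"`), `frame`, `landmark` (`"snout"`/`"cloaca"`),
#'   `u`, `v` and optionally `visible`.
#' @param left,right [camera_model()] objects.
#' @param sync_offset integer right-minus-left frame offset (from
#'   [estimate_sync_offset()]).
#' @param fps frames per second.
#' @param max_gap longest interpolatable gap, frames.
#' @param min_coverage minimum fraction of the frame span that must be
#'   observed in both views.
#' @return A raw [trajectory3d()]; interpolated frames flagged.
#' @export
reconstruct_trajectory <- function(landmarks, left, right, sync_offset = 0L,
                                   fps = 240, max_gap = 2L,
                                   min_coverage = 0.9) {
  stopifnot(all(c("camera", "frame", "landmark", "u", "v") %in%
                  names(landmarks)))
  if (is.null(landmarks$visible)) landmarks$visible <- TRUE
  lm <- landmarks[landmarks$visible, ]
  lm$frame_aligned <- ifelse(lm$camera == "right",
                             lm$frame - sync_offset, lm$frame)
  pick <- function(cam, landmark) {
    s <- lm[lm$camera == cam & lm$landmark == landmark, ]
    s[order(s$frame_aligned), c("frame_aligned", "u", "v")]
  }
  parts <- list(ls = pick("left", "snout"), lc = pick("left", "cloaca"),
                rs = pick("right", "snout"), rc = pick("right", "cloaca"))
  common <- Reduce(intersect, lapply(parts, function(p) p$frame_aligned))
  if (length(common) < 2L)
    stop("too few frames observed in both views")
  span <- seq(min(common), max(common))
  if (length(common) / length(span) < min_coverage)
    stop(sprintf("landmark coverage %.0f%% of the frame span is below %.0f%%",
                 100 * length(common) / length(span), 100 * min_coverage))
  missing <- setdiff(span, common)
  if (length(missing)) {
    runs <- split(missing, cumsum(c(1, diff(missing) != 1)))
    too_long <- vapply(runs, length, 1L) > max_gap
    if (any(too_long))
      stop("trajectory rejected: gap of ",
           max(vapply(runs, length, 1L)), " frames (> ", max_gap,
           ") at frames ",
           paste(vapply(runs[too_long], function(r)
             paste0(min(r), "-", max(r)), ""), collapse = ", "))
  }
  px <- function(p) {
    u <- stats::approx(p$frame_aligned, p$u, xout = span)$y
    v <- stats::approx(p$frame_aligned, p$v, xout = span)$y
    cbind(u, v)
  }
  snout <- triangulate_points(px(parts$ls), px(parts$rs), left, right)
  cloaca <- triangulate_points(px(parts$lc), px(parts$rc), left, right)
  trajectory3d(time = span / fps, snout = snout, cloaca = cloaca,
               frame_rate = fps,
               interpolated = span %in% missing)
}
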