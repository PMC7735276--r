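test_that("sync offset is the spike-position difference", {
  flat <- rep(100, 30)
  spike_at <- function(i) { b <- flat; b[i + 1] <- 255; b }
  expect_equal(estimate_sync_offset(spike_at(10), spike_at(10)), 0L)
  expect_equal(estimate_sync_offset(spike_at(10), spike_at(13)), 3L)
  # noisy traces with planted negative offset, generator round trip
  rig <- test_rig(sync_offset_frames = -7L)
  tr <- simulate_jump(jump_params(300, 45), fps = 240)
  set.seed(2)
  rend <- render_stereo(tr, rig, flash_frame = 12L)
  noisy <- lapply(rend$brightness, function(b) b + stats::rnorm(length(b)))
  expect_equal(estimate_sync_offset(noisy$left, noisy$right), -7L)
  # no spike above prominence: synchronization failure
  expect_error(estimate_sync_offset(flat, spike_at(4)), "synchronization")
})

test_that("resection recovers a known camera exactly from noiseless points", {
  set.seed(31)
  cam <- make_camera(c(50, -150, 10), c(60, 0, 15))
  pts <- cbind(runif(12, 10, 110), runif(12, -15, 15), runif(12, 0, 30))
  px <- project_points(cam, pts)
  est <- resect_camera(pts, cbind(px$u, px$v))
  expect_lt(attr(est, "rms_reprojection_px"), 1e-8)
  # recovered projection proportional to the truth
  Pt <- cam$projection / sqrt(sum(cam$projection^2))
  Pe <- est$projection * sign(sum(est$projection * Pt))
  expect_lt(max(abs(Pe - Pt)), 1e-9)
})

test_that("resection reprojection error tracks the pixel noise level", {
  set.seed(32)
  cam <- make_camera(c(50, -150, 10), c(60, 0, 15))
  pts <- cbind(runif(60, 10, 110), runif(60, -15, 15), runif(60, 0, 30))
  px <- project_points(cam, pts)
  obs <- cbind(px$u, px$v) + matrix(rnorm(120, 0, 0.5), 60, 2)
  est <- resect_camera(pts, obs)
  expect_gt(attr(est, "rms_reprojection_px"), 0.3)
  expect_lt(attr(est, "rms_reprojection_px"), 0.8)
})

test_that("degenerate resection geometries are refused", {
  cam <- make_camera(c(0, -100, 10), c(0, 0, 10))
  pts5 <- cbind(runif(5, -20, 20), runif(5, -5, 5), runif(5, 0, 20))
  px5 <- project_points(cam, pts5)
  expect_error(resect_camera(pts5, cbind(px5$u, px5$v)), "degenerate")
  coplanar <- cbind(runif(20, -20, 20), 0, runif(20, 0, 20))
  pxc <- project_points(cam, coplanar)
  expect_error(resect_camera(coplanar, cbind(pxc$u, pxc$v)), "coplanar")
})

test_that("triangulation round-trips noiseless projections", {
  rig <- test_rig()
  X <- c(10, 20, 5)
  pl <- project_points(rig$left, matrix(X, 1))
  pr <- project_points(rig$right, matrix(X, 1))
  Xhat <- triangulate_point(c(pl$u, pl$v), c(pr$u, pr$v),
                            rig$left, rig$right)
  expect_lt(max(abs(Xhat - X)), 1e-6)
  expect_lt(attr(Xhat, "reprojection_error_px"), 1e-6)
})

test_that("triangulation error under pixel noise matches error propagation", {
  # depth dominates stereo error; first-order propagation for a verging
  # pair predicts a per-point sd of sqrt(2) * d^2 / (f * b) * sigma_px with
  # d the distance to the baseline midpoint, f the focal length (px), b the
  # baseline. The measured RMS must track that prediction (no blow-up) and
  # stay sub-centimetre over the jump volume.
  rig <- test_rig()
  f <- 1400; b <- rig$baseline
  mid <- c(60, -150, 10)
  set.seed(41)
  sim <- replicate(300, {
    X <- c(runif(1, 20, 100), runif(1, -15, 15), runif(1, 0, 25))
    pl <- project_points(rig$left, matrix(X, 1))
    pr <- project_points(rig$right, matrix(X, 1))
    Xhat <- triangulate_point(c(pl$u, pl$v) + rnorm(2, 0, 0.5),
                              c(pr$u, pr$v) + rnorm(2, 0, 0.5),
                              rig$left, rig$right)
    d <- sqrt(sum((X - mid)^2))
    c(err = sqrt(sum((Xhat - X)^2)),
      pred = sqrt(2) * d^2 / (f * b) * 0.5)
  })
  rms <- sqrt(mean(sim["err", ]^2))
  pred_rms <- sqrt(mean(sim["pred", ]^2))
  expect_lt(rms / pred_rms, 1.5)
  expect_gt(rms / pred_rms, 0.5)
  expect_lt(rms, 1)
})

test_that("identical cameras raise an unreliable-triangulation error", {
  cam <- make_camera(c(0, -100, 10), c(0, 0, 10))
  expect_error(triangulate_point(c(960, 540), c(960, 540), cam, cam),
               "unreliable triangulation")
})

test_that("stereo QC accepts clean views and rejects planted corruption", {
  rig <- test_rig()
  corruption <- rep(0, 12); corruption[4] <- 0.05
  views <- generate_checkerboard_views(rig, 12, seed = 51,
                                       corruption = corruption)
  clean_cal <- calibrate_stereo(views)
  expect_identical(which(!clean_cal$qc$accepted), 4L)
  expect_lt(max(clean_cal$qc$inaccuracy[-4]), 0.01)
  # noiseless clean views: inaccuracy numerically zero
  expect_lt(max(clean_cal$qc$inaccuracy[-4]), 1e-8)
  # vacuous threshold accepts everything
  qc_all <- stereo_qc(views, clean_cal$left, clean_cal$right, threshold = 1)
  expect_true(all(qc_all$accepted))
  # view missing one camera is rejected with a reason
  v1 <- views[[1]]; v1$corners_px_right <- v1$corners_px_right[0, , drop = FALSE]
  qc1 <- stereo_qc(list(v1), clean_cal$left, clean_cal$right)
  expect_false(qc1$accepted)
  expect_match(qc1$reason, "one camera")
})

test_that("QC rejection is monotone in planted corruption", {
  rig <- test_rig()
  levels <- c(0.005, 0.02, 0.05, 0.1)
  inacc <- vapply(levels, function(f) {
    views <- generate_checkerboard_views(rig, 6, seed = 60,
                                         corruption = c(f, 0, 0, 0, 0, 0))
    cal <- resect_pair <- calibrate_stereo(views[-1])   # calibrate on clean
    stereo_qc(views[1], cal$left, cal$right)$inaccuracy
  }, 1)
  expect_true(all(diff(inacc) > 0))
  expect_true(all(inacc[levels >= 0.02] > 0.01))
})

test_that("trajectory reconstruction round-trips and honours the sync offset", {
  rig <- test_rig(sync_offset_frames = 3L)
  tr <- simulate_jump(jump_params(300, 45), fps = 240)
  rend <- render_stereo(tr, rig, flash_frame = 5L)
  off <- estimate_sync_offset(rend$brightness$left, rend$brightness$right)
  expect_equal(off, 3L)
  rec <- reconstruct_trajectory(rend$landmarks, rig$left, rig$right, off,
                                rig$fps)
  expect_lt(max(abs(rec$cloaca - tr$cloaca)), 1e-6)
  expect_lt(max(abs(rec$snout - tr$snout)), 1e-6)
  # timestamps step exactly 1/240 s
  expect_equal(unique(round(diff(rec$time), 12)), 1 / 240)
  # ignoring the offset leaves a systematic error
  rec_bad <- reconstruct_trajectory(rend$landmarks, rig$left, rig$right, 0L,
                                    rig$fps)
  expect_gt(max(abs(rec_bad$cloaca[, 1] - tr$cloaca[seq_len(nrow(rec_bad$cloaca)), 1])),
            0.1)
})

test_that("short gaps are interpolated and long gaps reject the trajectory", {
  rig <- test_rig()
  tr <- simulate_jump(jump_params(300, 45), fps = 240)
  rend <- render_stereo(tr, rig)
  lm <- rend$landmarks
  drop2 <- !(lm$camera == "left" & lm$frame %in% c(20, 21))
  rec <- reconstruct_trajectory(lm[drop2, ], rig$left, rig$right, 0L, 240)
  expect_equal(sum(rec$interpolated), 2L)
  expect_lt(max(abs(rec$cloaca - tr$cloaca)), 0.2)  # ballistic path ~linear over 2 frames
  drop4 <- !(lm$camera == "left" & lm$frame %in% 20:23)
  expect_error(reconstruct_trajectory(lm[drop4, ], rig$left, rig$right,
                                      0L, 240), "gap")
})
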