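test_that("planted hops match the projectile closed forms exactly", {
  cases <- list(c(speed = 300, elev = 45), c(speed = 342.96, elev = 45),
                c(speed = 200, elev = 30), c(speed = 250, elev = 70))
  for (cs in cases) {
    tr <- simulate_jump(jump_params(cs[["speed"]], cs[["elev"]]), fps = 240)
    range_cf <- cs[["speed"]]^2 * sin(2 * cs[["elev"]] * pi / 180) / 981
    apex_cf <- cs[["speed"]]^2 * sin(cs[["elev"]] * pi / 180)^2 / (2 * 981)
    expect_equal(tr$truth$distance, range_cf, tolerance = 1e-9)
    expect_equal(tr$truth$height, apex_cf, tolerance = 1e-9)
    # sampled cloaca path obeys the same physics
    expect_lt(abs(max(tr$cloaca[, 3]) - apex_cf), 981 / 2 / 480^2 + 1e-9)
    expect_equal(max(tr$cloaca[, 1]) - tr$cloaca[1, 1], range_cf,
                 tolerance = 1e-9)
  }
  # v = 300 at 45 degrees: 300^2 sin(90) / 981 and 45000 / 1962
  tr <- simulate_jump(jump_params(300, 45), fps = 240)
  expect_equal(tr$truth$distance, 91.7431192660551, tolerance = 1e-12)
  expect_equal(tr$truth$height, 22.9357798165138, tolerance = 1e-12)
})

test_that("a vertical jump has zero horizontal range", {
  tr <- simulate_jump(jump_params(250, 90), fps = 240)
  expect_equal(tr$truth$distance, 0, tolerance = 1e-9)
  expect_lt(max(abs(tr$cloaca[, 1] - tr$cloaca[1, 1])), 1e-9)
})

test_that("planted body angles appear at the first and last flight frame", {
  tr <- simulate_jump(jump_params(300, 45, body_angle_takeoff = 31.78,
                                  body_angle_landing = -22.18), fps = 240)
  elev <- function(i) {
    v <- tr$snout[i, ] - tr$cloaca[i, ]
    asin(v[3] / sqrt(sum(v^2))) * 180 / pi
  }
  expect_equal(elev(1), 31.78, tolerance = 1e-9)
  expect_equal(elev(nrow(tr$cloaca)), -22.18, tolerance = 1e-9)
})

test_that("invalid jump parameters are rejected", {
  expect_error(jump_params(-5, 45), "takeoff_speed")
  expect_error(jump_params(300, 0), "takeoff_elevation")
  expect_error(simulate_jump(jump_params(300, 45), fps = -1), "fps")
})

test_that("cohort generator is deterministic and hits preset means", {
  a <- simulate_cohort("F0_range-core_female", seed = 11)
  b <- simulate_cohort("F0_range-core_female", seed = 11)
  expect_identical(a$morphology, b$morphology)
  expect_identical(a$jump_params, b$jump_params)

  # sample means converge to the preset means at rate se*sqrt(n)/sqrt(N)
  big <- simulate_cohort("F0_range-core_female", seed = 3, n = 10000)
  spec <- cohort_presets()[["F0_range-core_female"]]
  sd_ind <- spec$trait_ses[["svl"]] * sqrt(spec$n)
  expect_lt(abs(mean(big$morphology$svl) - 110.06),
            4 * sd_ind / sqrt(10000))
  d <- vapply(big$jump_params, function(jp)
    jp$takeoff_speed^2 * sin(2 * jp$takeoff_elevation * pi / 180) / 981, 1)
  sd_d <- spec$trait_ses[["distance"]] * sqrt(spec$n)
  expect_lt(abs(mean(d) - 60.13), 4 * sd_d / sqrt(10000))
})

test_that("unknown presets are rejected with the valid list", {
  expect_error(simulate_cohort("F2_mars_female", seed = 1),
               "valid presets.*F0_range-core_female")
})

test_that("every reference cohort row maps to one preset", {
  p <- cohort_presets()
  expect_length(p, 10L)
  expect_setequal(vapply(p, function(s) s$n, 1L),
                  c(34L, 56L, 29L, 19L, 23L, 61L, 29L, 15L, 33L, 12L))
  for (s in p) {
    expect_true(all(s$trait_ses > 0))
    expect_gt(s$n, 0)
  }
})

test_that("noiseless stereo rendering reprojects truth exactly", {
  rig <- test_rig()
  tr <- simulate_jump(jump_params(300, 45), fps = 240)
  rend <- render_stereo(tr, rig)
  lm <- rend$landmarks
  sn_l <- lm[lm$camera == "left" & lm$landmark == "snout", ]
  pr <- project_points(rig$left, tr$snout)
  expect_equal(sn_l$u, pr$u, tolerance = 1e-12)
  expect_equal(sn_l$v, pr$v, tolerance = 1e-12)
  expect_true(all(lm$visible))
})

test_that("pixel noise has the planted RMS and the sync offset shifts the flash", {
  rig <- test_rig(pixel_noise_sd = 0.5, sync_offset_frames = 3L)
  tr <- simulate_jump(jump_params(300, 45), fps = 240)
  set.seed(5)
  rend <- render_stereo(tr, rig, flash_frame = 5L)
  clean <- render_stereo(tr, test_rig(sync_offset_frames = 3L),
                         flash_frame = 5L)
  resid <- c(rend$landmarks$u - clean$landmarks$u,
             rend$landmarks$v - clean$landmarks$v)
  expect_equal(sqrt(mean(resid^2)), 0.5, tolerance = 0.1)
  expect_equal(which.max(rend$brightness$right) -
                 which.max(rend$brightness$left), 3L)
})

test_that("points behind a camera are flagged invisible, not dropped", {
  cam <- make_camera(c(0, -100, 10), c(0, 0, 10))
  behind <- matrix(c(0, -200, 10), 1)
  pr <- project_points(cam, behind)
  expect_false(pr$visible)
  expect_equal(nrow(pr), 1L)
})

test_that("checkerboard views are coplanar in the board frame and QC-clean", {
  rig <- test_rig()
  views <- generate_checkerboard_views(rig, 10, seed = 21)
  for (v in views) {
    expect_equal(nrow(v$corners_3d), v$rows * v$cols)
    expect_lt(max(abs(v$corners_3d[, 3])), 1e-12)
  }
  cal <- calibrate_stereo(views)
  expect_true(all(cal$qc$accepted))
  expect_error(generate_checkerboard_views(rig, 0), "n_poses")
})

test_that("raceway generator follows track, refusal and distance rules", {
  # constant 0.5 m hops, no refusals: exactly 30 hops
  tr <- simulate_raceway_trial(hop_distance_mean = 0.5, hop_distance_sd = 0,
                               refusal_prob = 0, seed = 1)
  expect_equal(sum(tr$events$event == "hop"), 30L)
  expect_false(tr$terminated_early)

  # refusal_prob = 1: terminated with zero hops
  tr2 <- simulate_raceway_trial(refusal_prob = 1, seed = 1)
  expect_true(tr2$terminated_early)
  expect_equal(sum(tr2$events$event == "hop"), 0L)
  expect_equal(sum(tr2$events$event == "refusal"), 10L)

  # Monte-Carlo: recovered mean hop distance near the planted mean
  tr3 <- simulate_raceway_trial(hop_distance_mean = 0.6,
                                hop_distance_sd = 0.1, refusal_prob = 0,
                                seed = 9)
  hops <- tr3$events[tr3$events$event == "hop", ]
  interior <- hops$distance[-nrow(hops)]   # last hop is clipped at the line
  expect_lt(abs(mean(interior) - 0.6), 2 * 0.1 / sqrt(length(interior)))

  expect_error(simulate_raceway_trial(hop_distance_mean = -1), "positive|> 0")
})

test_that("generators are reproducible under a fixed seed", {
  r1 <- simulate_raceway_trial(seed = 4)
  r2 <- simulate_raceway_trial(seed = 4)
  expect_identical(r1$events, r2$events)
  v1 <- generate_checkerboard_views(test_rig(), 5, seed = 4)
  v2 <- generate_checkerboard_views(test_rig(), 5, seed = 4)
  expect_identical(v1, v2)
})
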