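# Shared fixtures: a small noiseless rig and helpers used across test files.

test_rig <- function(pixel_noise_sd = 0, sync_offset_frames = 0L, fps = 240) {
  default_stereo_rig(fps = fps, pixel_noise_sd = pixel_noise_sd,
                     sync_offset_frames = sync_offset_frames)
}

# Full noiseless measurement chain for one set of jump parameters:
# simulate -> render -> sync -> triangulate -> align -> detect -> extract.
measure_jump <- function(params, rig = test_rig(), flash_frame = 2L) {
  traj <- simulate_jump(params, fps = rig$fps)
  rend <- render_stereo(traj, rig, flash_frame = flash_frame)
  off <- estimate_sync_offset(rend$brightness$left, rend$brightness$right)
  rec <- reconstruct_trajectory(rend$landmarks, rig$left, rig$right,
                                off, rig$fps)
  al <- align_trajectory(rec)
  br <- detect_takeoff_landing(al)
  extract_kinematics(al, br$takeoff, br$landing)
}

# Shortcut skipping the stereo stage (direct geometry path).
measure_jump_direct <- function(params, fps = 240, epsilon = 0.1) {
  al <- align_trajectory(simulate_jump(params, fps = fps))
  br <- detect_takeoff_landing(al, epsilon)
  extract_kinematics(al, br$takeoff, br$landing)
}

# Balanced nested dataset generator for the ANOVA tests.
balanced_nested <- function(n_per_pop = 5, cat_effect = 0, pop_sd = 0,
                            pops_per_cat = 2) {
  category <- rep(c("core", "front"), each = pops_per_cat * n_per_pop)
  population <- rep(sprintf("p%d", seq_len(2 * pops_per_cat)),
                    each = n_per_pop)
  y <- stats::rnorm(length(category)) +
    ifelse(category == "front", cat_effect, 0) +
    rep(stats::rnorm(2 * pops_per_cat, 0, pop_sd), each = n_per_pop)
  data.frame(y = y, category = category, population = population)
}
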