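#' Simulate a complete study dataset on disk
#'
#' Generates everything [run_pipeline()] consumes, with known ground truth:
#' a calibration correspondence table from checkerboard views, a landmark
#' table of every hop rendered through the stereo rig, a morphology table,
#' a raceway event table whose per-animal mean hop distance is correlated
#' with jump distance (planted coupling), and a ground-truth sidecar per
#' trial. Animals are spread over `populations_per_category` populations
#' within each invasion category; an optional per-population effect shifts
#' jump distances to plant a population signal.
#'
#' @param out_dir directory to write into (created).
#' @param n_per_population animals per population.
#' @param populations_per_category populations in each invasion category.
#' @param seed integer seed; the dataset is reproducible from it.
#' @param rig a [stereo_rig()]; default noiseless rig at 240 fps.
#' @param n_calibration_poses checkerboard placements (field protocol:
#'   10-20).
#' @param corrupt_views integer indices of calibration views to corrupt
#'   (5% corner displacement) to plant QC failures.
#' @param population_effect_sd sd (cm) of per-population random shifts in
#'   jump distance.
#' @param raceway_coupling correlation between raceway mean hop distance
#'   and jump distance.
#' @param presets two preset names (range-core first) used for the two
#'   categories.
#' @return Invisibly, a list with the paths written (`landmarks`,
#'   `correspondences`, `morphology`, `raceway`, `truth`) plus
#'   `sync_offset` and the `rig`.
#' @export
simulate_study <- function(out_dir, n_per_population = 10L,
                           populations_per_category = 2L, seed = 1L,
                           rig = default_stereo_rig(),
                           n_calibration_poses = 12L,
                           corrupt_views = integer(0),
                           population_effect_sd = 0,
                           raceway_coupling = 0.32,
                           presets = c("F0_range-core_female",
                                       "F0_invasion-front_female")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)
  corruption <- rep(0, n_calibration_poses)
  corruption[corrupt_views] <- 0.05
  views <- generate_checkerboard_views(rig, n_calibration_poses,
                                       corruption = corruption)
  write_correspondences(views, file.path(out_dir, "correspondences.csv"))

  morph_all <- NULL; lm_all <- NULL; truth_all <- NULL; race_all <- NULL
  pop_names <- list(
    "range-core" = paste0("core_pop", seq_len(populations_per_category)),
    "invasion-front" = paste0("front_pop", seq_len(populations_per_category)))
  for (preset in presets) {
    co <- simulate_cohort(preset,
                          n = n_per_population * populations_per_category,
                          kinematic_coupling = 0.3)
    cat_name <- co$spec$invasion_category
    pops <- rep(pop_names[[cat_name]], each = n_per_population)
    co$morphology$population <- pops
    pop_shift <- stats::rnorm(populations_per_category, 0,
                              population_effect_sd)
    for (i in seq_along(co$jump_params)) {
      aid <- co$morphology$animal_id[i]
      jp <- co$jump_params[[i]]
      if (population_effect_sd > 0) {
        shift <- pop_shift[match(pops[i], pop_names[[cat_name]])]
        d <- jp$takeoff_speed^2 * sin(2 * deg2rad(jp$takeoff_elevation)) / 981
        h <- d / 4 * tan(deg2rad(jp$takeoff_elevation))
        d <- max(d + shift, 5)
        el <- rad2deg(atan(4 * h / d))
        jp$takeoff_speed <- sqrt(981 * d / sin(2 * deg2rad(el)))
        jp$takeoff_elevation <- el
      }
      traj <- simulate_jump(jp, fps = rig$fps)
      rend <- render_stereo(traj, rig, trial_id = paste0(aid, "_j1"))
      lm_all <- rbind(lm_all, rend$landmarks)
      truth_all <- rbind(truth_all,
                         data.frame(trial_id = paste0(aid, "_j1"),
                                    as.data.frame(traj$truth)))
      # raceway mean hop correlated with jump distance (z-score coupling)
      zd <- (traj$truth$distance - co$spec$trait_means[["distance"]]) /
        (co$spec$trait_ses[["distance"]] * sqrt(co$spec$n))
      mhop <- 0.6 + 0.1 * (raceway_coupling * zd +
                             sqrt(1 - raceway_coupling^2) * stats::rnorm(1))
      tr <- simulate_raceway_trial(aid, hop_distance_mean = max(mhop, 0.1),
                                   hop_distance_sd = 0.05,
                                   refusal_prob = 0.02)
      race_all <- rbind(race_all, data.frame(animal_id = aid, tr$events))
    }
    morph_all <- rbind(morph_all, co$morphology)
  }
  paths <- list(
    landmarks = file.path(out_dir, "landmarks.csv"),
    correspondences = file.path(out_dir, "correspondences.csv"),
    morphology = file.path(out_dir, "morphology.csv"),
    raceway = file.path(out_dir, "raceway.csv"),
    truth = file.path(out_dir, "truth.csv"))
  write_pipeline_csv(lm_all, paths$landmarks, "landmarks")
  write_pipeline_csv(morph_all, paths$morphology, "morphology")
  write_pipeline_csv(race_all, paths$raceway, "raceway")
  utils::write.csv(truth_all, paths$truth, row.names = FALSE)
  invisible(c(paths, list(sync_offset = rig$sync_offset_frames, rig = rig)))
}
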