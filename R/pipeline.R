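#' Pipeline configuration
#'
#' Bundles the file paths and tuning parameters of a full run. All paths
#' must exist at run time except `out_dir`, which is created.
#'
#' @param landmark_csv,correspondence_csv,morphology_csv,raceway_csv input
#'   tables (`raceway_csv` optional).
#' @param out_dir output directory.
#' @param fps frames per second of the recordings.
#' @param qc_threshold calibration QC threshold (relative inaccuracy).
#' @param epsilon take-off/landing detection threshold, cm.
#' @param smooth logical; 5-frame velocity smoothing.
#' @param residual_grouping passed to [shape_residuals()].
#' @param stay_threshold backward-elimination stay threshold.
#' @param square_size calibration-board square size, cm.
#' @param seed integer seed recorded in the run log.
#' @param verbose print stage progress.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(landmark_csv, correspondence_csv,
                            morphology_csv, raceway_csv = NULL,
                            out_dir = "hoptrack_out", fps = 240,
                            qc_threshold = 0.01, epsilon = 0.1,
                            smooth = FALSE,
                            residual_grouping = "by-generation",
                            stay_threshold = 0.05, square_size = 2.5,
                            seed = 1L, verbose = TRUE) {
  for (p in c(landmark_csv, correspondence_csv, morphology_csv, raceway_csv))
    if (!file.exists(p)) stop("input file does not exist: ", p)
  structure(list(landmark_csv = landmark_csv,
                 correspondence_csv = correspondence_csv,
                 morphology_csv = morphology_csv, raceway_csv = raceway_csv,
                 out_dir = out_dir, fps = fps, qc_threshold = qc_threshold,
                 epsilon = epsilon, smooth = smooth,
                 residual_grouping = residual_grouping,
                 stay_threshold = stay_threshold, square_size = square_size,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "pipeline_config")
}

.stage <- function(log, config, name, expr) {
  if (config$verbose) message("[hoptrack] stage: ", name)
  cat(format(Sys.time(), "%H:%M:%S"), " stage ", name, "\n",
      file = log, append = TRUE, sep = "")
  tryCatch(expr, error = function(e)
    stop("pipeline halted at stage '", name, "': ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes calibrate -> synchronize -> reconstruct -> align -> kinematics
#' -> best jump -> shape residuals -> statistics, writing each stage's
#' outputs to `config$out_dir` before the next stage begins, together with
#' a run log (package version, seed, parameters, QC rejections). A stage
#' error halts the run naming the stage and the offending trial; outputs of
#' completed stages are retained.
#'
#' The landmark table may contain many trials (`trial_id`); per-trial
#' brightness traces are not tabulated, so the synchronization offset is
#' taken from `sync_offset` (estimate it with [estimate_sync_offset()] from
#' the rendered traces, or leave 0 for pre-aligned tables).
#'
#' @param config a [pipeline_config()].
#' @param sync_offset integer right-minus-left frame offset applied to
#'   every trial.
#' @param animal_of_trial function mapping a trial id to its animal id
#'   (default: strips a trailing `_j<k>` jump counter).
#' @return List of result tables: `kinematics`, `residuals`, `qc`, `anova`,
#'   `correlations`, and `raceway` (when raceway data were supplied); all
#'   also written as CSV under `config$out_dir`.
#' @export
run_pipeline <- function(config, sync_offset = 0L,
                         animal_of_trial = function(id) sub("_j\\d+$", "", id)) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(config$out_dir, "run_log.txt")
  cat("hoptrack ", as.character(utils::packageVersion("hoptrack")),
      "; seed ", config$seed, "; fps ", config$fps,
      "; qc_threshold ", config$qc_threshold,
      "; epsilon ", config$epsilon, "\n", file = log, sep = "")

  calib <- .stage(log, config, "calibrate", {
    views <- read_correspondences(config$correspondence_csv,
                                  config$square_size)
    calibrate_stereo(views, qc_threshold = config$qc_threshold)
  })
  write_pipeline_csv(calib$qc, file.path(config$out_dir, "qc_report.csv"),
                     "qc_report")
  n_rej <- sum(!calib$qc$accepted)
  cat("QC rejections: ", n_rej, "\n", file = log, append = TRUE, sep = "")

  landmarks <- .stage(log, config, "read-landmarks",
                      read_pipeline_csv(config$landmark_csv, "landmarks"))

  kin_rows <- .stage(log, config, "reconstruct-kinematics", {
    trials <- split(landmarks, landmarks$trial_id)
    rows <- lapply(names(trials), function(tid) {
      tryCatch({
        traj <- reconstruct_trajectory(trials[[tid]], calib$left,
                                       calib$right, sync_offset, config$fps)
        utils::write.csv(as.data.frame(traj),
                         file.path(config$out_dir,
                                   paste0("trajectory_", tid, ".csv")),
                         row.names = FALSE)
        al <- align_trajectory(traj)
        br <- detect_takeoff_landing(al, config$epsilon)
        as.data.frame(extract_kinematics(al, br$takeoff, br$landing,
                                         smooth = config$smooth,
                                         trial_id = tid,
                                         animal_id = animal_of_trial(tid)))
      }, error = function(e)
        stop("trial '", tid, "': ", conditionMessage(e), call. = FALSE))
    })
    do.call(rbind, rows)
  })

  kin <- .stage(log, config, "best-jump", {
    kin_rows$best <- FALSE
    for (aid in unique(kin_rows$animal_id)) {
      idx <- which(kin_rows$animal_id == aid)
      sub <- kin_rows[idx, ]
      b <- idx[order(-sub$distance, sub$trial_id)][1]
      kin_rows$best[b] <- TRUE
    }
    kin_rows
  })
  write_pipeline_csv(kin, file.path(config$out_dir, "kinematics.csv"),
                     "kinematics")

  morph <- .stage(log, config, "read-morphology",
                  read_pipeline_csv(config$morphology_csv, "morphology"))
  residuals <- .stage(log, config, "shape-residuals",
                      shape_residual_matrix(morph,
                                            grouping = config$residual_grouping))
  write_pipeline_csv(residuals, file.path(config$out_dir, "residuals.csv"),
                     "residuals")

  stats_tabs <- .stage(log, config, "statistics", {
    best <- kin[kin$best, ]
    dat <- merge(best, morph, by = "animal_id")
    resp <- c("distance", "height", "mean_velocity", "max_velocity",
              "angle_takeoff", "angle_landing")
    anova_tab <- do.call(rbind, lapply(resp, function(v) {
      a <- nested_anova(dat[[v]], dat$invasion_category, dat$population)
      data.frame(analysis = "nested_anova", response = v, term = a$term,
                 df_num = a$df_num, df_den = a$df_den, statistic = "F",
                 value = a$F, p = a$p)
    }))
    rdat <- merge(dat, residuals, by = "animal_id")
    cor_pairs <- list(c("mean_velocity", "distance"),
                      c("mean_velocity", "height"),
                      c("angle_takeoff", "height"))
    cor_tab <- do.call(rbind, lapply(cor_pairs, function(pr) {
      ct <- pearson_corr(rdat[[pr[1]]], rdat[[pr[2]]])
      data.frame(analysis = "pearson", response = pr[2], term = pr[1],
                 df_num = ct$n, df_den = NA, statistic = "r", value = ct$r,
                 p = ct$p)
    }))
    list(anova = anova_tab, correlations = cor_tab)
  })
  write_pipeline_csv(rbind(stats_tabs$anova, stats_tabs$correlations),
                     file.path(config$out_dir, "stats.csv"), "stats")

  raceway_tab <- NULL
  if (!is.null(config$raceway_csv)) {
    raceway_tab <- .stage(log, config, "raceway", {
      ev <- read_pipeline_csv(config$raceway_csv, "raceway")
      sums <- lapply(split(ev, ev$animal_id), function(e) {
        term <- nrow(e) >= 10 && all(utils::tail(e$event, 10) == "refusal")
        tr <- raceway_trial(e$animal_id[1],
                            e[, c("time", "event", "distance", "position")],
                            terminated_early = term)
        s <- summarize_raceway(tr)
        data.frame(animal_id = s$animal_id, n_hops = s$n_hops,
                   mean_hop_distance_m = s$mean_hop_distance_m,
                   mean_speed_m_s = s$mean_speed_m_s,
                   final_position_m = s$final_position_m,
                   finished = s$finished)
      })
      sums <- do.call(rbind, sums)
      best <- kin[kin$best, c("animal_id", "distance", "height")]
      names(best) <- c("animal_id", "jump_distance_cm", "jump_height_cm")
      joined <- merge(sums, best, by = "animal_id")
      corr <- if (nrow(joined) >= 3) jump_vs_raceway(joined) else NULL
      utils::write.csv(sums, file.path(config$out_dir,
                                       "raceway_summary.csv"),
                       row.names = FALSE)
      list(summary = sums, correlations = corr)
    })
  }

  cat("done\n", file = log, append = TRUE)
  list(kinematics = kin, residuals = residuals, qc = calib$qc,
       anova = stats_tabs$anova, correlations = stats_tabs$correlations,
       raceway = raceway_tab)
}
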