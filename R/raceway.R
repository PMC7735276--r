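#' Raceway trial record
#'
#' Event log of one forced-locomotion trial on a straight track: hop events
#' carry a timestamp, the hop displacement and the cumulative position;
#' refusal events (unanswered prods) carry only a timestamp. A trial ends
#' when the animal crosses the far end of the track or refuses 10
#' consecutive prods, in which case `terminated_early` is set.
#'
#' @param animal_id identifier.
#' @param events data.frame with columns `time` (s), `event`
#'   (`"hop"`/`"refusal"`), `distance` (m, 0 for refusals), `position`
#'   (cumulative, m).
#' @param terminated_early logical: ended by the 10-consecutive-refusal
#'   rule.
#' @param track_length,segment_length m; defaults 15 and 5.
#' @return An object of class `raceway_trial`.
#' @export
raceway_trial <- function(animal_id, events, terminated_early = FALSE,
                          track_length = 15, segment_length = 5) {
  need <- c("time", "event", "distance", "position")
  if (!all(need %in% names(events)))
    stop("events need columns: ", paste(need, collapse = ", "))
  if (is.unsorted(events$position))
    stop("data integrity error: positions must be non-decreasing")
  if (any(events$position < 0 | events$position > track_length + 1e-9))
    stop("positions must lie within [0, track_length]")
  structure(list(animal_id = animal_id, events = events,
                 terminated_early = isTRUE(terminated_early),
                 track_length = track_length,
                 segment_length = segment_length),
            class = "raceway_trial")
}

#' @export
print.raceway_trial <- function(x, ...) {
  nh <- sum(x$events$event == "hop")
  cat("<raceway_trial> ", x$animal_id, ": ", nh, " hops, final position ",
      round(max(c(0, x$events$position)), 2), " m",
      if (x$terminated_early) " (terminated early)", "\n", sep = "")
  invisible(x)
}

#' Simulate one raceway trial
#'
#' Hops accumulate position along the track until the far end is crossed or
#' 10 consecutive refusals terminate the trial. Each prod is refused with
#' probability `refusal_prob`; otherwise the animal hops a
#' Normal(`hop_distance_mean`, `hop_distance_sd`) displacement truncated to
#' be positive. Events are `hop_interval_s` apart.
#'
#' @param animal_id identifier.
#' @param hop_distance_mean,hop_distance_sd m; mean must be > 0.
#' @param hop_interval_s time between prods, s (> 0).
#' @param refusal_prob probability in [0, 1) ... 1 is allowed and yields an
#'   immediately terminated trial.
#' @param seed integer seed.
#' @param track_length,segment_length m.
#' @param max_refusals consecutive refusals that terminate the trial.
#' @return A [raceway_trial()].
#' @export
simulate_raceway_trial <- function(animal_id = "toad",
                                   hop_distance_mean = 0.6,
                                   hop_distance_sd = 0.1,
                                   hop_interval_s = 1, refusal_prob = 0.05,
                                   seed = NULL, track_length = 15,
                                   segment_length = 5, max_refusals = 10L) {
  stopifnot_scalar_number(hop_distance_mean, "hop_distance_mean",
                          positive = TRUE)
  if (hop_distance_sd < 0) stop("'hop_distance_sd' must be >= 0")
  stopifnot_scalar_number(hop_interval_s, "hop_interval_s", positive = TRUE)
  if (refusal_prob < 0 || refusal_prob > 1)
    stop("'refusal_prob' must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)
  time <- 0; pos <- 0; consec <- 0L
  rows <- list()
  terminated <- FALSE
  repeat {
    time <- time + hop_interval_s
    if (stats::runif(1) < refusal_prob) {
      consec <- consec + 1L
      rows[[length(rows) + 1L]] <-
        data.frame(time = time, event = "refusal", distance = 0,
                   position = pos)
      if (consec >= max_refusals) { terminated <- TRUE; break }
    } else {
      consec <- 0L
      d <- abs(stats::rnorm(1, hop_distance_mean, hop_distance_sd))
      d <- min(d, track_length - pos)   # last hop ends at the finish line
      pos <- pos + d
      rows[[length(rows) + 1L]] <-
        data.frame(time = time, event = "hop", distance = d, position = pos)
      if (pos >= track_length - 1e-9) break
    }
  }
  raceway_trial(animal_id, do.call(rbind, rows), terminated_early = terminated,
                track_length = track_length, segment_length = segment_length)
}

#' Summarize a raceway trial
#'
#' Per-segment statistics (time between first crossings of successive
#' segment boundaries, hops counted by landing position) and overall
#' statistics: mean distance per hop (final position / hop count), mean
#' speed (final position / elapsed time to the last event) and whether the
#' animal finished the track. A final segment the animal entered but did
#' not complete is reported with `completed = FALSE`. For non-finishers the
#' overall statistics cover the distance actually travelled.
#'
#' @param trial a [raceway_trial()].
#' @return A list of class `raceway_summary`: `segments` (data.frame
#'   `segment`, `time_s`, `hops`, `completed`), `n_hops`,
#'   `mean_hop_distance_m`, `mean_speed_m_s`, `final_position_m`,
#'   `finished`, `terminated_early`, `animal_id`.
#' @export
summarize_raceway <- function(trial) {
  stopifnot(inherits(trial, "raceway_trial"))
  ev <- trial$events
  if (is.unsorted(ev$position))
    stop("data integrity error: positions must be non-decreasing")
  hops <- ev[ev$event == "hop", ]
  if (nrow(hops) == 0L && !trial$terminated_early)
    stop("trial has no hop events and no termination flag")
  final_pos <- if (nrow(ev)) max(ev$position) else 0
  elapsed <- if (nrow(ev)) max(ev$time) else NA_real_
  n_seg_total <- ceiling(trial$track_length / trial$segment_length)
  segs <- list()
  prev_cross <- 0
  for (k in seq_len(n_seg_total)) {
    lo <- (k - 1) * trial$segment_length
    hi <- k * trial$segment_length
    if (final_pos <= lo + 1e-12) break
    in_seg <- hops$position > lo + 1e-12 & hops$position <= hi + 1e-12
    crossed <- final_pos >= hi - 1e-9
    t_cross <- if (crossed)
      min(hops$time[hops$position >= hi - 1e-9]) else max(ev$time)
    segs[[k]] <- data.frame(segment = k, time_s = t_cross - prev_cross,
                            hops = sum(in_seg), completed = crossed)
    prev_cross <- t_cross
    if (!crossed) break
  }
  structure(list(segments = if (length(segs)) do.call(rbind, segs)
                 else data.frame(segment = integer(0), time_s = numeric(0),
                                 hops = integer(0), completed = logical(0)),
                 n_hops = nrow(hops),
                 mean_hop_distance_m = if (nrow(hops)) final_pos / nrow(hops)
                 else NA_real_,
                 mean_speed_m_s = if (nrow(hops)) final_pos / elapsed
                 else NA_real_,
                 final_position_m = final_pos,
                 finished = final_pos >= trial$track_length - 1e-9,
                 terminated_early = trial$terminated_early,
                 animal_id = trial$animal_id),
            class = "raceway_summary")
}

#' @export
print.raceway_summary <- function(x, ...) {
  cat(sprintf(paste0("<raceway_summary> %s: %d hops, %.2f m, mean hop ",
                     "%.2f m, speed %.2f m/s%s\n"), x$animal_id, x$n_hops,
              x$final_position_m,
              if (is.na(x$mean_hop_distance_m)) 0 else x$mean_hop_distance_m,
              if (is.na(x$mean_speed_m_s)) 0 else x$mean_speed_m_s,
              if (x$finished) ", finished" else ""))
  invisible(x)
}

#' Correlate raceway and jumping performance
#'
#' Pearson correlations between mean raceway hop distance and (a) jump
#' distance and (b) jump height over the animals present in both datasets.
#'
#' @param joined data.frame with columns `mean_hop_distance_m`,
#'   `jump_distance_cm`, `jump_height_cm` (one row per animal).
#' @return List with `distance` and `height` [pearson_corr()] results.
#' @export
jump_vs_raceway <- function(joined) {
  need <- c("mean_hop_distance_m", "jump_distance_cm", "jump_height_cm")
  miss <- setdiff(need, names(joined))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  joined <- joined[stats::complete.cases(joined[, need]), ]
  if (nrow(joined) < 3L)
    stop("insufficient overlap: fewer than 3 animals in both datasets")
  list(distance = pearson_corr(joined$mean_hop_distance_m,
                               joined$jump_distance_cm),
       height = pearson_corr(joined$mean_hop_distance_m,
                             joined$jump_height_cm))
}
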