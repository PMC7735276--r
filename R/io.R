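# Tabular exchange formats. Every table is a plain UTF-8 CSV with decimal
# points, one logical table per file, and a schema stamp in a leading
# comment line ('#schema: <name> <version>').

.schemas <- list(
  landmarks = list(
    cols = c("trial_id", "camera", "frame", "landmark", "u", "v", "visible"),
    numeric = c("frame", "u", "v")),
  correspondences = list(
    cols = c("view_id", "corner_id", "x", "y", "z", "board_x", "board_y",
             "u_left", "v_left", "u_right", "v_right"),
    numeric = c("x", "y", "z", "board_x", "board_y", "u_left", "v_left",
                "u_right", "v_right")),
  trajectory = list(
    cols = c("t", "snout_x", "snout_y", "snout_z", "cloaca_x", "cloaca_y",
             "cloaca_z", "interpolated"),
    numeric = c("t", "snout_x", "snout_y", "snout_z", "cloaca_x",
                "cloaca_y", "cloaca_z")),
  kinematics = list(
    cols = c("animal_id", "trial_id", "mean_velocity", "max_velocity",
             "distance", "height", "angle_takeoff", "angle_landing", "best"),
    numeric = c("mean_velocity", "max_velocity", "distance", "height",
                "angle_takeoff", "angle_landing")),
  morphology = list(
    cols = c("animal_id", "population", "invasion_category", "class",
             "generation", "svl", "mass", "femur", "tibiofibula", "hindfoot",
             "forefoot", "head_width", "humerus", "radioulna"),
    numeric = c("svl", "mass", "femur", "tibiofibula", "hindfoot",
                "forefoot", "head_width", "humerus", "radioulna")),
  residuals = list(cols = c("animal_id"), numeric = character(0)),
  raceway = list(
    cols = c("animal_id", "time", "event", "distance", "position"),
    numeric = c("time", "distance", "position")),
  qc_report = list(
    cols = c("board_id", "inaccuracy", "threshold", "accepted", "reason"),
    numeric = c("inaccuracy", "threshold")),
  stats = list(
    cols = c("analysis", "response", "term", "df_num", "df_den",
             "statistic", "value", "p"),
    numeric = c("value", "p")))

#' Write a pipeline table
#'
#' Writes `x` as CSV with a `#schema:` stamp. The schema must be one of the
#' documented pipeline schemas and `x` must carry its required columns.
#'
#' @param x data.frame.
#' @param path output file.
#' @param schema schema name, one of `names(hoptrack_schemas())`.
#' @return `path`, invisibly.
#' @export
write_pipeline_csv <- function(x, path, schema) {
  sc <- .schemas[[schema]]
  if (is.null(sc)) stop("unknown schema '", schema, "'")
  miss <- setdiff(sc$cols, names(x))
  if (length(miss))
    stop("schema '", schema, "': missing column '", miss[1], "'")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("#schema: ", schema, " 1"), con)
  utils::write.csv(x, con, row.names = FALSE)
  invisible(path)
}

#' Read a pipeline table
#'
#' Reads a CSV written by [write_pipeline_csv()] (or assembled by hand with
#' the same header), validating that every required column of the schema is
#' present and that numeric columns parse as numbers with decimal points.
#' Files using locale-style decimal commas are rejected with an explicit
#' message.
#'
#' @param path CSV file.
#' @param schema schema name.
#' @return data.frame.
#' @export
read_pipeline_csv <- function(path, schema) {
  sc <- .schemas[[schema]]
  if (is.null(sc)) stop("unknown schema '", schema, "'")
  x <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE,
                       fileEncoding = "UTF-8")
  miss <- setdiff(sc$cols, names(x))
  if (length(miss))
    stop("schema '", schema, "': missing column '", miss[1], "' in ", path)
  for (cc in intersect(sc$numeric, names(x))) {
    if (is.character(x[[cc]])) {
      if (any(grepl(",", x[[cc]], fixed = TRUE)))
        stop("column '", cc, "' in ", path, " uses decimal commas; ",
             "tables must use decimal points")
      stop("column '", cc, "' in ", path, " is not numeric")
    }
  }
  x
}

#' Pipeline table schemas
#'
#' @return Named list describing the required and numeric columns of every
#'   CSV schema the pipeline reads and writes.
#' @export
hoptrack_schemas <- function() .schemas

#' Write a checkerboard correspondence table
#'
#' Serializes calibration views to the `correspondences` schema (world- and
#' board-frame corner coordinates plus both cameras' pixels).
#'
#' @param views list of [checkerboard_view()] objects.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_correspondences <- function(views, path) {
  tab <- do.call(rbind, lapply(views, function(v) {
    w <- corners_world(v)
    data.frame(view_id = v$board_id, corner_id = seq_len(nrow(w)),
               x = w[, 1], y = w[, 2], z = w[, 3],
               board_x = v$corners_3d[, 1], board_y = v$corners_3d[, 2],
               u_left = v$corners_px_left[, 1],
               v_left = v$corners_px_left[, 2],
               u_right = v$corners_px_right[, 1],
               v_right = v$corners_px_right[, 2])
  }))
  write_pipeline_csv(tab, path, "correspondences")
}

#' Read a correspondence table back into checkerboard views
#'
#' @param path CSV written by [write_correspondences()].
#' @param square_size board square size, cm (the table stores corner
#'   coordinates; the square size is needed to normalize QC discrepancies).
#' @return List of [checkerboard_view()] objects. World poses are not
#'   recoverable from the table and are returned as identity placeholders;
#'   world corner coordinates are attached as attribute `corners_world`.
#' @export
read_correspondences <- function(path, square_size = 2.5) {
  tab <- read_pipeline_csv(path, "correspondences")
  lapply(split(tab, tab$view_id), function(v) {
    v <- v[order(v$corner_id), ]
    bx <- sort(unique(round(v$board_x, 9)))
    by <- sort(unique(round(v$board_y, 9)))
    view <- checkerboard_view(
      board_id = v$view_id[1], square_size = square_size,
      rows = length(by), cols = length(bx),
      pose = list(R = diag(3), t = c(0, 0, 0)),
      corners_3d = cbind(v$board_x, v$board_y, 0),
      corners_px_left = cbind(v$u_left, v$v_left),
      corners_px_right = cbind(v$u_right, v$v_right))
    attr(view, "corners_world") <- cbind(v$x, v$y, v$z)
    view
  })
}
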