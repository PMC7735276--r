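#' Size-corrected shape residuals
#'
#' Regresses a linear trait on snout-vent length by ordinary least squares
#' within each fitting group and returns the residual score of every animal
#' as its size-corrected shape measure. Within each group the residuals sum
#' to zero and are uncorrelated with SVL by construction.
#'
#' @param records morphology data.frame with columns `animal_id`, `svl`,
#'   the trait column, and (depending on `grouping`) `generation` / `class`.
#' @param trait name of the trait column to correct (e.g. `"femur"`).
#' @param grouping fitting-group level: `"pooled"` (one regression),
#'   `"by-generation"` (default; separate F0/F1 fits) or `"by-class"`.
#' @return A data.frame (class `shape_residuals`) with `animal_id`, `group`,
#'   `residual`, and per-row `slope` and `intercept` of the group fit.
#' @examples
#' rec <- data.frame(animal_id = 1:10, generation = "F0",
#'                   svl = seq(90, 120, length.out = 10))
#' rec$femur <- 0.4 * rec$svl
#' shape_residuals(rec, "femur")$residual  # all ~0
#' @export
shape_residuals <- function(records, trait,
                            grouping = c("by-generation", "pooled",
                                         "by-class")) {
  grouping <- match.arg(grouping)
  if (!trait %in% names(records)) stop("no column '", trait, "' in records")
  if (!"svl" %in% names(records)) stop("records need an 'svl' column")
  group <- switch(grouping,
                  "pooled" = rep("all", nrow(records)),
                  "by-generation" = as.character(records$generation),
                  "by-class" = as.character(records$class))
  out <- lapply(split(seq_len(nrow(records)), group), function(idx) {
    g <- records[idx, ]
    if (nrow(g) < 3L)
      stop("degenerate fit: fewer than 3 records in group '",
           group[idx[1]], "'", call. = FALSE)
    if (stats::var(g$svl) <= 0)
      stop("degenerate fit: zero SVL variance in group '",
           group[idx[1]], "'", call. = FALSE)
    fit <- stats::lm(stats::reformulate("svl", trait), data = g)
    data.frame(animal_id = g$animal_id, group = group[idx[1]],
               residual = unname(stats::resid(fit)),
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               row = idx)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$row), ]
  out$row <- NULL
  rownames(out) <- NULL
  class(out) <- c("shape_residuals", class(out))
  out
}

#' Shape-residual matrix over several traits
#'
#' Convenience wrapper applying [shape_residuals()] to each trait and
#' returning the residual scores as columns.
#'
#' @param records morphology data.frame.
#' @param traits character vector of trait columns; defaults to the linear
#'   measures (mass excluded).
#' @param grouping passed to [shape_residuals()].
#' @return data.frame with `animal_id` and one `resid_<trait>` column per
#'   trait.
#' @export
shape_residual_matrix <- function(records,
                                  traits = c("femur", "tibiofibula",
                                             "hindfoot", "forefoot",
                                             "head_width", "humerus",
                                             "radioulna"),
                                  grouping = "by-generation") {
  out <- data.frame(animal_id = records$animal_id)
  for (tr in traits)
    out[[paste0("resid_", tr)]] <-
      shape_residuals(records, tr, grouping)$residual
  out
}
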