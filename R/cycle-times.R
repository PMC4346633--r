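#' Division-speed thresholds
#'
#' The published category boundaries for tracked division times: fast
#' (< 600 min), medium (600--800 min), slow (> 1000 min) and no division
#' (undivided for more than 30 h = 1800 min until the end of imaging). The
#' 800--1000 min gap those categories leave open is reported as an explicit
#' `INTERMEDIATE` category, never silently merged. `day_boundary` (24 h)
#' separates early from late dividers (first vs second imaging day).
#'
#' @param fast_max,medium_max,slow_min,no_division_min,day_boundary minutes.
#' @return object of class `speed_thresholds`.
#' @export
speed_thresholds <- function(fast_max = 600, medium_max = 800, slow_min = 1000,
                             no_division_min = 1800, day_boundary = 1440) {
  if (!(fast_max <= medium_max && medium_max <= slow_min && slow_min < no_division_min))
    ft_validation_error("require fast_max <= medium_max <= slow_min < no_division_min")
  structure(list(fast_max = fast_max, medium_max = medium_max,
                 slow_min = slow_min, no_division_min = no_division_min,
                 day_boundary = day_boundary),
            class = "speed_thresholds")
}

#' Classify a division (or undivided span) into a speed category
#'
#' For divided cells: `FAST` below `fast_max`, `MEDIUM` in
#' `[fast_max, medium_max]`, `INTERMEDIATE` in `(medium_max, slow_min]` (the
#' unnamed gap of the published categories), `SLOW` above `slow_min`. For
#' undivided cells the duration is the observed division-free span:
#' `NO_DIVISION` if it exceeds `no_division_min`, otherwise `UNCALLABLE`
#' (censored too early to call). Vectorised.
#'
#' @param duration minutes; cycle time for divided cells, observed
#'   division-free span for undivided ones.
#' @param thresholds a [speed_thresholds()] object.
#' @param divided logical (recycled): was the span terminated by a division?
#' @return character vector over
#'   `{FAST, MEDIUM, INTERMEDIATE, SLOW, NO_DIVISION, UNCALLABLE}`.
#' @examples
#' classify_division_speed(c(550, 700, 900, 1200), speed_thresholds())
#' @export
classify_division_speed <- function(duration, thresholds = speed_thresholds(),
                                    divided = TRUE) {
  if (any(!is.finite(duration)) || any(duration < 0))
    ft_domain_error("durations must be finite and nonnegative")
  divided <- rep_len(divided, length(duration))
  out <- character(length(duration))
  th <- thresholds
  out[divided & duration < th$fast_max] <- "FAST"
  out[divided & duration >= th$fast_max & duration <= th$medium_max] <- "MEDIUM"
  out[divided & duration > th$medium_max & duration <= th$slow_min] <- "INTERMEDIATE"
  out[divided & duration > th$slow_min] <- "SLOW"
  out[!divided & duration > th$no_division_min] <- "NO_DIVISION"
  out[!divided & duration <= th$no_division_min] <- "UNCALLABLE"
  out
}

#' Extract per-cell cycle times from a tree
#'
#' The founder's cycle start was never observed (tracking begins at its first
#' cytokinesis), so with `complete_only = TRUE` (the default, and the
#' measurement rule of the source protocol) the founder is dropped and only
#' cells with fully observed cycles (fate `DIVIDED`) are returned.
#'
#' @param tree a `lineage_tree`.
#' @param complete_only drop the founder and all non-divided cells.
#' @return data.frame (`cell_id`, `depth`, `generation_abs`, `cycle_time`)
#'   where `generation_abs = generation_offset + depth`.
#' @export
extract_cycle_times <- function(tree, complete_only = TRUE) {
  n <- tree$nodes
  keep <- if (complete_only) n$fate == "DIVIDED" & n$depth > 0 else rep(TRUE, nrow(n))
  out <- data.frame(
    cell_id = n$cell_id[keep],
    depth = n$depth[keep],
    generation_abs = n$generation_offset[keep] + n$depth[keep],
    cycle_time = ifelse(n$fate[keep] == "DIVIDED",
                        n$end_time[keep] - n$birth_time[keep], NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Classify a founder as an early or late divider
#'
#' Early dividers complete their first cytokinesis on the first imaging day,
#' late dividers on the second; founders that do not divide within two days
#' (or at all) get `NONE`.
#'
#' @param tree a `lineage_tree` whose founder was present at imaging start.
#' @param thresholds a [speed_thresholds()]; `day_boundary` sets the day length.
#' @return `"EARLY"`, `"LATE"` or `"NONE"`.
#' @export
early_late_divider <- function(tree, thresholds = speed_thresholds()) {
  root <- tree$nodes[is.na(tree$nodes$parent_id), ]
  if (root$fate != "DIVIDED") return("NONE")
  t1 <- root$end_time
  if (t1 < thresholds$day_boundary) "EARLY"
  else if (t1 < 2 * thresholds$day_boundary) "LATE"
  else "NONE"
}
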