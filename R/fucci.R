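#' Fucci gating thresholds for fluorescence traces
#'
#' The dual Fucci reporter marks G0/G1 by mKO2-hCdt1 and S/G2/M by
#' mAG-hGeminin; quiescent (G0) cells sit at a distinctly higher mKO2 level
#' (mKO2++) than cycling G1 cells. Thresholds are inclusive and expressed in
#' the arbitrary units of the trace; defaults are 20% of the generator's
#' cycling plateau (1000 a.u.) for positivity and 2000 a.u. for the quiescent
#' mKO2++ level.
#'
#' @param theta_ko mKO2 positivity threshold (a.u.).
#' @param theta_ko_high mKO2++ quiescent threshold (a.u.), `> theta_ko`.
#' @param theta_ag mAG positivity threshold (a.u.).
#' @param min_dwell minutes; runs shorter than this are smoothed away
#'   (about 3--4 frames at 3--4 min per frame).
#' @return object of class `fucci_gate`.
#' @export
fucci_gate <- function(theta_ko = 200, theta_ko_high = 2000,
                       theta_ag = 200, min_dwell = 12) {
  if (!(theta_ko > 0 && theta_ko < theta_ko_high))
    ft_validation_error("require 0 < theta_ko < theta_ko_high")
  if (theta_ag <= 0) ft_validation_error("theta_ag must be positive")
  if (min_dwell < 0) ft_validation_error("min_dwell must be nonnegative")
  structure(list(theta_ko = theta_ko, theta_ko_high = theta_ko_high,
                 theta_ag = theta_ag, min_dwell = min_dwell),
            class = "fucci_gate")
}

#' Classify a single (mKO2, mAG) intensity pair into a Fucci state
#'
#' States: `KO_HIGH` (quiescent G0, mKO2++ mAG-), `KO_POS` (cycling G1),
#' `DOUBLE_POS` (G1/S transition), `AG_POS` (S/G2/M), `DN` (double negative,
#' the early-G1 gap between mAG degradation and mKO2 accumulation).
#' Thresholds are inclusive, so a point exactly at both thresholds is
#' `DOUBLE_POS`. Vectorised.
#'
#' @param ko2,ag nonnegative intensities (a.u.).
#' @param gate a [fucci_gate()].
#' @return character vector of states.
#' @export
classify_point <- function(ko2, ag, gate = fucci_gate()) {
  if (any(ko2 < 0) || any(ag < 0)) ft_domain_error("intensities must be nonnegative")
  ag_pos <- ag >= gate$theta_ag
  ko_pos <- ko2 >= gate$theta_ko
  out <- rep("DN", length(ko2))
  out[ko_pos & ag_pos] <- "DOUBLE_POS"
  out[!ko_pos & ag_pos] <- "AG_POS"
  out[ko_pos & !ag_pos & ko2 >= gate$theta_ko_high] <- "KO_HIGH"
  out[ko_pos & !ag_pos & ko2 < gate$theta_ko_high] <- "KO_POS"
  out
}

#' Segment a fluorescence trace into Fucci-state intervals
#'
#' Classifies every frame, then smooths by minimum dwell: runs shorter than
#' `min_dwell` are merged (shortest first, ties to the earlier run) into the
#' flanking run with the longer duration (ties to the earlier flank), so
#' single-frame flicker never survives. The resulting intervals tile
#' `[t_1, t_n]` exactly. Frame `j` covers `[t_j, t_{j+1})`.
#'
#' @param trace list or data.frame with `times` (strictly increasing, min),
#'   `ko2`, `ag` (equal-length intensity vectors, a.u.).
#' @param gate a [fucci_gate()].
#' @return object of class `phase_segmentation`: list with `intervals`
#'   (data.frame `start_min`, `end_min`, `state`) and `durations`, a named
#'   vector of total minutes per state (`d_DN`, `d_KO`, `d_KO_HIGH`, `d_DP`,
#'   `d_AG`).
#' @export
segment_trace <- function(trace, gate = fucci_gate()) {
  times <- trace$times %||% trace$time_min
  ko2 <- trace$ko2 %||% trace$ko2_au
  ag <- trace$ag %||% trace$ag_au
  if (length(times) < 3)
    ft_error("trace has fewer than 3 frames", "ft_insufficient_data_error")
  if (length(ko2) != length(times) || length(ag) != length(times))
    ft_schema_error("trace channels must have the same length as times")
  if (any(diff(times) <= 0)) ft_schema_error("trace times must be strictly increasing")

  states <- classify_point(ko2, ag, gate)
  # per-frame coverage: frame j covers [t_j, t_{j+1}); the last frame is a point
  bounds <- c(times, times[length(times)])

  # run-length representation: (state, start index, end index); duration from bounds
  r <- rle(states)
  run_state <- r$values
  run_end <- cumsum(r$lengths)
  run_start <- c(1, head(run_end, -1) + 1)
  run_dur <- function() bounds[run_end + 1] - bounds[run_start]

  # merge short runs, shortest first (ties -> earliest), into the longer flank
  repeat {
    if (length(run_state) <= 1) break
    d <- run_dur()
    short <- which(d < gate$min_dwell)
    if (length(short) == 0) break
    i <- short[order(d[short], short)][1]
    left <- if (i > 1) d[i - 1] else -Inf
    right <- if (i < length(run_state)) d[i + 1] else -Inf
    target <- if (left >= right) i - 1 else i + 1
    # absorb run i into target, then collapse equal neighbours
    if (target < i) run_start[i] <- run_start[target] else run_end[i] <- run_end[target]
    run_state[i] <- run_state[target]
    keep <- setdiff(seq_along(run_state), target)
    run_state <- run_state[keep]; run_start <- run_start[keep]; run_end <- run_end[keep]
    while (length(run_state) > 1 && any(head(run_state, -1) == tail(run_state, -1))) {
      j <- which(head(run_state, -1) == tail(run_state, -1))[1]
      run_end[j] <- run_end[j + 1]
      keep <- setdiff(seq_along(run_state), j + 1)
      run_state <- run_state[keep]; run_start <- run_start[keep]; run_end <- run_end[keep]
    }
  }

  intervals <- data.frame(
    start_min = bounds[run_start],
    end_min = bounds[run_end + 1],
    state = run_state,
    stringsAsFactors = FALSE
  )
  dur <- c(d_DN = 0, d_KO = 0, d_KO_HIGH = 0, d_DP = 0, d_AG = 0)
  key <- c(DN = "d_DN", KO_POS = "d_KO", KO_HIGH = "d_KO_HIGH",
           DOUBLE_POS = "d_DP", AG_POS = "d_AG")
  for (i in seq_len(nrow(intervals)))
    dur[key[[intervals$state[i]]]] <- dur[key[[intervals$state[i]]]] +
      intervals$end_min[i] - intervals$start_min[i]

  structure(list(intervals = intervals, durations = dur,
                 span = c(times[1], times[length(times)])),
            class = "phase_segmentation")
}

#' @export
print.phase_segmentation <- function(x, ...) {
  cat(sprintf("<phase_segmentation> %d intervals over [%.0f, %.0f] min\n",
              nrow(x$intervals), x$span[1], x$span[2]))
  print(round(x$durations, 1))
  invisible(x)
}

#' Per-cell Fucci phase durations over a tree
#'
#' Segments each cell's trace and returns the per-cycle phase durations;
#' `d_KO` counts cycling `KO_POS` time only (`KO_HIGH` quiescence and the
#' `DOUBLE_POS` transition are reported separately). Each trace must cover its
#' cell's `[birth_time, end_time]` to within `align_tolerance`.
#'
#' @param tree a `lineage_tree`.
#' @param traces named list of traces (names = `cell_id`), each a list with
#'   `times`, `ko2`, `ag` as for [segment_trace()]. Cells without a trace are
#'   skipped.
#' @param gate a [fucci_gate()].
#' @param align_tolerance minutes; maximum allowed mismatch between trace span
#'   and the cell's recorded cycle (default one frame, 4 min).
#' @return data.frame: `cell_id`, `cycle_time`, `d_DN`, `d_KO`, `d_KO_HIGH`,
#'   `d_DP`, `d_AG`.
#' @export
mko2_phase_duration <- function(tree, traces, gate = fucci_gate(),
                                align_tolerance = 4) {
  n <- tree$nodes
  out <- list()
  for (i in seq_len(nrow(n))) {
    tr <- traces[[n$cell_id[i]]]
    if (is.null(tr)) next
    times <- tr$times %||% tr$time_min
    if (abs(times[1] - n$birth_time[i]) > align_tolerance ||
        abs(times[length(times)] - n$end_time[i]) > align_tolerance)
      ft_error(sprintf("trace for cell %s does not span its cycle", n$cell_id[i]),
               "ft_alignment_error")
    seg <- segment_trace(tr, gate)
    out[[length(out) + 1]] <- data.frame(
      cell_id = n$cell_id[i],
      cycle_time = n$end_time[i] - n$birth_time[i],
      as.list(seg$durations),
      stringsAsFactors = FALSE
    )
  }
  if (length(out) == 0)
    return(data.frame(cell_id = character(0), cycle_time = numeric(0),
                      d_DN = numeric(0), d_KO = numeric(0), d_KO_HIGH = numeric(0),
                      d_DP = numeric(0), d_AG = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
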