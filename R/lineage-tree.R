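#' Build a validated division tree from track records
#'
#' Turns a table of per-cell track records (one row per tracked cell, with a
#' parent link) into a validated `lineage_tree`: a rooted binary division tree
#' with depths, cycle times and the canonical kinship labels of a tracked
#' microgrid well (founder `C1`, first-division cells `M1`/`M2`, second-division
#' cells `D1`--`D4`, anything deeper `DEEPER`).
#'
#' Kinship labels are assigned by birth order within each division: the
#' earlier-listed child of a division gets the lower index, so the daughters of
#' `M1` are `D1`/`D2` and the daughters of `M2` are `D3`/`D4`.
#'
#' @param records data.frame with columns `tree_id`, `well_id`, `cell_id`,
#'   `parent_id` (`NA` or `""` for the root), `birth_time_min`, `end_time_min`,
#'   `fate` (one of `DIVIDED`, `DIED`, `CENSORED`) and `generation_offset`
#'   (sorted generation of the founder, e.g. 1, 3 or 8). Optional columns
#'   `size_class`, `cd62l_class`, `latent_state` are carried through.
#'   All rows must belong to one tree.
#' @param imaging_end end of the imaging window in minutes; defaults to the
#'   largest `end_time_min` in the records.
#' @param frame_tolerance tolerance, in minutes, for the requirement that a
#'   child's birth time equal its parent's end time (one sampling interval;
#'   frames were 3--4 min apart).
#'
#' @return An object of class `lineage_tree`: a list with `tree_id`, `well_id`,
#'   `imaging_end`, `qc_status` (`"INCLUDED"` until [qc_filter()] says
#'   otherwise), `qc_reason`, and `nodes`, a data.frame with one row per cell
#'   (`cell_id`, `parent_id`, `depth`, `birth_time`, `end_time`, `fate`,
#'   `cycle_time` -- populated only for `DIVIDED` cells -- `kinship_label`,
#'   `generation_offset`, `size_class`, `cd62l_class`, `latent_state`).
#'
#' @examples
#' rec <- quartet_records()
#' tr <- build_tree(rec)
#' tr$nodes[, c("cell_id", "depth", "kinship_label", "fate")]
#' @seealso [build_trees()] for a multi-tree table, [quartet_records()] for the
#'   canonical 7-cell example.
#' @export
build_tree <- function(records, imaging_end = NULL, frame_tolerance = 4) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  required <- c("tree_id", "well_id", "cell_id", "parent_id",
                "birth_time_min", "end_time_min", "fate", "generation_offset")
  missing_cols <- setdiff(required, names(records))
  if (length(missing_cols) > 0)
    ft_schema_error(paste0("track records are missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  if (nrow(records) == 0) ft_structural_error("no track records supplied")
  if (length(unique(records$tree_id)) != 1)
    ft_usage_error("build_tree() expects records for a single tree_id; use build_trees()")

  pid <- as.character(records$parent_id)
  pid[is.na(pid) | pid == ""] <- NA_character_
  cid <- as.character(records$cell_id)
  if (anyDuplicated(cid))
    ft_structural_error("duplicate cell_id in track records")
  if (any(!is.finite(records$birth_time_min)) || any(!is.finite(records$end_time_min)))
    ft_parse_error("non-numeric or missing birth/end time in track records")
  if (any(records$birth_time_min < 0))
    ft_timing_error("negative birth_time_min in track records")
  if (any(records$end_time_min < records$birth_time_min))
    ft_timing_error("end_time_min earlier than birth_time_min")
  if (!all(records$fate %in% c("DIVIDED", "DIED", "CENSORED")))
    ft_schema_error("fate must be one of DIVIDED, DIED, CENSORED")

  is_root <- is.na(pid)
  if (sum(is_root) != 1)
    ft_structural_error(sprintf("tree %s must have exactly one root, found %d",
                                records$tree_id[1], sum(is_root)))

  # parent resolution, within the same well
  nonroot <- which(!is_root)
  midx <- match(pid[nonroot], cid)
  if (anyNA(midx)) {
    bad <- cid[nonroot][is.na(midx)][1]
    ft_structural_error(sprintf("record %s has parent_id not found in its well", bad))
  }
  if (any(records$well_id[nonroot] != records$well_id[midx])) {
    bad <- cid[nonroot][records$well_id[nonroot] != records$well_id[midx]][1]
    ft_structural_error(sprintf("record %s links to a parent in a different well", bad))
  }

  # children per node, in record (birth) order
  children <- split(seq_len(nrow(records))[!is_root], pid[nonroot])
  n_children <- vapply(cid, function(id) length(children[[id]] %||% integer(0)), 0L)
  div <- records$fate == "DIVIDED"
  if (any(div & n_children != 2)) {
    bad <- cid[div & n_children != 2][1]
    ft_structural_error(sprintf("cell %s is marked DIVIDED but has %d child(ren), expected 2",
                                bad, n_children[[bad]]))
  }
  if (any(!div & n_children != 0)) {
    bad <- cid[!div & n_children != 0][1]
    ft_structural_error(sprintf("cell %s is %s but has children",
                                bad, records$fate[cid == bad]))
  }

  # child birth time tied to parent's end time within one frame
  dt <- abs(records$birth_time_min[nonroot] - records$end_time_min[midx])
  if (any(dt > frame_tolerance)) {
    bad <- cid[nonroot][dt > frame_tolerance][1]
    ft_timing_error(sprintf(
      "cell %s is born %.1f min away from its parent's division (tolerance %g min)",
      bad, max(dt), frame_tolerance))
  }

  # depths by traversal from the root (also proves connectivity/acyclicity)
  depth <- rep(NA_integer_, nrow(records))
  root <- which(is_root)
  depth[root] <- 0L
  frontier <- root
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (i in frontier) {
      kids <- children[[cid[i]]] %||% integer(0)
      depth[kids] <- depth[i] + 1L
      nxt <- c(nxt, kids)
    }
    frontier <- nxt
  }
  if (anyNA(depth))
    ft_structural_error("track records contain cells not reachable from the root")

  label <- rep("DEEPER", nrow(records))
  label[root] <- "C1"
  d1 <- which(depth == 1L)
  d1 <- d1[order(match(d1, seq_len(nrow(records))))]
  if (length(d1) > 0) label[d1] <- paste0("M", seq_along(d1))
  for (m in seq_along(d1)) {
    kids <- children[[cid[d1[m]]]] %||% integer(0)
    if (length(kids) > 0) label[kids] <- paste0("D", (m - 1L) * 2L + seq_along(kids))
  }

  opt <- function(col) if (col %in% names(records)) as.character(records[[col]]) else NA_character_
  nodes <- data.frame(
    cell_id = cid,
    parent_id = pid,
    depth = depth,
    birth_time = as.numeric(records$birth_time_min),
    end_time = as.numeric(records$end_time_min),
    fate = as.character(records$fate),
    cycle_time = ifelse(div, records$end_time_min - records$birth_time_min, NA_real_),
    kinship_label = label,
    generation_offset = as.integer(records$generation_offset),
    size_class = opt("size_class"),
    cd62l_class = opt("cd62l_class"),
    latent_state = opt("latent_state"),
    stringsAsFactors = FALSE
  )
  nodes <- nodes[order(nodes$depth, nodes$birth_time, nodes$cell_id), ]
  rownames(nodes) <- NULL

  structure(list(
    tree_id = as.character(records$tree_id[1]),
    well_id = as.character(records$well_id[1]),
    imaging_end = imaging_end %||% max(nodes$end_time),
    qc_status = "INCLUDED",
    qc_reason = NA_character_,
    nodes = nodes
  ), class = "lineage_tree")
}

#' Build every tree in a multi-tree track table
#'
#' @param records track records as for [build_tree()], possibly spanning many
#'   `tree_id`s.
#' @param imaging_end,frame_tolerance passed to [build_tree()].
#' @return list of `lineage_tree`, in order of first appearance of each
#'   `tree_id`.
#' @export
build_trees <- function(records, imaging_end = NULL, frame_tolerance = 4) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  if (!"tree_id" %in% names(records))
    ft_schema_error("track records are missing column(s): tree_id")
  ids <- unique(as.character(records$tree_id))
  lapply(ids, function(id)
    build_tree(records[records$tree_id == id, , drop = FALSE],
               imaging_end = imaging_end, frame_tolerance = frame_tolerance))
}

#' @export
print.lineage_tree <- function(x, ...) {
  n_div <- sum(x$nodes$fate == "DIVIDED")
  cat(sprintf("<lineage_tree %s> well %s: %d cells (%d divided), depth %d, %s\n",
              x$tree_id, x$well_id, nrow(x$nodes), n_div,
              max(x$nodes$depth), x$qc_status))
  invisible(x)
}

#' Canonical 7-cell quartet track table
#'
#' The canonical tracked family: founder `C1` divides into mothers `M1`/`M2`,
#' each of which divides into a daughter pair; daughters are censored (or, with
#' `daughters_divide = TRUE`, divide again into censored grandchildren, so that
#' all six non-founder cycles are completely observed).
#'
#' @param daughters_divide should `D1`--`D4` divide (adding 8 censored
#'   grandchildren)?
#' @param tree_id,well_id identifiers for the emitted records.
#' @return data.frame in the track-record schema of [build_tree()].
#' @export
quartet_records <- function(daughters_divide = FALSE, tree_id = "T1", well_id = "W1") {
  rec <- data.frame(
    tree_id = tree_id, well_id = well_id,
    cell_id = c("c1", "m1", "m2", "d1", "d2", "d3", "d4"),
    parent_id = c(NA, "c1", "c1", "m1", "m1", "m2", "m2"),
    birth_time_min = c(0, 700, 700, 1450, 1450, 1500, 1500),
    end_time_min = c(700, 1450, 1500, 2200, 2250, 2300, 2180),
    fate = c("DIVIDED", "DIVIDED", "DIVIDED", rep("CENSORED", 4)),
    generation_offset = 1L,
    stringsAsFactors = FALSE
  )
  if (daughters_divide) {
    rec$fate[4:7] <- "DIVIDED"
    kids <- data.frame(
      tree_id = tree_id, well_id = well_id,
      cell_id = paste0("g", 1:8),
      parent_id = rep(c("d1", "d2", "d3", "d4"), each = 2),
      birth_time_min = rep(rec$end_time_min[4:7], each = 2),
      end_time_min = 3000,
      fate = "CENSORED",
      generation_offset = 1L,
      stringsAsFactors = FALSE
    )
    rec <- rbind(rec, kids)
  }
  rec
}
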