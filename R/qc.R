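#' Per-well quality-control filter for tracked trees
#'
#' Reproduces the exclusion rules of manual microgrid tracking: a well is
#' dropped wholesale if a tracked cell died during imaging, if the well held
#' more than one cell at the start of imaging, or if a foreign cell entered the
#' well (seen in track tables as an extra root born after time zero). Exclusion
#' is per well: every tree sharing an excluded well is excluded.
#'
#' @param trees list of `lineage_tree` objects (see [build_tree()]).
#' @param rules character vector of active rules, any of
#'   `"death_during_imaging"`, `"multiple_initial_cells"`,
#'   `"foreign_cell_entered"`. Default: all three.
#' @param start_tolerance minutes: roots born at or before this time count as
#'   initial cells; later roots count as intruders.
#'
#' @return list with `included` (trees, untouched), `excluded` (trees with
#'   `qc_status = "EXCLUDED"` and the rule in `qc_reason`) and `log`, a
#'   data.frame (`tree_id`, `well_id`, `rule`, `detail`) with one row per
#'   exclusion.
#' @export
qc_filter <- function(trees,
                      rules = c("death_during_imaging",
                                "multiple_initial_cells",
                                "foreign_cell_entered"),
                      start_tolerance = 4) {
  rules <- match.arg(rules, several.ok = TRUE,
                     choices = c("death_during_imaging",
                                 "multiple_initial_cells",
                                 "foreign_cell_entered"))
  wells <- vapply(trees, function(t) t$well_id, "")
  root_birth <- vapply(trees, function(t) min(t$nodes$birth_time[is.na(t$nodes$parent_id)]), 0)

  log_rows <- list()
  excluded_wells <- character(0)
  mark_well <- function(well, rule, detail) {
    for (i in which(wells == well)) {
      log_rows[[length(log_rows) + 1]] <<- data.frame(
        tree_id = trees[[i]]$tree_id, well_id = well,
        rule = rule, detail = detail, stringsAsFactors = FALSE)
    }
    excluded_wells <<- union(excluded_wells, well)
  }

  if ("death_during_imaging" %in% rules) {
    for (i in seq_along(trees)) {
      if (any(trees[[i]]$nodes$fate == "DIED"))
        mark_well(wells[i], "death_during_imaging", "death during imaging")
    }
  }
  if ("multiple_initial_cells" %in% rules) {
    for (w in unique(wells)) {
      n0 <- sum(wells == w & root_birth <= start_tolerance)
      if (n0 > 1)
        mark_well(w, "multiple_initial_cells",
                  sprintf("%d cells present at start of imaging", n0))
    }
  }
  if ("foreign_cell_entered" %in% rules) {
    for (i in seq_along(trees)) {
      if (root_birth[i] > start_tolerance)
        mark_well(wells[i], "foreign_cell_entered",
                  sprintf("untracked cell appeared at %.0f min", root_birth[i]))
    }
  }

  out_inc <- list(); out_exc <- list()
  for (i in seq_along(trees)) {
    t <- trees[[i]]
    if (wells[i] %in% excluded_wells) {
      t$qc_status <- "EXCLUDED"
      rl <- unique(unlist(lapply(log_rows, function(r)
        if (r$tree_id == t$tree_id) r$rule else NULL)))
      t$qc_reason <- paste(rl, collapse = ";")
      out_exc[[length(out_exc) + 1]] <- t
    } else {
      out_inc[[length(out_inc) + 1]] <- t
    }
  }
  log <- if (length(log_rows) > 0) {
    lg <- do.call(rbind, log_rows)
    lg[!duplicated(lg[, c("tree_id", "rule")]), , drop = FALSE]
  } else {
    data.frame(tree_id = character(0), well_id = character(0),
               rule = character(0), detail = character(0),
               stringsAsFactors = FALSE)
  }
  rownames(log) <- NULL
  list(included = out_inc, excluded = out_exc, log = log)
}
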