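track_columns <- c("tree_id", "well_id", "cell_id", "parent_id",
                   "birth_time_min", "end_time_min", "fate", "generation_offset")
track_optional <- c("size_class", "cd62l_class", "latent_state")

#' Read a track CSV
#'
#' Comma-separated, UTF-8, header mandatory; one row per tracked cell with
#' columns `tree_id`, `well_id`, `cell_id`, `parent_id` (empty for the root),
#' `birth_time_min`, `end_time_min`, `fate`, `generation_offset` and the
#' optional `size_class` / `cd62l_class` / `latent_state`. Times are minutes
#' from imaging start (fractional allowed).
#'
#' @param path CSV path.
#' @return data.frame of track records (canonical column order).
#' @export
read_tracks <- function(path) {
  if (!file.exists(path)) ft_usage_error(sprintf("track file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(track_columns, names(df))
  if (length(missing_cols) > 0)
    ft_schema_error(paste0("track CSV is missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  for (col in c("birth_time_min", "end_time_min")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      row <- which(is.na(v))[1]
      ft_parse_error(sprintf("non-numeric %s in row %d of %s", col, row, path))
    }
    df[[col]] <- v
  }
  df$generation_offset <- as.integer(df$generation_offset)
  df$parent_id[df$parent_id == ""] <- NA_character_
  keep <- c(track_columns, intersect(track_optional, names(df)))
  df[, keep, drop = FALSE]
}

#' Write trees (or raw records) as a track CSV
#'
#' Canonical column order; round-trip stable (write-read-write is
#' byte-identical).
#'
#' @param trees list of `lineage_tree` objects, or a track record data.frame.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracks <- function(trees, path) {
  df <- if (is.data.frame(trees)) trees else do.call(rbind, lapply(trees, function(t) {
    n <- t$nodes
    data.frame(tree_id = t$tree_id, well_id = t$well_id, cell_id = n$cell_id,
               parent_id = n$parent_id, birth_time_min = n$birth_time,
               end_time_min = n$end_time, fate = n$fate,
               generation_offset = n$generation_offset,
               size_class = n$size_class, cd62l_class = n$cd62l_class,
               latent_state = n$latent_state, stringsAsFactors = FALSE)
  }))
  keep <- c(track_columns, intersect(track_optional, names(df)))
  df <- df[, keep, drop = FALSE]
  df$parent_id[is.na(df$parent_id)] <- ""
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read fluorescence traces from a long-format CSV
#'
#' Columns `cell_id`, `time_min`, `ko2_au`, `ag_au`.
#'
#' @param path CSV path.
#' @return named list of traces (`times`, `ko2`, `ag`), one per cell.
#' @export
read_traces <- function(path) {
  if (!file.exists(path)) ft_usage_error(sprintf("trace file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cell_id", "time_min", "ko2_au", "ag_au")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0)
    ft_schema_error(paste0("trace CSV is missing column(s): ",
                           paste(missing_cols, collapse = ", ")))
  lapply(split(df, df$cell_id), function(d) {
    d <- d[order(d$time_min), ]
    list(cell_id = d$cell_id[1], times = d$time_min, ko2 = d$ko2_au, ag = d$ag_au)
  })
}

#' Write fluorescence traces to a long-format CSV
#'
#' @param traces named list of traces as produced by [simulate_trees()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr)
    data.frame(cell_id = tr$cell_id, time_min = tr$times,
               ko2_au = round(tr$ko2, 3), ag_au = round(tr$ag, 3),
               stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write phase segmentations to CSV
#'
#' @param segmentations named list of `phase_segmentation` (names = cell ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_segmentations <- function(segmentations, path) {
  df <- do.call(rbind, lapply(names(segmentations), function(id) {
    iv <- segmentations[[id]]$intervals
    data.frame(cell_id = id, start_min = iv$start_min, end_min = iv$end_min,
               state = iv$state, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Run the full kinship analysis on a set of trees
#'
#' QC-filters the trees, then computes every statistical block of the
#' pipeline: per-generation cycle-time summaries, Spearman correlations for
#' each kinship relation, a permutation null for the mother-daughter set,
#' category fractions and the inheritance table.
#'
#' @param trees list of `lineage_tree` objects.
#' @param thresholds a [speed_thresholds()].
#' @param n_perm permutations for the null.
#' @param seed RNG seed (permutation + inheritance dedupe).
#' @return list of result blocks (see the `results` JSON written by the CLI).
#' @export
analyze_trees <- function(trees, thresholds = speed_thresholds(),
                          n_perm = 999, seed = 1) {
  qc <- qc_filter(trees)
  inc <- qc$included

  cyc <- do.call(rbind, lapply(inc, extract_cycle_times))
  summaries <- list()
  if (!is.null(cyc) && nrow(cyc) > 0) {
    for (g in sort(unique(cyc$generation_abs))) {
      s <- summarize_cycle_times(cyc$cycle_time[cyc$generation_abs == g], unit = "h")
      summaries[[as.character(g)]] <- list(mu = s$mu, sigma = s$sigma, n = s$n,
                                           unit = s$unit)
    }
  }

  correlations <- list()
  md_pairs <- NULL
  for (rel in c("SIBLING", "MOTHER_DAUGHTER", "COUSIN", "NON_RELATIVE")) {
    ps <- kinship_pairs(inc, rel)
    if (rel == "MOTHER_DAUGHTER") md_pairs <- ps
    correlations[[rel]] <- if (ps$n_pairs >= 3) {
      cr <- spearman_cor(ps)
      list(rho = cr$rho, p_value = cr$p_value, n = cr$n)
    } else list(rho = NA, p_value = NA, n = ps$n_pairs)
  }

  permutation <- if (!is.null(md_pairs) && md_pairs$n_pairs >= 3) {
    pr <- permutation_null(md_pairs, n_perm = n_perm, seed = seed)
    list(observed_rho = pr$observed_rho, empirical_p = pr$empirical_p,
         n_perm = pr$n_perm, seed = seed)
  } else list(observed_rho = NA, empirical_p = NA, n_perm = n_perm, seed = seed)

  fractions <- category_fractions(inc, thresholds)
  inheritance <- tryCatch({
    it <- inheritance_table(inc, thresholds, seed = seed)
    list(chi2 = it$chi2, df = it$df, p_value = it$p_value,
         n_dyads = it$n_dyads, n_tested = it$n_tested,
         low_expected = it$low_expected, dedupe = it$dedupe,
         counts = as.data.frame.matrix(unclass(it$counts)))
  }, ft_degenerate_error = function(e) list(error = conditionMessage(e)))

  list(
    summary = summaries,
    correlations = correlations,
    permutation = permutation,
    category_fractions = fractions,
    inheritance = inheritance,
    qc = list(n_included = length(inc), n_excluded = length(qc$excluded),
              log = qc$log),
    thresholds = unclass(thresholds),
    version = as.character(utils::packageVersion("fuccitrack"))
  )
}

#' Write analysis results as JSON
#'
#' @param results output of [analyze_trees()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE, na = "null")
  invisible(path)
}

# deterministic md5 of the resolved config
config_hash <- function(cfg) {
  tmp <- tempfile(fileext = ".toml")
  on.exit(unlink(tmp))
  write_config(cfg, tmp)
  unname(tools::md5sum(tmp))
}

#' Write a run manifest
#'
#' Records the resolved config hash, seed, input and output files and the
#' package version, so any run is reproducible from its manifest.
#'
#' @param path manifest path (JSON).
#' @param cfg `sim_config` or `NULL`.
#' @param seed seed used.
#' @param inputs,outputs character vectors of file paths.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(path, cfg = NULL, seed = NULL,
                           inputs = character(0), outputs = character(0)) {
  missing_out <- outputs[!file.exists(outputs)]
  if (length(missing_out) > 0)
    ft_validation_error(paste0("manifest lists missing output(s): ",
                               paste(missing_out, collapse = ", ")))
  man <- list(
    config_hash = if (is.null(cfg)) NA else config_hash(cfg),
    seed = seed,
    inputs = as.list(inputs), outputs = as.list(outputs),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    version = as.character(utils::packageVersion("fuccitrack"))
  )
  jsonlite::write_json(man, path, auto_unbox = TRUE, pretty = TRUE, na = "null")
  invisible(path)
}
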