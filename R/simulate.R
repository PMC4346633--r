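#' Simulate clonally expanding Fucci T-cell lineage trees
#'
#' Branching-process generator emulating the tracked microgrid experiments:
#' one founder per well, lognormal division times with family /
#' generational-drift / division-shared / individual variance components (see
#' [sim_config()]), a heritable slow state switching on at
#' `slow_onset_generation`, censoring at the imaging window, a division-depth
#' cap, optional per-cycle death, CTV dye dilution and deterministic
#' state-linked phenotype (SLOW cells are SMALL / CD62L-high).
#'
#' @param cfg a [sim_config()].
#' @param traces also synthesize per-cell Fucci fluorescence traces
#'   (see [synthesize_trace()])?
#' @param seed overrides `cfg$seed` when given.
#' @param founder_state force every founder's latent state (`"FAST"` or
#'   `"SLOW"`); default `NULL` applies the generation rule (founders of sorted
#'   generation `>= slow_onset_generation` are SLOW with probability `p_on`).
#' @param naive_mode founders start quiescent (mKO2++) and sit through an
#'   activation lag of `activation_lag_min` before their first cycle.
#'
#' @return list with
#'   * `trees`: list of validated `lineage_tree` (via [build_tree()]),
#'   * `records`: the track table (schema of [read_tracks()]),
#'   * `truth`: ground-truth data.frame (latent state, true drawn cycle time,
#'     absolute phase boundaries `dn_end` / `g1s_time` / `s_end`, division
#'     shock, CTV intensity, `capped` flag),
#'   * `traces`: named list of traces (or `NULL`),
#'   * `imaging_window`, `frame_interval`: the values drawn for this run.
#'
#' Identical `cfg` + seed give identical output.
#' @examples
#' sim <- simulate_trees(sim_config(n_founders = 4, seed = 1), traces = FALSE)
#' length(sim$trees)
#' @export
simulate_trees <- function(cfg, traces = TRUE, seed = NULL,
                           founder_state = NULL, naive_mode = FALSE) {
  validate_sim_config(cfg)
  seed <- seed %||% cfg$seed
  if (!is.null(seed)) set.seed(seed)

  window <- if (length(cfg$imaging_window) == 2)
    stats::runif(1, cfg$imaging_window[1], cfg$imaging_window[2]) else cfg$imaging_window
  fi <- if (length(cfg$frame_interval) == 2)
    stats::runif(1, cfg$frame_interval[1], cfg$frame_interval[2]) else cfg$frame_interval

  gk <- as.character(cfg$generation_offset)
  lp <- lognorm_params(cfg$gen_mean_h[[gk]], cfg$gen_sd_h[[gk]])
  v <- lp[["varlog"]]
  sd_f <- sqrt(cfg$share_family * v)
  sd_g <- sqrt(cfg$share_drift * v)
  sd_b <- sqrt(cfg$share_division * v)
  sd_e <- sqrt(cfg$share_individual * v)

  rows <- list()
  emit <- function(row) rows[[length(rows) + 1]] <<- row

  for (f in seq_len(cfg$n_founders)) {
    tree_id <- sprintf("T%04d", f)
    well_id <- sprintf("W%04d", f)
    F_t <- stats::rnorm(1, 0, sd_f)
    G_t <- stats::rnorm(1, 0, sd_g)

    st0 <- founder_state %||%
      (if (cfg$generation_offset >= cfg$slow_onset_generation &&
           stats::runif(1) < cfg$p_on) "SLOW" else "FAST")

    # queue entries: id, parent, depth, birth, state, division shock B
    queue <- list(list(id = paste0(tree_id, "_c1"), parent = NA_character_,
                       depth = 0L, birth = 0, state = st0,
                       B = stats::rnorm(1, 0, sd_b)))
    counter <- 1L
    while (length(queue) > 0) {
      cell <- queue[[1]]; queue <- queue[-1]
      gen_abs <- cfg$generation_offset + cell$depth

      arrested <- FALSE
      if (cell$state == "SLOW") {
        if (stats::runif(1) < cfg$p_arrest) {
          arrested <- TRUE; Ttrue <- NA_real_
        } else {
          Ttrue <- stats::rlnorm(1, cfg$slow_meanlog, cfg$slow_sdlog)
        }
      } else {
        Ttrue <- exp(lp[["meanlog"]] + F_t + G_t * (cell$depth - cfg$drift_center) +
                       cell$B + stats::rnorm(1, 0, sd_e))
      }
      lag <- if (naive_mode && cell$depth == 0L) cfg$activation_lag_min else 0
      div_time <- if (arrested) Inf else cell$birth + lag + Ttrue

      died <- !arrested && cfg$death_prob > 0 && stats::runif(1) < cfg$death_prob
      capped <- FALSE
      if (died) {
        fate <- "DIED"
        end <- cell$birth + stats::runif(1, 0, min(div_time - cell$birth, window - cell$birth))
      } else if (div_time > window) {
        fate <- "CENSORED"; end <- window
      } else if (cell$depth >= cfg$max_depth) {
        # tracking stops at this cell's division: censoring it at the imaging
        # end would fake a long undivided span (a spurious NO_DIVISION call)
        fate <- "CENSORED"; end <- div_time; capped <- TRUE
      } else {
        fate <- "DIVIDED"; end <- div_time
      }

      # phase partition (absolute times); founders have no post-mitotic DN gap
      # in naive mode (quiescent lag replaces it)
      cyc_start <- cell$birth + lag
      if (arrested) {
        dn_end <- min(cyc_start + cfg$d_dn_min, end)
        g1s <- NA_real_; s_end <- NA_real_
      } else {
        g1f <- if (cell$state == "SLOW") cfg$g1_frac_slow else cfg$g1_frac_fast
        span <- div_time - cyc_start
        d_dn <- min(cfg$d_dn_min, 0.2 * span)
        dn_end <- cyc_start + d_dn
        g1s <- dn_end + g1f * (span - d_dn)
        s_end <- g1s + cfg$s_frac * (div_time - g1s)
      }

      # phenotype deterministically linked to latent state
      if (cell$state == "SLOW") {
        size <- "SMALL"; cd62l <- "HI"
      } else {
        size <- "LARGE"
        cd62l <- if (gen_abs < cfg$slow_onset_generation) "INT" else "LO"
      }
      ctv <- ctv_intensity(gen_abs, cfg, noise = TRUE)

      emit(list(tree_id = tree_id, well_id = well_id, cell_id = cell$id,
                parent_id = cell$parent, birth_time_min = cell$birth,
                end_time_min = end, fate = fate,
                generation_offset = cfg$generation_offset,
                depth = cell$depth, latent_state = cell$state,
                size_class = size, cd62l_class = cd62l,
                capped = capped, cycle_time_true = if (arrested) NA_real_ else Ttrue,
                lag = lag, dn_end = dn_end, g1s_time = g1s, s_end = s_end,
                ctv = ctv))

      if (fate == "DIVIDED") {
        Bkids <- stats::rnorm(1, 0, sd_b)
        for (d in 1:2) {
          counter <- counter + 1L
          child_state <- if (cfg$generation_offset + cell$depth + 1L >=
                             cfg$slow_onset_generation) {
            p <- if (cell$state == "SLOW") cfg$p_stay else cfg$p_on
            if (stats::runif(1) < p) "SLOW" else "FAST"
          } else "FAST"
          queue[[length(queue) + 1]] <- list(
            id = sprintf("%s_%03d", tree_id, counter), parent = cell$id,
            depth = cell$depth + 1L, birth = end, state = child_state, B = Bkids)
        }
      }
    }
  }

  # column-wise assembly (rbind of one-row frames is quadratic in cells)
  fields <- names(rows[[1]])
  truth <- as.data.frame(
    lapply(stats::setNames(fields, fields), function(f)
      unlist(lapply(rows, `[[`, f), use.names = FALSE)),
    stringsAsFactors = FALSE)
  records <- truth[, c("tree_id", "well_id", "cell_id", "parent_id",
                       "birth_time_min", "end_time_min", "fate",
                       "generation_offset", "size_class", "cd62l_class",
                       "latent_state")]
  trees <- build_trees(records, imaging_end = window, frame_tolerance = fi + 1)

  trace_list <- NULL
  if (traces) {
    trace_list <- vector("list", nrow(truth))
    names(trace_list) <- truth$cell_id
    for (i in seq_len(nrow(truth)))
      trace_list[[i]] <- synthesize_trace(truth[i, ], cfg, frame_interval = fi)
  }

  list(trees = trees, records = records, truth = truth, traces = trace_list,
       imaging_window = window, frame_interval = fi)
}

#' Synthesize a Fucci fluorescence trace for one simulated cell
#'
#' Piecewise-linear mKO2/mAG intensities over the cell's observed span,
#' sampled at the frame interval with multiplicative lognormal noise:
#' background during the double-negative gap, an mKO2 rise to plateau through
#' G1, then rapid mKO2 degradation and an mAG rise at the G1/S transition,
#' mAG high through M. Quiescent founders (naive mode) sit at the mKO2++
#' level through the activation lag; arrested slow cells stay mKO2+ after the
#' gap. Noise is applied as `I * exp(N(0, cv) - cv^2/2)`.
#'
#' @param cell one row of the ground-truth table of [simulate_trees()] (needs
#'   `birth_time_min`, `end_time_min`, `lag`, `dn_end`, `g1s_time`,
#'   `latent_state`, `depth`).
#' @param cfg a [sim_config()].
#' @param frame_interval minutes between samples.
#' @param noise_cv multiplicative noise CV; default from `cfg`
#'   (set 0 for a noiseless trace).
#' @return list with `times`, `ko2`, `ag` plus the ground-truth durations
#'   `d_DN`, `d_KO`, `d_AG` (minutes; `NA` where a phase is absent).
#' @export
synthesize_trace <- function(cell, cfg, frame_interval = 3.5,
                             noise_cv = cfg$reporter_noise_cv) {
  birth <- cell$birth_time_min; end <- cell$end_time_min
  lag_end <- birth + cell$lag
  dn_end <- cell$dn_end; g1s <- cell$g1s_time
  bg <- cfg$reporter_background; hi <- cfg$reporter_plateau
  rise <- cfg$reporter_rise_min; decay <- cfg$reporter_decay_min

  ramp <- function(t, t0, from, to, dur) {
    ifelse(t < t0, from, ifelse(t >= t0 + dur, to, from + (to - from) * (t - t0) / dur))
  }
  ko_at <- function(t) {
    out <- rep(bg, length(t))
    q <- t < lag_end                       # quiescent activation lag: mKO2++
    out[q] <- cfg$ko_high_level
    g1 <- !q & t >= dn_end & (is.na(g1s) | t < g1s)
    out[g1] <- ramp(t[g1], dn_end, bg, hi, rise)
    if (!is.na(g1s)) {
      sg <- !q & t >= g1s
      out[sg] <- ramp(t[sg], g1s, hi, bg, decay)
    }
    out
  }
  ag_at <- function(t) {
    if (is.na(g1s)) return(rep(bg, length(t)))
    ifelse(t < g1s, bg, ramp(t, g1s, bg, hi, rise))
  }

  times <- seq(birth, end, by = frame_interval)
  if (times[length(times)] < end) times <- c(times, end)
  ko2 <- ko_at(times); ag <- ag_at(times)
  if (noise_cv > 0) {
    n <- length(times)
    ko2 <- ko2 * exp(stats::rnorm(n, 0, noise_cv) - noise_cv^2 / 2)
    ag <- ag * exp(stats::rnorm(n, 0, noise_cv) - noise_cv^2 / 2)
  }
  list(cell_id = cell$cell_id, times = times, ko2 = ko2, ag = ag,
       d_DN = if (is.na(dn_end)) NA_real_ else dn_end - (birth + cell$lag),
       d_KO = if (is.na(g1s)) end - dn_end else g1s - dn_end,
       d_AG = if (is.na(g1s)) NA_real_ else end - g1s)
}

#' CTV dye intensity after a number of divisions
#'
#' Median intensity halves at each division; beyond `ctv_floor_generation`
#' (default 9) dilution reaches the unlabelled background and generations are
#' no longer distinguishable.
#'
#' @param generation absolute generation (divisions since labelling), `>= 0`.
#' @param cfg a [sim_config()].
#' @param noise apply lognormal noise with CV `cfg$ctv_cv`?
#' @return intensity in a.u. (vectorised over `generation`), with attribute
#'   none; use [ctv_diluted_out()] for the floor flag.
#' @export
ctv_intensity <- function(generation, cfg, noise = FALSE) {
  if (any(generation < 0)) ft_domain_error("generation must be >= 0")
  med <- cfg$ctv_i0 / 2^generation
  if (noise && cfg$ctv_cv > 0)
    med <- med * exp(stats::rnorm(length(med), 0, sqrt(log(1 + cfg$ctv_cv^2))))
  med
}

#' Is a generation beyond the CTV detection floor?
#'
#' @param generation absolute generation(s).
#' @param cfg a [sim_config()].
#' @return logical: `TRUE` when the dye is diluted out (indistinguishable
#'   from unlabelled background).
#' @export
ctv_diluted_out <- function(generation, cfg) {
  generation >= cfg$ctv_floor_generation
}

#' Per-generation CTV intensity distribution of a snapshot
#'
#' @param snapshot a data.frame from [population_snapshot()].
#' @return data.frame: `generation`, `n`, `median_ctv`, `diluted_out`.
#' @export
ctv_histogram <- function(snapshot) {
  gens <- sort(unique(snapshot$generation))
  out <- do.call(rbind, lapply(gens, function(g) {
    sel <- snapshot$generation == g
    data.frame(generation = g, n = sum(sel),
               median_ctv = stats::median(snapshot$ctv[sel]),
               diluted_out = all(snapshot$diluted_out[sel]))
  }))
  rownames(out) <- NULL
  out
}
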