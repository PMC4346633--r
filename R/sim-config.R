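#' Simulation configuration for the branching-process generator
#'
#' All generative parameters for the clonal-expansion simulator, with defaults
#' set to the stated world of the tracked Fucci imaging experiments.
#'
#' Division times are lognormal per sorted generation, calibrated so the
#' marginal arithmetic mean and s.d. at the measured depths equal the printed
#' summary statistics (generation 1: 13.4 +/- 5.4 h; generation 3: 14.3 +/-
#' 4.4 h; generation 8 fast cyclers reuse the generation-3 parameters, since
#' no separate figure is printed for them). On the log scale each cycle time
#' decomposes as
#' \deqn{\log T = m_g + F_\tau + G_\tau (k - k_0) + B_{div} + \epsilon}
#' with a per-tree family effect \eqn{F}, a per-tree generational drift
#' \eqn{G} evaluated at depth \eqn{k} around the centre \eqn{k_0 = 1.5} (the
#' midpoint of the two measured division rounds), a division-shared shock
#' \eqn{B} drawn once per division and inherited by both daughters (the source
#' of sibling synchrony), and an individual residual. The four components are
#' parameterised as shares of the generation's total log variance with
#' `share_family + 0.25 * share_drift + share_division + share_individual = 1`,
#' which makes the depth-1/2 marginals exactly the calibrated lognormal and
#' yields log-scale correlations of 0.8 (siblings), 0.3 (cousins) and 0.1
#' (mother--daughter) at the defaults.
#'
#' From `slow_onset_generation` (default 8) onward a heritable slow state
#' switches on: daughters of fast mothers become SLOW with probability `p_on`,
#' daughters of SLOW mothers stay SLOW with probability `p_stay`, and a SLOW
#' daughter arrests (never divides in the window) with probability `p_arrest`;
#' non-arrested SLOW cells draw their time from a slow lognormal with median
#' 30 h. SLOW cells are SMALL and CD62L-high; fast cells at depth >= 1 are
#' LARGE with CD62L intermediate before the onset generation and low after.
#'
#' @param generation_offset sorted generation of the founders (1, 3 or 8).
#' @param n_founders number of wells, one founder each.
#' @param imaging_window minutes; scalar for a fixed window or a length-2
#'   range from which one value is drawn per run (default 3960--5400, i.e.
#'   66--90 h).
#' @param frame_interval minutes between frames; scalar or length-2 range
#'   (default 3--4), one value drawn per run.
#' @param max_depth divisions simulated below the founder before tracking
#'   stops (capped cells are censored at the imaging end and flagged in the
#'   ground truth).
#' @param gen_mean_h,gen_sd_h named numeric vectors (names `"1"`, `"3"`,
#'   `"8"`): per-sorted-generation arithmetic mean and s.d. of fast-cycler
#'   division times, hours.
#' @param share_family,share_drift,share_division,share_individual variance
#'   shares of the log-cycle-time components (see Details).
#' @param drift_center depth at which the generational drift vanishes.
#' @param slow_onset_generation,p_on,p_stay,p_arrest slow-state Markov switch.
#' @param slow_meanlog,slow_sdlog lognormal (log-minutes) for SLOW division
#'   times; default median `exp(slow_meanlog)` = 1800 min = 30 h.
#' @param d_dn_min fixed early-G1 double-negative gap, minutes.
#' @param g1_frac_fast,g1_frac_slow G1 (mKO2+) fraction of the post-DN cycle.
#' @param s_frac leading fraction of the mAG+ segment counted as S phase
#'   (for BrdU labelling).
#' @param reporter_plateau,ko_high_level,reporter_rise_min,reporter_decay_min,
#'   reporter_noise_cv,reporter_background piecewise-linear reporter kinetics
#'   and multiplicative noise.
#' @param ctv_i0,ctv_cv,ctv_floor_generation CTV dye: founder intensity,
#'   lognormal CV, and the generation at which dilution reaches background.
#' @param death_prob per-cycle death probability (default 0: dead-cell wells
#'   are excluded upstream in vitro).
#' @param activation_lag_min quiescent (mKO2++) lag before a naive founder's
#'   first division in cohort mode, minutes.
#' @param seed integer or `NULL`; used by [simulate_trees()] when set.
#' @return object of class `sim_config` (a validated list).
#' @seealso [read_config()], [write_config()], [simulate_trees()]
#' @export
sim_config <- function(generation_offset = 1,
                       n_founders = 40,
                       imaging_window = c(3960, 5400),
                       frame_interval = c(3, 4),
                       max_depth = 4,
                       gen_mean_h = c("1" = 13.4, "3" = 14.3, "8" = 14.3),
                       gen_sd_h = c("1" = 5.4, "3" = 4.4, "8" = 4.4),
                       share_family = 0.2,
                       share_drift = 0.4,
                       share_division = 0.5,
                       share_individual = 0.2,
                       drift_center = 1.5,
                       slow_onset_generation = 8,
                       p_on = 0.25,
                       p_stay = 0.8,
                       p_arrest = 0.35,
                       slow_meanlog = log(1800),
                       slow_sdlog = 0.35,
                       d_dn_min = 60,
                       g1_frac_fast = 0.25,
                       g1_frac_slow = 0.7,
                       s_frac = 0.6,
                       reporter_plateau = 1000,
                       ko_high_level = 2500,
                       reporter_rise_min = 10,
                       reporter_decay_min = 3,
                       reporter_noise_cv = 0.05,
                       reporter_background = 20,
                       ctv_i0 = 10000,
                       ctv_cv = 0.15,
                       ctv_floor_generation = 9,
                       death_prob = 0,
                       activation_lag_min = 1440,
                       seed = NULL) {
  cfg <- as.list(environment())
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  chk <- function(ok, msg) if (!ok) ft_validation_error(msg)
  chk(cfg$generation_offset %in% c(1, 3, 8), "generation_offset must be 1, 3 or 8")
  chk(cfg$n_founders >= 1, "n_founders must be >= 1")
  chk(all(cfg$imaging_window > 0) && length(cfg$imaging_window) %in% 1:2,
      "imaging_window must be a positive scalar or range")
  chk(all(cfg$frame_interval > 0) && length(cfg$frame_interval) %in% 1:2,
      "frame_interval must be a positive scalar or range")
  chk(cfg$max_depth >= 1, "max_depth must be >= 1")
  chk(all(c("1", "3", "8") %in% names(cfg$gen_mean_h)) &&
        all(c("1", "3", "8") %in% names(cfg$gen_sd_h)),
      "gen_mean_h / gen_sd_h need entries for generations 1, 3 and 8")
  chk(all(cfg$gen_mean_h > 0) && all(cfg$gen_sd_h > 0), "generation means/sds must be positive")
  sh <- c(cfg$share_family, cfg$share_drift, cfg$share_division, cfg$share_individual)
  chk(all(sh >= 0), "variance shares must be nonnegative")
  chk(abs(cfg$share_family + 0.25 * cfg$share_drift +
            cfg$share_division + cfg$share_individual - 1) < 1e-8,
      "variance shares must satisfy family + drift/4 + division + individual = 1")
  for (p in c("p_on", "p_stay", "p_arrest", "death_prob"))
    chk(cfg[[p]] >= 0 && cfg[[p]] <= 1, paste(p, "must be in [0,1]"))
  chk(exp(cfg$slow_meanlog) > 1440, "slow state median must exceed 1440 min")
  chk(cfg$g1_frac_fast > 0 && cfg$g1_frac_fast < 1 &&
        cfg$g1_frac_slow > 0 && cfg$g1_frac_slow < 1,
      "G1 fractions must be in (0,1)")
  chk(cfg$s_frac > 0 && cfg$s_frac <= 1, "s_frac must be in (0,1]")
  chk(cfg$d_dn_min >= 0, "d_dn_min must be nonnegative")
  chk(cfg$reporter_plateau > 0 && cfg$ko_high_level > cfg$reporter_plateau,
      "ko_high_level must exceed reporter_plateau")
  chk(cfg$ctv_i0 > 0 && cfg$ctv_cv >= 0 && cfg$ctv_floor_generation >= 1,
      "invalid CTV parameters")
  invisible(TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "<sim_config> generation %d, %d founders, window %s min, max depth %d\n",
    x$generation_offset, x$n_founders,
    paste(x$imaging_window, collapse = "-"), x$max_depth))
  cat(sprintf("  slow state: onset gen %d, p_on %.2f, p_stay %.2f, p_arrest %.2f\n",
              x$slow_onset_generation, x$p_on, x$p_stay, x$p_arrest))
  invisible(x)
}

# lognormal (meanlog, sdlog) whose arithmetic mean/sd match (mean_h, sd_h) hours
lognorm_params <- function(mean_h, sd_h) {
  m <- mean_h * 60; s <- sd_h * 60
  v <- log(1 + (s / m)^2)
  c(meanlog = log(m) - v / 2, varlog = v)
}

# ---- TOML subset ----------------------------------------------------------
# The pre-installed R stack has no TOML parser, so the config format is read
# and written by a minimal subset parser: [section] headers, key = value with
# numbers, booleans, quoted strings and flat numeric arrays, '#' comments.

parse_toml_value <- function(txt, line_no) {
  txt <- trimws(txt)
  if (txt == "true") return(TRUE)
  if (txt == "false") return(FALSE)
  if (grepl("^\".*\"$", txt)) return(gsub("^\"|\"$", "", txt))
  if (grepl("^\\[.*\\]$", txt)) {
    inner <- trimws(gsub("^\\[|\\]$", "", txt))
    if (inner == "") return(numeric(0))
    parts <- trimws(strsplit(inner, ",")[[1]])
    return(vapply(parts, function(p) parse_toml_value(p, line_no), numeric(1),
                  USE.NAMES = FALSE))
  }
  val <- suppressWarnings(as.numeric(txt))
  if (is.na(val))
    ft_parse_error(sprintf("cannot parse TOML value '%s' (line %d)", txt, line_no))
  val
}

read_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list(); section <- NULL
  for (i in seq_along(lines)) {
    ln <- sub("#.*$", "", lines[i])
    ln <- trimws(ln)
    if (ln == "") next
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      out[[section]] <- out[[section]] %||% list()
    } else if (grepl("=", ln, fixed = TRUE)) {
      eq <- regexpr("=", ln, fixed = TRUE)
      key <- trimws(substr(ln, 1, eq - 1))
      val <- parse_toml_value(substr(ln, eq + 1, nchar(ln)), i)
      if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
    } else {
      ft_parse_error(sprintf("unparseable TOML line %d: '%s'", i, lines[i]))
    }
  }
  out
}

format_toml_value <- function(v) {
  if (is.logical(v)) return(if (v) "true" else "false")
  if (is.character(v)) return(sprintf('"%s"', v))
  if (length(v) > 1) return(paste0("[", paste(format(v, digits = 15), collapse = ", "), "]"))
  format(v, digits = 15)
}

write_toml <- function(sections, path) {
  lines <- character(0)
  for (s in names(sections)) {
    lines <- c(lines, sprintf("[%s]", s))
    for (k in names(sections[[s]]))
      lines <- c(lines, sprintf("%s = %s", k, format_toml_value(sections[[s]][[k]])))
    lines <- c(lines, "")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a simulation configuration from a TOML file
#'
#' The file holds sections `[imaging]`, `[distributions]`, `[heritability]`,
#' `[slow_state]`, `[reporter]`, `[ctv]`, `[brdu]`, `[phenotype]`; any omitted
#' key falls back to the [sim_config()] default. See the shipped default file
#' `system.file("extdata", "default_config.toml", package = "fuccitrack")`.
#'
#' @param path TOML file path.
#' @return a validated `sim_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) ft_usage_error(sprintf("config file not found: %s", path))
  tm <- read_toml(path)
  g <- function(section, key) (tm[[section]] %||% list())[[key]]
  args <- list()
  set <- function(name, val) if (!is.null(val)) args[[name]] <<- val

  set("seed", g("imaging", "seed"))
  set("generation_offset", g("imaging", "generation_offset"))
  set("n_founders", g("imaging", "n_founders"))
  set("imaging_window", g("imaging", "imaging_window"))
  set("frame_interval", g("imaging", "frame_interval"))
  set("max_depth", g("imaging", "max_depth"))
  set("activation_lag_min", g("imaging", "activation_lag_min"))

  mh <- g("distributions", "gen_mean_h"); sh <- g("distributions", "gen_sd_h")
  if (!is.null(mh)) { names(mh) <- c("1", "3", "8"); args$gen_mean_h <- mh }
  if (!is.null(sh)) { names(sh) <- c("1", "3", "8"); args$gen_sd_h <- sh }

  set("share_family", g("heritability", "share_family"))
  set("share_drift", g("heritability", "share_drift"))
  set("share_division", g("heritability", "share_division"))
  set("share_individual", g("heritability", "share_individual"))
  set("drift_center", g("heritability", "drift_center"))

  set("slow_onset_generation", g("slow_state", "onset_generation"))
  set("p_on", g("slow_state", "p_on"))
  set("p_stay", g("slow_state", "p_stay"))
  set("p_arrest", g("slow_state", "p_arrest"))
  set("slow_meanlog", g("slow_state", "meanlog"))
  set("slow_sdlog", g("slow_state", "sdlog"))

  set("d_dn_min", g("reporter", "d_dn_min"))
  set("g1_frac_fast", g("reporter", "g1_frac_fast"))
  set("g1_frac_slow", g("reporter", "g1_frac_slow"))
  set("reporter_plateau", g("reporter", "plateau"))
  set("ko_high_level", g("reporter", "ko_high_level"))
  set("reporter_rise_min", g("reporter", "rise_min"))
  set("reporter_decay_min", g("reporter", "decay_min"))
  set("reporter_noise_cv", g("reporter", "noise_cv"))
  set("reporter_background", g("reporter", "background"))

  set("ctv_i0", g("ctv", "i0"))
  set("ctv_cv", g("ctv", "cv"))
  set("ctv_floor_generation", g("ctv", "floor_generation"))

  set("s_frac", g("brdu", "s_frac"))
  set("death_prob", g("phenotype", "death_prob"))

  do.call(sim_config, args)
}

#' Write a simulation configuration to a TOML file
#'
#' @param cfg a `sim_config`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  sections <- list(
    imaging = list(
      generation_offset = cfg$generation_offset,
      n_founders = cfg$n_founders,
      imaging_window = cfg$imaging_window,
      frame_interval = cfg$frame_interval,
      max_depth = cfg$max_depth,
      activation_lag_min = cfg$activation_lag_min
    ),
    distributions = list(
      gen_mean_h = unname(cfg$gen_mean_h[c("1", "3", "8")]),
      gen_sd_h = unname(cfg$gen_sd_h[c("1", "3", "8")])
    ),
    heritability = list(
      share_family = cfg$share_family, share_drift = cfg$share_drift,
      share_division = cfg$share_division, share_individual = cfg$share_individual,
      drift_center = cfg$drift_center
    ),
    slow_state = list(
      onset_generation = cfg$slow_onset_generation,
      p_on = cfg$p_on, p_stay = cfg$p_stay, p_arrest = cfg$p_arrest,
      meanlog = cfg$slow_meanlog, sdlog = cfg$slow_sdlog
    ),
    reporter = list(
      d_dn_min = cfg$d_dn_min, g1_frac_fast = cfg$g1_frac_fast,
      g1_frac_slow = cfg$g1_frac_slow, plateau = cfg$reporter_plateau,
      ko_high_level = cfg$ko_high_level, rise_min = cfg$reporter_rise_min,
      decay_min = cfg$reporter_decay_min, noise_cv = cfg$reporter_noise_cv,
      background = cfg$reporter_background
    ),
    ctv = list(i0 = cfg$ctv_i0, cv = cfg$ctv_cv,
               floor_generation = cfg$ctv_floor_generation),
    brdu = list(s_frac = cfg$s_frac),
    phenotype = list(death_prob = cfg$death_prob)
  )
  if (!is.null(cfg$seed)) sections$imaging$seed <- cfg$seed
  write_toml(sections, path)
}
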