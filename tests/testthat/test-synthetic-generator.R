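test_that("config validation rejects bad parameters before sampling", {
  expect_error(sim_config(generation_offset = 5), class = "ft_validation_error")
  expect_error(sim_config(p_on = 1.5), class = "ft_validation_error")
  expect_error(sim_config(share_family = 0.9), class = "ft_validation_error")
  expect_error(sim_config(slow_meanlog = log(1000)), class = "ft_validation_error")
  expect_error(sim_config(s_frac = 0), class = "ft_validation_error")
})

test_that("identical config and seed give identical output", {
  cfg <- sim_config(n_founders = 10, seed = 77)
  a <- simulate_trees(cfg)
  b <- simulate_trees(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)
  expect_identical(a$traces, b$traces)
})

test_that("trees satisfy the conservation identities", {
  cfg <- sim_config(n_founders = 25, seed = 8)
  sim <- simulate_trees(cfg, traces = FALSE)
  for (t in sim$trees) {
    n <- t$nodes
    expect_equal(nrow(n), 1 + 2 * sum(n$fate == "DIVIDED"))
    expect_equal(sum(is.na(n$parent_id)), 1)
    kids <- n[!is.na(n$parent_id), ]
    pend <- n$end_time[match(kids$parent_id, n$cell_id)]
    expect_true(all(abs(kids$birth_time - pend) < 1e-9))
    expect_true(all(n$end_time <= sim$imaging_window + 1e-9))
  }
})

test_that("no slow cells arise below the onset generation", {
  sim <- simulate_trees(sim_config(n_founders = 40, seed = 12), traces = FALSE)
  expect_true(all(sim$truth$latent_state == "FAST"))
})

test_that("the slow-state switch rate matches p_on at the onset generation", {
  cfg <- sim_config(generation_offset = 8, n_founders = 600, p_on = 0.3,
                    imaging_window = 6000, max_depth = 1, seed = 13)
  sim <- simulate_trees(cfg, traces = FALSE)
  tr <- sim$truth
  founders <- tr[tr$depth == 0, ]
  fast_founders <- founders$cell_id[founders$latent_state == "FAST" &
                                      founders$fate == "DIVIDED"]
  daughters <- tr[tr$depth == 1 & tr$parent_id %in% fast_founders, ]
  n <- nrow(daughters)
  expect_gte(n, 500)
  phat <- mean(daughters$latent_state == "SLOW")
  ci <- 0.3 + c(-1, 1) * qnorm(0.995) * sqrt(0.3 * 0.7 / n)
  expect_gte(phat, ci[1]); expect_lte(phat, ci[2])
})

test_that("generation-1 marginals recover the configured mean and spread", {
  cfg <- sim_config(n_founders = 200, imaging_window = 20000, max_depth = 3,
                    seed = 9)
  sim <- simulate_trees(cfg, traces = FALSE)
  cyc <- do.call(rbind, lapply(sim$trees, extract_cycle_times))
  s <- summarize_cycle_times(cyc$cycle_time, unit = "h")
  expect_gt(s$n, 1000)
  # 3-sigma guard band at this n (the tight 2-SE check is in acceptance)
  expect_lt(abs(s$mu - 13.4), 3 * 5.4 / sqrt(s$n))
  expect_lt(abs(s$sigma - 5.4), 0.15 * 5.4)
})

test_that("noiseless trace synthesis is exact at the ground-truth boundaries", {
  cfg <- sim_config(n_founders = 5, imaging_window = 6000, max_depth = 2,
                    seed = 10, reporter_noise_cv = 0)
  sim <- simulate_trees(cfg, traces = TRUE)
  row <- sim$truth[sim$truth$depth == 1 & sim$truth$fate == "DIVIDED", ][1, ]
  tr <- sim$traces[[row$cell_id]]
  seg <- segment_trace(tr)
  fi <- sim$frame_interval
  expect_lt(abs(seg$durations[["d_DN"]] - tr$d_DN), 2 * fi)
  expect_lt(abs(seg$durations[["d_KO"]] - tr$d_KO), 2 * fi)
  expect_lt(abs(seg$durations[["d_AG"]] - tr$d_AG), 2 * fi)
  # slow cells spend the configured larger G1 fraction in mKO2+
  expect_equal(row$g1s_time - row$dn_end,
               cfg$g1_frac_fast * (row$end_time_min - row$dn_end),
               tolerance = 1e-8)
})

test_that("quiescent naive founders are mKO2++ until activation", {
  cfg <- sim_config(n_founders = 15, seed = 18, activation_lag_min = 1440)
  sim <- simulate_trees(cfg, traces = TRUE, naive_mode = TRUE)
  snap0 <- population_snapshot(sim, 0, cfg)
  expect_equal(nrow(snap0), 15)
  expect_true(all(snap0$fucci_state == "KO_HIGH"))
  f1 <- sim$truth[sim$truth$depth == 0, ][1, ]
  tr <- sim$traces[[f1$cell_id]]
  pre <- tr$times < f1$birth_time_min + f1$lag
  expect_true(all(tr$ko2[pre] > fucci_gate()$theta_ko_high * 0.5))
  expect_true(all(tr$ag[pre] < fucci_gate()$theta_ag))
})

test_that("cohort snapshots show the expansion-phase reporter crossover", {
  cfg <- sim_config(n_founders = 60, imaging_window = 4500, seed = 19)
  co <- simulate_cohort(cfg, times = c(0, 3000))
  fr <- co$fractions
  expect_equal(fr$frac_ko[fr$time == 0], 1)       # all quiescent at t = 0
  expect_equal(fr$frac_ag[fr$time == 0], 0)
  mid <- fr[fr$time == 3000, ]
  expect_gt(mid$frac_ag + mid$frac_dn, mid$frac_ko) # cycling: mAG+/DN dominate
})

test_that("deterministic 12-h cycles give 16 cells at 48 h", {
  cfg <- sim_config(gen_mean_h = c("1" = 12, "3" = 12, "8" = 12),
                    gen_sd_h = c("1" = 1e-9, "3" = 1e-9, "8" = 1e-9),
                    n_founders = 3, imaging_window = 2880, max_depth = 10,
                    seed = 20)
  counts <- single_cell_expansion(cfg, horizon = 2880, replicates = 3, seed = 20)
  expect_equal(counts, c(16L, 16L, 16L))
})

test_that("arrested slow founders do not expand", {
  cfg <- sim_config(generation_offset = 8, p_arrest = 1, n_founders = 5, seed = 21)
  counts <- single_cell_expansion(cfg, founder_state = "SLOW",
                                  replicates = 5, seed = 21)
  expect_equal(counts, rep(1L, 5))
})

test_that("fast founders out-expand slow founders (rank-sum test)", {
  cfg <- sim_config(generation_offset = 8, seed = 22, max_depth = 8)
  fast <- single_cell_expansion(cfg, founder_state = "FAST", replicates = 200,
                                seed = 22)
  slow <- single_cell_expansion(cfg, founder_state = "SLOW", replicates = 200,
                                seed = 23)
  res <- expansion_rank_test(fast, slow, alternative = "greater")
  expect_lt(res$p_value, 0.001)
})

test_that("CTV halves per division down to the nine-division floor", {
  cfg <- sim_config()
  expect_equal(ctv_intensity(0, cfg), cfg$ctv_i0)
  expect_equal(ctv_intensity(3, cfg), cfg$ctv_i0 / 8)
  expect_false(ctv_diluted_out(3, cfg))
  expect_true(ctv_diluted_out(10, cfg))
  expect_error(ctv_intensity(-1, cfg), class = "ft_domain_error")
  # with noise, medians still halve per generation below the floor
  set.seed(30)
  meds <- vapply(0:5, function(g) median(ctv_intensity(rep(g, 4000), cfg,
                                                       noise = TRUE)), 0)
  ratios <- meds[-length(meds)] / meds[-1]
  expect_true(all(abs(ratios - 2) < 0.1))
})

test_that("BrdU labelling follows S-phase overlap bookkeeping", {
  cfg <- sim_config(n_founders = 30, imaging_window = 4500, seed = 24)
  sim <- simulate_trees(cfg, traces = FALSE)
  expect_error(brdu_pulse(sim, 1000, 0, cfg), class = "ft_domain_error")
  # hand-checked 3-cell case: founder divides at 1000, S on (g1s, s_end)
  rec <- data.frame(
    tree_id = "T1", well_id = "W1",
    cell_id = c("a", "b", "c"), parent_id = c(NA, "a", "a"),
    birth_time_min = c(0, 1000, 1000), end_time_min = c(1000, 2000, 2000),
    fate = c("DIVIDED", "CENSORED", "CENSORED"), generation_offset = 1L,
    stringsAsFactors = FALSE)
  truth <- data.frame(
    rec,
    depth = c(0L, 1L, 1L), latent_state = "FAST",
    size_class = "LARGE", cd62l_class = "INT", capped = FALSE,
    cycle_time_true = c(1000, NA, NA), lag = 0,
    dn_end = c(60, 1060, 1060), g1s_time = c(295, 1295, NA),
    s_end = c(718, 1718, NA), ctv = 1, stringsAsFactors = FALSE)
  handsim <- list(truth = truth, trees = NULL)
  # pulse (400, 500]: only the founder's S (295-718) overlaps; daughters
  # inherit its label at harvest 500 -> but they are born later; at t = 500
  # only 'a' is alive and it is labelled
  out <- brdu_pulse(handsim, 400, 100, cfg)
  expect_equal(out$frac_brdu[out$fucci_state == "ALL"], 1)
  # pulse (800, 900]: founder past S (in mAG, post-718 it is still AG_POS but
  # not S) -> no label anywhere
  out2 <- brdu_pulse(handsim, 800, 100, cfg)
  expect_equal(out2$frac_brdu[out2$fucci_state == "ALL"], 0)
  # pulse spanning the founder's S, harvested after division: both daughters
  # carry the inherited label even though their own S (from 1295) never ran
  out3 <- brdu_pulse(handsim, 600, 500, cfg)   # harvest at 1100
  expect_equal(out3$n[out3$fucci_state == "ALL"], 2)
  expect_equal(out3$frac_brdu[out3$fucci_state == "ALL"], 1)
})

test_that("BrdU fractions rise with pulse length and mAG+ leads at 3 h", {
  cfg <- sim_config(n_founders = 50, imaging_window = 4500, seed = 25)
  sim <- simulate_trees(cfg, traces = FALSE)
  t0 <- 2000
  fr <- lapply(c(180, 300, 480), function(d) brdu_pulse(sim, t0, d, cfg))
  getf <- function(x, s) x$frac_brdu[x$fucci_state == s]
  for (s in c("KO_POS", "AG_POS", "ALL")) {
    v <- vapply(fr, getf, 0, s = s)
    expect_true(all(diff(v) >= -1e-9), info = s)
  }
  expect_gt(getf(fr[[1]], "AG_POS"), getf(fr[[1]], "KO_POS") + 0.3)
})
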