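test_that("build_tree labels the canonical quartet and computes cycle times", {
  tr <- build_tree(quartet_records())
  n <- tr$nodes
  expect_setequal(n$kinship_label, c("C1", "M1", "M2", "D1", "D2", "D3", "D4"))
  expect_equal(n$depth[n$kinship_label == "C1"], 0L)
  expect_equal(sort(n$kinship_label[n$depth == 2]), c("D1", "D2", "D3", "D4"))
  # daughters of M1 are D1/D2
  m1 <- n$cell_id[n$kinship_label == "M1"]
  expect_setequal(n$kinship_label[!is.na(n$parent_id) & n$parent_id == m1],
                  c("D1", "D2"))
  expect_equal(n$cycle_time[n$kinship_label == "M1"], 750)
  expect_true(all(is.na(n$cycle_time[n$fate == "CENSORED"])))
  # node-count identity: 1 + 2 * #DIVIDED
  expect_equal(nrow(n), 1 + 2 * sum(n$fate == "DIVIDED"))
})

test_that("a single censored record yields a founder-only tree with no pairs", {
  rec <- quartet_records()[1, ]
  rec$fate <- "CENSORED"
  tr <- build_tree(rec)
  expect_equal(nrow(tr$nodes), 1)
  for (rel in c("SIBLING", "MOTHER_DAUGHTER", "COUSIN"))
    expect_equal(kinship_pairs(list(tr), rel)$n_pairs, 0)
  expect_equal(nrow(extract_cycle_times(tr)), 0)
})

test_that("structural and timing defects are rejected with classed errors", {
  rec <- quartet_records()
  bad <- rec; bad$parent_id[4] <- "nonexistent"
  expect_error(build_tree(bad), class = "ft_structural_error")

  bad <- rec; bad$well_id[4] <- "W2"   # parent link across wells
  expect_error(build_tree(bad), class = "ft_structural_error")

  bad <- rec[-4, ]                      # DIVIDED mother with one child
  expect_error(build_tree(bad), class = "ft_structural_error")

  bad <- rec; bad$birth_time_min[4] <- rec$end_time_min[2] + 30
  expect_error(build_tree(bad), class = "ft_timing_error")

  bad <- rec; bad$fate[4] <- "CENSORED"; bad$parent_id[2] <- "d1"
  expect_error(build_tree(bad), class = "ft_structural_error") # cycle/two roots
})

test_that("qc_filter applies the three per-well exclusion rules", {
  clean <- build_tree(quartet_records(tree_id = "T1", well_id = "W1"))
  died_rec <- quartet_records(tree_id = "T2", well_id = "W2")
  died_rec$fate[5] <- "DIED"
  died <- build_tree(died_rec)
  # two founders in one well at t = 0
  f1 <- quartet_records()[1, ]; f1$fate <- "CENSORED"
  f1$tree_id <- "T3"; f1$well_id <- "W3"
  f2 <- f1; f2$tree_id <- "T4"; f2$cell_id <- "c2"
  # intruder: root born mid-imaging in the clean tree's well
  intr <- f1; intr$tree_id <- "T5"; intr$well_id <- "W5"
  host <- quartet_records(tree_id = "T6", well_id = "W5")
  intr$birth_time_min <- 900; intr$end_time_min <- 2000

  trees <- list(clean, died, build_tree(f1), build_tree(f2),
                build_tree(intr), build_tree(host))
  res <- qc_filter(trees)
  expect_equal(vapply(res$included, function(t) t$tree_id, ""), "T1")
  expect_setequal(res$log$rule[res$log$tree_id == "T2"], "death_during_imaging")
  expect_setequal(res$log$rule[res$log$tree_id %in% c("T3", "T4")],
                  "multiple_initial_cells")
  # the whole well is dropped: host tree excluded along with the intruder
  expect_true(all(c("T5", "T6") %in% res$log$tree_id))
  expect_true(all(vapply(res$excluded, function(t) t$qc_status, "") == "EXCLUDED"))
})

test_that("extract_cycle_times follows the founder-exclusion measurement rule", {
  tr <- build_tree(quartet_records())            # only M1, M2 divide
  ct <- extract_cycle_times(tr)
  expect_equal(nrow(ct), 2)
  expect_setequal(ct$generation_abs, 2)          # offset 1 + depth 1
  full <- build_tree(quartet_records(daughters_divide = TRUE))
  expect_equal(nrow(extract_cycle_times(full)), 6)
  expect_equal(nrow(extract_cycle_times(full, complete_only = FALSE)), 15)
})

test_that("kinship_pairs enumerates the canonical quartet", {
  tr <- build_tree(quartet_records(daughters_divide = TRUE))
  expect_equal(kinship_pairs(list(tr), "SIBLING")$n_pairs, 3)
  expect_equal(kinship_pairs(list(tr), "COUSIN")$n_pairs, 4)
  # founder excluded by default; the idealized count admits C1 -> M dyads
  expect_equal(kinship_pairs(list(tr), "MOTHER_DAUGHTER")$n_pairs, 4)
  expect_equal(kinship_pairs(list(tr), "MOTHER_DAUGHTER",
                             include_founder = TRUE)$n_pairs, 6)
  # only M1's daughters divide -> no complete cousin pair
  part <- quartet_records(daughters_divide = TRUE)
  part <- part[!part$parent_id %in% c("d3", "d4"), ]
  part$fate[part$cell_id %in% c("d3", "d4")] <- "CENSORED"
  expect_equal(kinship_pairs(list(build_tree(part)), "COUSIN")$n_pairs, 0)
  expect_error(kinship_pairs(list(tr), "AUNT"), class = "ft_usage_error")
})

test_that("pair counts match the brute-force enumerator on depths 1-4", {
  set.seed(42)
  for (d in 1:4) {
    tr <- build_tree(make_complete_tree(d), imaging_end = 1e5)
    for (rel in c("SIBLING", "MOTHER_DAUGHTER", "COUSIN")) {
      for (inc in c(FALSE, TRUE)) {
        expect_equal(kinship_pairs(list(tr), rel, include_founder = inc)$n_pairs,
                     brute_force_pairs(tr, rel, include_founder = inc),
                     info = sprintf("depth %d, %s, founder %s", d, rel, inc))
      }
    }
    # closed forms: with cycles complete through depth d, siblings number
    # 2^d - 1 (one pair per division producing complete daughters) and
    # mother-daughter dyads (founder admitted) 2 * (2^d - 1) = all complete
    # non-root cells; the latter is the depth-(d+1) instance of 2*(2^(d-1)-1)
    expect_equal(kinship_pairs(list(tr), "SIBLING")$n_pairs, 2^d - 1)
    expect_equal(kinship_pairs(list(tr), "MOTHER_DAUGHTER",
                               include_founder = TRUE)$n_pairs,
                 2 * (2^d - 1))
  }
})

test_that("non-relative pairing yields min(n1, n2) rank-matched pairs", {
  set.seed(7)
  t1 <- build_tree(make_complete_tree(2, tree_id = "A", well_id = "WA"))
  t2 <- build_tree(make_complete_tree(1, tree_id = "B", well_id = "WB"))
  ps <- kinship_pairs(list(t1, t2), "NON_RELATIVE")
  n1 <- sum(t1$nodes$fate == "DIVIDED" & t1$nodes$depth > 0)
  n2 <- sum(t2$nodes$fate == "DIVIDED" & t2$nodes$depth > 0)
  expect_equal(ps$n_pairs, min(n1, n2))
})

test_that("kinship pairs never contain censored or dead members", {
  set.seed(11)
  cfg <- sim_config(n_founders = 30, seed = 99, death_prob = 0.05)
  sim <- simulate_trees(cfg, traces = FALSE)
  for (rel in c("SIBLING", "MOTHER_DAUGHTER", "COUSIN", "NON_RELATIVE")) {
    ps <- kinship_pairs(sim$trees, rel)
    if (ps$n_pairs == 0) next
    ok_ids <- unlist(lapply(sim$trees, function(t)
      t$nodes$cell_id[t$nodes$fate == "DIVIDED" & t$nodes$depth > 0]))
    expect_true(all(ps$pairs$cell_a %in% ok_ids))
    expect_true(all(ps$pairs$cell_b %in% ok_ids))
  }
})

test_that("classify_division_speed partitions durations as printed", {
  th <- speed_thresholds()
  expect_equal(classify_division_speed(c(550, 600, 800, 900, 1000.5, 1200), th),
               c("FAST", "MEDIUM", "MEDIUM", "INTERMEDIATE", "SLOW", "SLOW"))
  expect_equal(classify_division_speed(c(2000, 1500), th, divided = FALSE),
               c("NO_DIVISION", "UNCALLABLE"))
  expect_error(classify_division_speed(-5, th), class = "ft_domain_error")
  # partition property: every duration maps to exactly one category
  set.seed(3)
  x <- runif(500, 0, 3000)
  cats <- classify_division_speed(x, th, divided = runif(500) < 0.5)
  expect_true(all(nchar(cats) > 0))
  expect_true(all(cats %in% c("FAST", "MEDIUM", "INTERMEDIATE", "SLOW",
                              "NO_DIVISION", "UNCALLABLE")))
  expect_error(speed_thresholds(fast_max = 900, medium_max = 800),
               class = "ft_validation_error")
})

test_that("early/late divider classification uses the 24-h day boundary", {
  rec <- quartet_records()
  rec$end_time_min[1] <- 1200; rec$birth_time_min[2:3] <- 1200  # 20 h
  rec$end_time_min[2:3] <- 2000; rec$birth_time_min[4:7] <- 2000
  expect_equal(early_late_divider(build_tree(rec)), "EARLY")
  rec$end_time_min[1] <- 1800; rec$birth_time_min[2:3] <- 1800  # 30 h
  expect_equal(early_late_divider(build_tree(rec)), "LATE")
  lone <- quartet_records()[1, ]; lone$fate <- "CENSORED"
  expect_equal(early_late_divider(build_tree(lone)), "NONE")
})
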