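# Fixture builders and independent oracles shared across test files.
# Everything is generated in code; no stored data.

# A complete binary tree whose cells at depth <= observed_depth are DIVIDED
# (complete cycles) and whose deepest layer is CENSORED. Cycle times drawn
# from `rcycle` (default: uniform around 700 min).
make_complete_tree <- function(observed_depth, tree_id = "T1", well_id = "W1",
                               rcycle = function(n) runif(n, 600, 800)) {
  rows <- list()
  add <- function(id, parent, birth, end, fate)
    rows[[length(rows) + 1]] <<- data.frame(
      tree_id = tree_id, well_id = well_id, cell_id = id, parent_id = parent,
      birth_time_min = birth, end_time_min = end, fate = fate,
      generation_offset = 1L, stringsAsFactors = FALSE)
  recurse <- function(id, parent, birth, depth) {
    if (depth > observed_depth) {
      add(id, parent, birth, birth + 500, "CENSORED")
      return(invisible())
    }
    end <- birth + rcycle(1)
    add(id, parent, birth, end, "DIVIDED")
    recurse(paste0(id, "a"), id, end, depth + 1)
    recurse(paste0(id, "b"), id, end, depth + 1)
  }
  recurse("r", NA_character_, 0, 0)
  do.call(rbind, rows)
}

# Brute-force kinship pair enumerator, independent of kinship_pairs():
# works from the raw parent map by exhaustive comparison of all cell pairs.
brute_force_pairs <- function(tree, relation, include_founder = FALSE) {
  n <- tree$nodes
  ok <- n$fate == "DIVIDED" & (n$depth > 0 | include_founder)
  parent_of <- stats::setNames(n$parent_id, n$cell_id)
  grandparent <- function(id) {
    p <- parent_of[[id]]
    if (is.na(p)) NA_character_ else parent_of[[p]]
  }
  count <- 0L
  ids <- n$cell_id
  if (relation == "MOTHER_DAUGHTER") {
    for (a in ids) for (b in ids) {
      if (!is.na(parent_of[[b]]) && parent_of[[b]] == a &&
          ok[n$cell_id == a] && ok[n$cell_id == b])
        count <- count + 1L
    }
  } else {
    for (i in seq_along(ids)) for (j in seq_along(ids)) {
      if (i >= j) next
      a <- ids[i]; b <- ids[j]
      if (!(ok[i] && ok[j])) next
      pa <- parent_of[[a]]; pb <- parent_of[[b]]
      if (relation == "SIBLING" &&
          !is.na(pa) && !is.na(pb) && pa == pb) count <- count + 1L
      if (relation == "COUSIN") {
        ga <- grandparent(a); gb <- grandparent(b)
        if (!is.na(ga) && !is.na(gb) && ga == gb &&
            (is.na(pa) || is.na(pb) || pa != pb)) count <- count + 1L
      }
    }
  }
  count
}

# Exhaustive Spearman permutation oracle: rho via stats::cor, p by full
# enumeration (independent of the package's all_perms/spearman_rho).
oracle_exact_spearman_p <- function(x, y) {
  n <- length(x)
  obs <- stats::cor(x, y, method = "spearman")
  perms <- gtools_permutations(n)
  rhos <- apply(perms, 1, function(p) stats::cor(x, y[p], method = "spearman"))
  mean(abs(rhos) >= abs(obs) - 1e-12)
}

# minimal permutation generator (lexicographic), avoids extra deps
gtools_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- gtools_permutations(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(rep(k, nrow(sub)), sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

# Trees with prescribed mother/daughter cycle times (depth-1 mothers, depth-2
# daughters divided via censored grandchildren) for contingency fixtures.
make_dyad_tree <- function(tree_id, mother_cycles, daughter_cycles) {
  stopifnot(length(mother_cycles) == 2, length(daughter_cycles) == 4)
  rows <- list()
  add <- function(id, parent, birth, end, fate)
    rows[[length(rows) + 1]] <<- data.frame(
      tree_id = tree_id, well_id = paste0("W", tree_id), cell_id = id,
      parent_id = parent, birth_time_min = birth, end_time_min = end,
      fate = fate, generation_offset = 8L, stringsAsFactors = FALSE)
  add("c1", NA_character_, 0, 500, "DIVIDED")
  for (m in 1:2) {
    mid <- paste0("m", m)
    mend <- 500 + mother_cycles[m]
    add(mid, "c1", 500, mend, "DIVIDED")
    for (d in 1:2) {
      k <- (m - 1) * 2 + d
      did <- paste0("d", k)
      dend <- mend + daughter_cycles[k]
      add(did, mid, mend, dend, "DIVIDED")
      add(paste0(did, "x"), did, dend, dend + 100, "CENSORED")
      add(paste0(did, "y"), did, dend, dend + 100, "CENSORED")
    }
  }
  build_tree(do.call(rbind, rows), imaging_end = 10000)
}
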