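#' Summary statistics of cycle times
#'
#' Arithmetic mean, n-1 sample standard deviation and event count, with an
#' explicit unit tag (the printed per-generation summaries are in hours).
#'
#' @param values positive durations.
#' @param unit `"min"` or `"h"`; when `values` are minutes and `unit = "h"`
#'   they are converted.
#' @param values_unit unit the input is expressed in (default `"min"`).
#' @return object of class `summary_stats`: list with `mu`, `sigma`, `n`,
#'   `unit`, `degenerate` (`TRUE` when `n == 1`, where `sigma = 0` by
#'   convention).
#' @export
summarize_cycle_times <- function(values, unit = "h", values_unit = "min") {
  values <- values[!is.na(values)]
  if (length(values) == 0) ft_usage_error("no cycle times to summarize")
  if (any(values <= 0)) ft_domain_error("cycle times must be positive")
  if (values_unit == "min" && unit == "h") values <- values / 60
  if (values_unit == "h" && unit == "min") values <- values * 60
  n <- length(values)
  structure(list(mu = mean(values),
                 sigma = if (n > 1) stats::sd(values) else 0,
                 n = n, unit = unit, degenerate = n == 1),
            class = "summary_stats")
}

#' @export
print.summary_stats <- function(x, ...) {
  cat(sprintf("mu = %.2f %s, sigma = %.2f %s, N = %d%s\n",
              x$mu, x$unit, x$sigma, x$unit, x$n,
              if (x$degenerate) " (degenerate)" else ""))
  invisible(x)
}

# average ranks (midranks for ties)
midrank <- function(x) rank(x, ties.method = "average")

spearman_rho <- function(x, y) {
  rx <- midrank(x); ry <- midrank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0)
    ft_error("zero variance in one margin: rho undefined", "ft_degenerate_error")
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# all permutations of 1..n (n <= 8)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

#' Spearman rank correlation for a kinship pair set
#'
#' Average-rank tie handling; two-sided p-value from the t-distribution
#' approximation, or exact by full permutation enumeration for `n <= 8`
#' (`method = "exact"`).
#'
#' @param pairs a `pair_set` (see [kinship_pairs()]) or a data.frame with
#'   columns `t_a`, `t_b`.
#' @param method `"t"` (asymptotic, default) or `"exact"`.
#' @return object of class `correlation_result`: list with `rho`, `p_value`,
#'   `n`, `relation`, `method`.
#' @examples
#' p <- data.frame(t_a = c(1, 2, 3), t_b = c(3, 1, 2))
#' spearman_cor(p)$rho   # -0.5
#' @export
spearman_cor <- function(pairs, method = c("t", "exact")) {
  method <- match.arg(method)
  relation <- if (inherits(pairs, "pair_set")) pairs$relation else NA_character_
  df <- if (inherits(pairs, "pair_set")) pairs$pairs else pairs
  n <- nrow(df)
  if (n < 3) ft_error("need at least 3 pairs for a correlation",
                      "ft_insufficient_pairs_error")
  rho <- spearman_rho(df$t_a, df$t_b)
  if (method == "exact") {
    if (n > 8) ft_usage_error("exact permutation p only for n <= 8")
    perms <- all_perms(n)
    rhos <- apply(perms, 1, function(p) spearman_rho(df$t_a, df$t_b[p]))
    p_value <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    if (abs(rho) >= 1) {
      p_value <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p_value <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
  }
  structure(list(rho = rho, p_value = p_value, n = n,
                 relation = relation, method = method),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Spearman rho = %.3f, P = %.3g, N = %d%s\n", x$rho, x$p_value,
              x$n, if (is.na(x$relation)) "" else paste0(" (", x$relation, ")")))
  invisible(x)
}

#' Permutation null for a kinship correlation
#'
#' Destroys the pair structure while preserving both marginals: the second
#' member of every pair is shuffled uniformly across pairs `n_perm` times and
#' the Spearman rho recomputed, mirroring the randomization control applied
#' to the tracked generation-8 cycle times. The empirical p uses the add-one
#' rule \eqn{p = (1 + \#\{|\rho_{null}| \ge |\rho_{obs}|\}) / (n_{perm}+1)},
#' so it is never exactly zero.
#'
#' @param pairs a `pair_set` or data.frame with `t_a`, `t_b`.
#' @param n_perm number of permutations (`>= 100`).
#' @param seed RNG seed for reproducibility.
#' @return object of class `permutation_result`: list with `observed_rho`,
#'   `null_rhos`, `empirical_p`, `n_perm`, `seed`.
#' @export
permutation_null <- function(pairs, n_perm = 999, seed = NULL) {
  if (n_perm < 100) ft_usage_error("n_perm must be at least 100")
  df <- if (inherits(pairs, "pair_set")) pairs$pairs else pairs
  if (nrow(df) < 3) ft_error("need at least 3 pairs",
                             "ft_insufficient_pairs_error")
  if (!is.null(seed)) set.seed(seed)
  obs <- spearman_rho(df$t_a, df$t_b)
  nulls <- vapply(seq_len(n_perm), function(i)
    spearman_rho(df$t_a, sample(df$t_b)), 0)
  p <- (1 + sum(abs(nulls) >= abs(obs) - 1e-12)) / (n_perm + 1)
  structure(list(observed_rho = obs, null_rhos = nulls, empirical_p = p,
                 n_perm = n_perm, seed = seed),
            class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("observed rho = %.3f, empirical P = %.4f (%d permutations)\n",
              x$observed_rho, x$empirical_p, x$n_perm))
  invisible(x)
}

# per-daughter classification table used by category_fractions / inheritance
daughter_categories <- function(trees, thresholds) {
  rows <- lapply(trees, function(tree) {
    n <- tree$nodes
    d <- n[n$depth > 0, , drop = FALSE]
    if (nrow(d) == 0) return(NULL)
    span <- d$end_time - d$birth_time
    divided <- d$fate == "DIVIDED"
    cat <- classify_division_speed(span, thresholds, divided = divided)
    cat[d$fate == "DIED"] <- "UNCALLABLE"
    data.frame(tree_id = tree$tree_id, cell_id = d$cell_id,
               parent_id = d$parent_id, depth = d$depth,
               generation_abs = d$generation_offset + d$depth,
               generation_offset = d$generation_offset,
               span = span, divided = divided, category = cat,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0)
    return(data.frame(tree_id = character(0), cell_id = character(0),
                      parent_id = character(0), depth = integer(0),
                      generation_abs = integer(0), generation_offset = integer(0),
                      span = numeric(0), divided = logical(0),
                      category = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Division-speed category fractions per sorted generation
#'
#' Classifies every non-founder cell by [classify_division_speed()] and
#' tabulates fractions per sorted generation. `INTERMEDIATE` (the 800--1000
#' min gap the published categories leave open) and `UNCALLABLE` (censored
#' too early to call) are reported separately, never merged.
#'
#' @param trees list of QC-included `lineage_tree` objects.
#' @param thresholds a [speed_thresholds()].
#' @return data.frame with `generation_offset`, `n` and one fraction column
#'   per category (`FAST`, `MEDIUM`, `INTERMEDIATE`, `SLOW`, `NO_DIVISION`,
#'   `UNCALLABLE`); fractions sum to 1 per row.
#' @export
category_fractions <- function(trees, thresholds = speed_thresholds()) {
  dc <- daughter_categories(trees, thresholds)
  cats <- c("FAST", "MEDIUM", "INTERMEDIATE", "SLOW", "NO_DIVISION", "UNCALLABLE")
  if (nrow(dc) == 0) {
    out <- data.frame(generation_offset = integer(0), n = integer(0))
    for (c_ in cats) out[[c_]] <- numeric(0)
    return(out)
  }
  gens <- sort(unique(dc$generation_offset))
  out <- do.call(rbind, lapply(gens, function(g) {
    sel <- dc$generation_offset == g
    row <- data.frame(generation_offset = g, n = sum(sel))
    for (c_ in cats) row[[c_]] <- mean(dc$category[sel] == c_)
    row
  }))
  rownames(out) <- NULL
  out
}

#' Mother-to-daughter division-speed inheritance table
#'
#' Counts daughter speed categories conditioned on the mother's category
#' (mothers: `FAST`/`MEDIUM`/`SLOW`; daughters additionally `NO_DIVISION`;
#' `INTERMEDIATE` cells are tabulated in side columns and excluded from the
#' test, as are `UNCALLABLE` daughters). Mothers must have completely
#' observed cycles; daughters must have divided or been observed undivided
#' for longer than `no_division_min`.
#'
#' The chi-square test of independence (no continuity correction) assumes
#' independent observations, but dyads within one tree are clustered by
#' construction (sibling daughters share a division shock and all members
#' share family effects), which makes the all-dyad test anticonservative.
#' The default `dedupe = "tree"` therefore draws one random dyad per tree for
#' the test while `counts` still reports every dyad; `"division"` keeps one
#' daughter per mother; `"none"` tests all dyads (anticonservative, for
#' comparison).
#'
#' @param trees list of QC-included `lineage_tree` objects.
#' @param thresholds a [speed_thresholds()].
#' @param dedupe dyad subsampling policy for the test (see Details).
#' @param seed seed for the dedupe draw.
#' @param mother_depth depth(s) of eligible mothers; the default `1` mirrors
#'   the tracking protocol, which measures two division rounds after the
#'   first observed cytokinesis (mothers M1/M2 at depth 1, daughters D1--D4
#'   at depth 2). `NULL` admits mothers at any depth.
#' @return object of class `inheritance_table`: list with `counts` (all
#'   dyads, full category set), `tested_counts` (deduped, test categories),
#'   `row_fractions`, `chi2`, `df`, `p_value`, `n_dyads`, `n_tested`,
#'   `low_expected` (warning flag: some expected count < 5), `dedupe`.
#' @export
inheritance_table <- function(trees, thresholds = speed_thresholds(),
                              dedupe = c("tree", "division", "none"),
                              seed = NULL, mother_depth = 1L) {
  dedupe <- match.arg(dedupe)
  if (!is.null(seed)) set.seed(seed)
  dc <- daughter_categories(trees, thresholds)
  # mother categories: cells with complete cycles that have classified daughters
  by_tree <- split(dc, dc$tree_id)
  dyads <- list()
  for (tree in trees) {
    d <- by_tree[[tree$tree_id]]
    if (is.null(d)) next
    n <- tree$nodes
    moms <- n[n$fate == "DIVIDED" & n$depth > 0 &
                (is.null(mother_depth) | n$depth %in% mother_depth), , drop = FALSE]
    if (nrow(moms) == 0) next
    mcat <- classify_division_speed(moms$cycle_time, thresholds, divided = TRUE)
    for (i in seq_len(nrow(moms))) {
      kd <- d[!is.na(d$parent_id) & d$parent_id == moms$cell_id[i], , drop = FALSE]
      if (nrow(kd) == 0) next
      dyads[[length(dyads) + 1]] <- data.frame(
        tree_id = tree$tree_id, mother = moms$cell_id[i],
        mother_cat = mcat[i], daughter = kd$cell_id,
        daughter_cat = kd$category, stringsAsFactors = FALSE)
    }
  }
  if (length(dyads) == 0) ft_error("no mother-daughter dyads available",
                                   "ft_degenerate_error")
  dy <- do.call(rbind, dyads)
  dy <- dy[dy$daughter_cat != "UNCALLABLE", , drop = FALSE]

  mother_lv <- c("FAST", "MEDIUM", "INTERMEDIATE", "SLOW")
  daughter_lv <- c("FAST", "MEDIUM", "INTERMEDIATE", "SLOW", "NO_DIVISION")
  counts <- table(factor(dy$mother_cat, mother_lv),
                  factor(dy$daughter_cat, daughter_lv))
  names(dimnames(counts)) <- c("mother", "daughter")

  # test set: drop INTERMEDIATE on both margins, dedupe clustered dyads
  tdy <- dy[dy$mother_cat != "INTERMEDIATE" & dy$daughter_cat != "INTERMEDIATE", ,
            drop = FALSE]
  if (nrow(tdy) > 0 && dedupe == "tree") {
    keep <- vapply(split(seq_len(nrow(tdy)), tdy$tree_id),
                   function(ix) if (length(ix) == 1) ix else sample(ix, 1), 0L)
    tdy <- tdy[keep, , drop = FALSE]
  } else if (nrow(tdy) > 0 && dedupe == "division") {
    keep <- vapply(split(seq_len(nrow(tdy)), paste(tdy$tree_id, tdy$mother)),
                   function(ix) if (length(ix) == 1) ix else sample(ix, 1), 0L)
    tdy <- tdy[keep, , drop = FALSE]
  }
  tc <- table(factor(tdy$mother_cat, c("FAST", "MEDIUM", "SLOW")),
              factor(tdy$daughter_cat, c("FAST", "MEDIUM", "SLOW", "NO_DIVISION")))
  tc <- tc[rowSums(tc) > 0, colSums(tc) > 0, drop = FALSE]
  if (nrow(tc) < 2)
    ft_error("fewer than 2 non-empty mother categories: degenerate table",
             "ft_degenerate_error")
  if (ncol(tc) < 2)
    ft_error("fewer than 2 non-empty daughter categories: degenerate table",
             "ft_degenerate_error")
  ct <- suppressWarnings(stats::chisq.test(tc, correct = FALSE))

  rf <- prop.table(counts, 1)
  structure(list(counts = counts, tested_counts = tc, row_fractions = rf,
                 chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = ct$p.value, n_dyads = nrow(dy), n_tested = nrow(tdy),
                 low_expected = any(ct$expected < 5), dedupe = dedupe),
            class = "inheritance_table")
}

#' @export
print.inheritance_table <- function(x, ...) {
  cat(sprintf("<inheritance_table> %d dyads (%d tested, dedupe=%s): chi2 = %.2f, df = %d, P = %.3g%s\n",
              x$n_dyads, x$n_tested, x$dedupe, x$chi2, x$df, x$p_value,
              if (x$low_expected) " [low expected counts]" else ""))
  print(x$counts)
  invisible(x)
}

#' Division synchrony in a two-colour mixed cohort
#'
#' Emulates the co-culture of two differentially labelled populations: the
#' fraction of same-label sibling pairs dividing within a synchrony window is
#' contrasted with cross-label pairs (rank-order matched non-relatives), and
#' the cross-label pairs' Spearman correlation is reported (expected null).
#'
#' @param trees_a,trees_b lists of `lineage_tree` from two independent
#'   simulations (the two colours).
#' @param window synchrony window, minutes.
#' @return list with `sibling_synchrony`, `cross_synchrony` (fractions of
#'   pairs with division-time difference within `window`),
#'   `n_sibling_pairs`, `n_cross_pairs` and `cross_correlation`
#'   (a `correlation_result`).
#' @export
synchrony_metrics <- function(trees_a, trees_b, window = 60) {
  if (missing(trees_b) || length(trees_b) == 0 || length(trees_a) == 0)
    ft_usage_error("synchrony_metrics needs two labelled populations")
  # same-label sibling synchrony: co-daughters are born together, so the
  # division-time gap equals the cycle-time gap
  division_times <- function(tree) {
    n <- tree$nodes
    n$end_time[n$fate == "DIVIDED" & n$depth > 0]
  }
  sib <- rbind(kinship_pairs(trees_a, "SIBLING")$pairs,
               kinship_pairs(trees_b, "SIBLING")$pairs)
  # cross-label: tree k of colour A against tree k of colour B ("co-cultured
  # well"); each division in A matched to the nearest division in B
  m <- min(length(trees_a), length(trees_b))
  gaps <- numeric(0)
  for (k in seq_len(m)) {
    da <- division_times(trees_a[[k]]); db <- division_times(trees_b[[k]])
    if (length(da) == 0 || length(db) == 0) next
    gaps <- c(gaps, vapply(da, function(t) min(abs(t - db)), 0))
  }
  # cross-label cycle-time pairs for the null correlation
  inter <- vector("list", 2 * m)
  inter[seq(1, 2 * m, 2)] <- trees_a[1:m]
  inter[seq(2, 2 * m, 2)] <- trees_b[1:m]
  cross <- kinship_pairs(inter, "NON_RELATIVE")$pairs
  if (nrow(sib) == 0 || length(gaps) == 0)
    ft_error("not enough pairs for synchrony metrics", "ft_insufficient_pairs_error")
  list(
    sibling_synchrony = mean(abs(sib$t_a - sib$t_b) <= window),
    cross_synchrony = mean(gaps <= window),
    n_sibling_pairs = nrow(sib),
    n_cross_pairs = length(gaps),
    cross_correlation = spearman_cor(cross)
  )
}
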