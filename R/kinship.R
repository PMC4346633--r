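#' Extract kinship-classified cycle-time pairs from division trees
#'
#' Builds the pair sets whose correlations carry the heritability analysis:
#'
#' * `SIBLING` -- the two co-daughters of one division, each unordered pair
#'   counted once;
#' * `MOTHER_DAUGHTER` -- every (parent, child) dyad with both cycles fully
#'   observed, ordered mother-first;
#' * `COUSIN` -- every cross pair between the daughter sets of two sibling
#'   mothers (4 per complete quartet);
#' * `NON_RELATIVE` -- pairs drawn across different trees (the two-colour
#'   co-culture control): trees are taken in consecutive disjoint pairs, cells
#'   of each tree ordered by (depth, kinship label) and matched by rank, giving
#'   `min(n1, n2)` pairs per tree pair.
#'
#' Founders never contribute a cycle time (their start is unobserved); pairs
#' with any `CENSORED`/`DIED` member are dropped.
#'
#' @param trees list of QC-included `lineage_tree` objects.
#' @param relation one of `"SIBLING"`, `"MOTHER_DAUGHTER"`, `"COUSIN"`,
#'   `"NON_RELATIVE"`.
#' @param include_founder treat a divided founder's span as a complete cycle?
#'   Default `FALSE`: a founder's birth is the start of imaging, not a
#'   division, so its cycle time is unknowable in real tracks. `TRUE` is only
#'   meaningful for idealized or simulated trees.
#' @return object of class `pair_set`: list with `relation`, `pairs`
#'   (data.frame `cell_a`, `cell_b`, `t_a`, `t_b`, minutes) and `n_pairs`.
#' @examples
#' trees <- list(build_tree(quartet_records(daughters_divide = TRUE)))
#' kinship_pairs(trees, "SIBLING")$n_pairs   # {M1,M2},{D1,D2},{D3,D4}
#' kinship_pairs(trees, "COUSIN")$n_pairs    # 4 cross pairs
#' @export
kinship_pairs <- function(trees, relation, include_founder = FALSE) {
  if (inherits(trees, "lineage_tree")) trees <- list(trees)
  if (!is.character(relation) || length(relation) != 1 ||
      !relation %in% c("SIBLING", "MOTHER_DAUGHTER", "COUSIN", "NON_RELATIVE"))
    ft_usage_error("relation must be one of SIBLING, MOTHER_DAUGHTER, COUSIN, NON_RELATIVE")

  rows <- list()
  add <- function(a, b, ta, tb) {
    rows[[length(rows) + 1]] <<- data.frame(
      cell_a = a, cell_b = b, t_a = ta, t_b = tb, stringsAsFactors = FALSE)
  }

  # cells with completely observed cycles (non-founder unless include_founder)
  complete <- function(tree) {
    n <- tree$nodes
    n[n$fate == "DIVIDED" & (n$depth > 0 | include_founder), , drop = FALSE]
  }

  if (relation == "NON_RELATIVE") {
    usable <- Filter(function(t) nrow(complete(t)) > 0, trees)
    if (length(usable) >= 2) {
      for (k in seq(1, length(usable) - 1, by = 2)) {
        a <- complete(usable[[k]]); b <- complete(usable[[k + 1]])
        a <- a[order(a$depth, a$kinship_label, a$cell_id), ]
        b <- b[order(b$depth, b$kinship_label, b$cell_id), ]
        m <- min(nrow(a), nrow(b))
        for (i in seq_len(m))
          add(a$cell_id[i], b$cell_id[i], a$cycle_time[i], b$cycle_time[i])
      }
    }
  } else {
    for (tree in trees) {
      n <- tree$nodes
      ok <- n$fate == "DIVIDED" & (n$depth > 0 | include_founder)
      # cycle_time is populated for the founder too; usable only when the
      # founder's span is declared a true cycle
      idx <- seq_len(nrow(n))
      kids_of <- split(idx[!is.na(n$parent_id)], n$parent_id[!is.na(n$parent_id)])
      if (relation == "SIBLING") {
        for (kids in kids_of) {
          if (length(kids) == 2 && all(ok[kids]))
            add(n$cell_id[kids[1]], n$cell_id[kids[2]],
                n$cycle_time[kids[1]], n$cycle_time[kids[2]])
        }
      } else if (relation == "MOTHER_DAUGHTER") {
        for (i in idx) {
          if (!ok[i]) next
          for (k in kids_of[[n$cell_id[i]]] %||% integer(0))
            if (ok[k]) add(n$cell_id[i], n$cell_id[k], n$cycle_time[i], n$cycle_time[k])
        }
      } else { # COUSIN: cross pairs between daughter sets of two sibling mothers
        for (kids in kids_of) {
          if (length(kids) != 2) next
          da <- kids_of[[n$cell_id[kids[1]]]] %||% integer(0)
          db <- kids_of[[n$cell_id[kids[2]]]] %||% integer(0)
          for (i in da) for (j in db)
            if (ok[i] && ok[j])
              add(n$cell_id[i], n$cell_id[j], n$cycle_time[i], n$cycle_time[j])
        }
      }
    }
  }

  pairs <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(cell_a = character(0), cell_b = character(0),
               t_a = numeric(0), t_b = numeric(0), stringsAsFactors = FALSE)
  structure(list(relation = relation, pairs = pairs, n_pairs = nrow(pairs)),
            class = "pair_set")
}

#' @export
print.pair_set <- function(x, ...) {
  cat(sprintf("<pair_set %s> %d pairs\n", x$relation, x$n_pairs))
  invisible(x)
}
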