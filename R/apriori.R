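# Apriori frequent-itemset mining.
#
# Level k is a list(sets = list of strictly-increasing integer id vectors,
# counts = integer vector), rows in lexicographic order of the id
# sequences. An itemset is "large" (frequent) when count / N >= min_support.

# order a list of id vectors lexicographically; returns permutation
.lex_order <- function(sets) {
  if (length(sets) == 0) return(integer(0))
  k <- length(sets[[1]])
  m <- do.call(rbind, sets)
  do.call(order, lapply(seq_len(k), function(j) m[, j]))
}

.level <- function(sets, counts) {
  o <- .lex_order(sets)
  list(sets = sets[o], counts = as.integer(counts[o]))
}

# frequency cutoff in counts; >= comparison with fp guard
.support_count <- function(N, min_support) N * min_support - 1e-9

#' First Apriori pass: large 1-itemsets
#'
#' Counts every item's occurrences across the database and retains those
#' whose support (count / N) reaches `min_support`.
#'
#' @param db a [transaction_db()].
#' @param min_support minimum support as a fraction in (0, 1].
#' @return a `large_itemsets` object with level 1 only: fields `levels`
#'   (list indexed by k), `min_support`, `N`, `items` (vocabulary).
#' @examples
#' db <- transaction_db(list(c("a", "b"), c("a", "c"), "a", c("a", "b"), "b"))
#' first_pass(db, 0.4)
#' @export
first_pass <- function(db, min_support) {
  stopifnot(inherits(db, "transaction_db"))
  if (!(min_support > 0 && min_support <= 1)) {
    stop("min_support must lie in (0, 1]")
  }
  counts <- integer(db$m)
  for (t in db$transactions) counts[t] <- counts[t] + 1L
  keep <- which(counts >= .support_count(db$N, min_support))
  lev1 <- .level(lapply(keep, identity), counts[keep])
  structure(
    list(levels = list(`1` = lev1), min_support = min_support,
         N = db$N, items = db$items),
    class = "large_itemsets"
  )
}

#' @export
print.large_itemsets <- function(x, ...) {
  sizes <- vapply(x$levels, function(l) length(l$sets), integer(1))
  cat("large_itemsets: min_support ", x$min_support, ", N ", x$N, "\n", sep = "")
  for (k in seq_along(sizes)) {
    cat("  level ", k, ": ", sizes[k], " itemset(s)\n", sep = "")
  }
  invisible(x)
}

#' Candidate generation (apriori-gen)
#'
#' Joins pairs of large (k-1)-itemsets that agree on their first k-2 items,
#' then prunes every candidate having a (k-1)-subset that is not large.
#' Returns a duplicate-free superset of the large k-itemsets.
#'
#' @param L_prev a level as stored in a `large_itemsets` object (list with
#'   `sets`), holding the large (k-1)-itemsets in lexicographic order.
#' @return list of candidate k-itemsets (strictly increasing id vectors) in
#'   lexicographic order; empty list when no candidate survives.
#' @examples
#' L3 <- list(sets = list(c(1L,2L,3L), c(1L,2L,4L), c(1L,3L,4L), c(2L,3L,4L)))
#' apriori_gen(L3) # the single candidate {1,2,3,4}
#' @export
apriori_gen <- function(L_prev) {
  sets <- L_prev$sets
  if (length(sets) == 0) return(list())
  k1 <- length(sets[[1]])
  if (k1 == 0) stop("level-1 itemsets are produced by first_pass, not apriori_gen")

  prev_keys <- vapply(sets, .iset_key, character(1))
  prefix <- vapply(sets, function(s) .iset_key(s[-k1]), character(1))
  cand <- list()
  for (grp in split(seq_along(sets), prefix)) {
    if (length(grp) < 2) next
    for (a in seq_len(length(grp) - 1L)) {
      for (b in seq(a + 1L, length(grp))) {
        p <- sets[[grp[a]]]
        q <- sets[[grp[b]]]
        # grp is in lexicographic order, so p[k1] < q[k1]
        cand[[length(cand) + 1L]] <- c(p, q[k1])
      }
    }
  }
  if (length(cand) == 0) return(list())
  # prune: every (k-1)-subset must be large
  ok <- vapply(cand, function(c_set) {
    all(vapply(seq_along(c_set),
      function(i) .iset_key(c_set[-i]) %in% prev_keys, logical(1)))
  }, logical(1))
  cand <- cand[ok]
  cand[.lex_order(cand)]
}

#' Mine all large itemsets with the Apriori algorithm
#'
#' Runs the first pass, then iterates candidate generation
#' ([apriori_gen()]), hash-tree counting ([build_hash_tree()] /
#' [count_subsets()]) and support filtering until a level is empty.
#' Transactions shorter than the current level are skipped (they cannot
#' contain a k-subset). Counts are exact and order-invariant.
#'
#' @inheritParams first_pass
#' @param hash_branches hash-tree branching constant `T` (routing by
#'   `item_id mod T`); must be at least 2.
#' @param max_leaf_size leaf capacity before a split.
#' @return a `large_itemsets` object with levels 1..K, K the last
#'   non-empty level. Mined sets and counts are independent of
#'   `hash_branches` and `max_leaf_size`.
#' @examples
#' db <- transaction_db(list(c("a", "b", "c"), c("a", "b"), c("a", "c")))
#' mine_frequent(db, min_support = 0.5)
#' @export
mine_frequent <- function(db, min_support, hash_branches = 3L, max_leaf_size = 8L) {
  L <- first_pass(db, min_support)
  cutoff <- .support_count(db$N, min_support)
  k <- 2L
  repeat {
    prev <- L$levels[[as.character(k - 1L)]]
    if (is.null(prev) || length(prev$sets) == 0) break
    cand <- apriori_gen(prev)
    if (length(cand) == 0) break
    tree <- build_hash_tree(cand, hash_branches, max_leaf_size)
    for (t in db$transactions) {
      if (length(t) >= k) count_subsets(tree, t)
    }
    counted <- hash_tree_counts(tree)
    keep <- counted$counts >= cutoff
    if (!any(keep)) break
    L$levels[[as.character(k)]] <- .level(counted$sets[keep], counted$counts[keep])
    k <- k + 1L
  }
  L
}

#' Look up the exact count of a mined itemset
#'
#' Every subset of a large itemset is itself large (anti-monotonicity), so
#' rule bodies and heads can always be counted from the mined table.
#'
#' @param L a `large_itemsets` object.
#' @param ids strictly increasing integer item-id vector.
#' @return integer count, or `NA` if the itemset was not mined.
#' @export
itemset_count <- function(L, ids) {
  lev <- L$levels[[as.character(length(ids))]]
  if (is.null(lev)) return(NA_integer_)
  key <- .iset_key(ids)
  hit <- match(key, vapply(lev$sets, .iset_key, character(1)))
  if (is.na(hit)) NA_integer_ else lev$counts[hit]
}
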