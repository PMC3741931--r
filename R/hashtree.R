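# Hash tree for candidate counting.
#
# Interior nodes route on hash(i) = i mod T of the item at the node's
# depth; leaves hold candidate itemsets and their counters. Nodes are
# environments so counters update in place while streaming transactions.

.ht_new_node <- function(depth, tree) {
  node <- new.env(parent = emptyenv())
  node$leaf <- TRUE
  node$depth <- depth          # which item position routes below this node
  node$sets <- list()
  node$counts <- integer(0)
  node$children <- NULL
  node$id <- tree$next_id
  tree$next_id <- tree$next_id + 1L
  tree$leaves[[as.character(node$id)]] <- node
  node
}

.ht_insert <- function(node, set, tree) {
  if (node$leaf) {
    node$sets[[length(node$sets) + 1L]] <- set
    node$counts <- c(node$counts, 0L)
    # split an over-full leaf while routing items remain
    if (length(node$sets) > tree$max_leaf_size && node$depth <= length(set)) {
      sets <- node$sets
      node$leaf <- FALSE
      node$sets <- list()
      node$counts <- integer(0)
      node$children <- vector("list", tree$branches)
      rm(list = as.character(node$id), envir = tree$leaves)
      for (s in sets) .ht_insert(node, s, tree)
    }
    return(invisible(NULL))
  }
  b <- (set[node$depth] %% tree$branches) + 1L
  if (is.null(node$children[[b]])) {
    node$children[[b]] <- .ht_new_node(node$depth + 1L, tree)
  }
  .ht_insert(node$children[[b]], set, tree)
}

#' Build a hash tree over a candidate set
#'
#' Candidates are inserted by routing on `item_id mod T` at successive
#' depths; a leaf exceeding `max_leaf_size` splits on the next item
#' position, unless all `k` positions are exhausted (deep leaves may then
#' hold more than `max_leaf_size` candidates).
#'
#' @param candidates list of strictly increasing integer item-id vectors,
#'   all of the same size `k` (as returned by [apriori_gen()]).
#' @param branches the branching constant `T` (>= 2); routing uses
#'   `item_id mod T`.
#' @param max_leaf_size leaf capacity before a split.
#' @return object of class `hash_tree`. Counters start at zero.
#' @examples
#' tr <- build_hash_tree(list(c(1L, 4L)), branches = 3)
#' count_subsets(tr, c(1L, 2L, 4L))
#' hash_tree_counts(tr)
#' @export
build_hash_tree <- function(candidates, branches = 3L, max_leaf_size = 8L) {
  branches <- as.integer(branches)
  if (is.na(branches) || branches < 2L) stop("hash-tree branching constant must be >= 2")
  if (max_leaf_size < 1L) stop("max_leaf_size must be >= 1")
  tree <- new.env(parent = emptyenv())
  tree$branches <- branches
  tree$max_leaf_size <- as.integer(max_leaf_size)
  tree$leaves <- new.env(parent = emptyenv())
  tree$next_id <- 1L
  tree$root <- .ht_new_node(1L, tree)
  for (s in candidates) .ht_insert(tree$root, s, tree)
  class(tree) <- "hash_tree"
  tree
}

# collect the distinct leaves reachable from `node` by hashing successive
# items of t (the recursive subset function); visited is an env keyed by
# leaf id so that a leaf reached along several item choices is processed
# once per transaction
.ht_reach <- function(node, t, from, tree, visited) {
  if (node$leaf) {
    visited[[as.character(node$id)]] <- node
    return(invisible(NULL))
  }
  if (from > length(t)) return(invisible(NULL))
  for (j in seq(from, length(t))) {
    b <- (t[j] %% tree$branches) + 1L
    child <- node$children[[b]]
    if (!is.null(child)) .ht_reach(child, t, j + 1L, tree, visited)
  }
  invisible(NULL)
}

#' Count a transaction's candidate subsets
#'
#' Traverses the tree with each item of `t` as a possible next routing
#' item; at every reached leaf, each candidate contained in `t` has its
#' counter incremented by one. Counters of candidates not contained in `t`
#' are untouched; an empty transaction is a no-op.
#'
#' @param tree a [build_hash_tree()] result (modified in place).
#' @param t transaction as a strictly increasing integer item-id vector.
#' @return the tree, invisibly.
#' @export
count_subsets <- function(tree, t) {
  if (length(t) == 0) return(invisible(tree))
  visited <- new.env(parent = emptyenv())
  .ht_reach(tree$root, t, 1L, tree, visited)
  for (leaf in as.list(visited)) {
    if (length(leaf$sets) == 0) next
    hit <- vapply(leaf$sets, function(s) all(s %in% t), logical(1))
    leaf$counts <- leaf$counts + as.integer(hit)
  }
  invisible(tree)
}

#' Extract candidates and counters from a hash tree
#'
#' @param tree a `hash_tree`.
#' @return list with `sets` (list of id vectors) and `counts` (integer),
#'   in lexicographic itemset order.
#' @export
hash_tree_counts <- function(tree) {
  leaves <- as.list(tree$leaves)
  sets <- list()
  counts <- integer(0)
  for (leaf in leaves) {
    sets <- c(sets, leaf$sets)
    counts <- c(counts, leaf$counts)
  }
  o <- .lex_order(sets)
  list(sets = sets[o], counts = counts[o])
}
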