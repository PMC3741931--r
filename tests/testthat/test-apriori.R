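# Apriori engine: first pass, candidate generation, hash tree, full mining.

test_that("first pass keeps exactly the items at or above minimum support", {
  db <- transaction_db(list(
    c("a", "b"), c("a", "c"), c("a", "b"), "a", "b"
  ))
  # a in 4, b in 3, c in 1 of 5 transactions
  L <- first_pass(db, 0.4)
  lev1 <- L$levels[["1"]]
  got <- setNames(lev1$counts, db$items[unlist(lev1$sets)])
  expect_equal(got, c(a = 4L, b = 3L))

  expect_equal(length(first_pass(transaction_db(list()), 0.5)$levels[["1"]]$sets), 0)
  expect_error(first_pass(db, 0), "min_support")
  expect_error(first_pass(db, 1.1), "min_support")
})

test_that("apriori-gen joins on shared prefixes and prunes infrequent subsets", {
  # L3 = {ABC, ABD, ACD, BCD} joins to the single candidate ABCD
  L3 <- list(sets = list(c(1L, 2L, 3L), c(1L, 2L, 4L), c(1L, 3L, 4L), c(2L, 3L, 4L)))
  expect_equal(apriori_gen(L3), list(c(1L, 2L, 3L, 4L)))

  # a single 1-itemset has nothing to join
  expect_equal(apriori_gen(list(sets = list(5L))), list())

  # AB, AC join to ABC but BC is absent, so the candidate is pruned
  L2 <- list(sets = list(c(1L, 2L), c(1L, 3L), c(2L, 4L)))
  expect_equal(apriori_gen(L2), list())

  expect_error(apriori_gen(list(sets = list(integer(0)))), "first_pass")
})

test_that("candidates in a hash tree are reachable by their own items", {
  # single candidate {1,4} with T = 3: both items hash to bucket 1
  tr <- build_hash_tree(list(c(1L, 4L)), branches = 3, max_leaf_size = 8)
  count_subsets(tr, c(1L, 4L))
  got <- hash_tree_counts(tr)
  expect_equal(got$sets, list(c(1L, 4L)))
  expect_equal(got$counts, 1L)

  # empty candidate set: a single empty leaf, counting is a no-op
  tr0 <- build_hash_tree(list(), branches = 3)
  count_subsets(tr0, c(1L, 2L))
  expect_equal(hash_tree_counts(tr0)$sets, list())

  # random 3-item candidates with forced splits remain reachable
  set.seed(42)
  cands <- unique(lapply(1:10, function(i) sort(sample(1:9, 3))))
  tr3 <- build_hash_tree(cands, branches = 3, max_leaf_size = 2)
  for (cand in cands) {
    count_subsets(tr3, cand)
  }
  got3 <- hash_tree_counts(tr3)
  for (cand in cands) {
    i <- which(vapply(got3$sets, identical, logical(1), as.integer(cand)))
    expect_length(i, 1)
    # counted once per transaction equal to it, plus once per superset-free
    # other candidate containing it (none here: all candidates are size 3)
    expect_equal(got3$counts[i], sum(vapply(cands, function(x)
      all(cand %in% x), logical(1))))
  }

  expect_error(build_hash_tree(list(), branches = 1), ">= 2")
})

test_that("subset counting updates exactly the contained candidates once", {
  # C2 = {AB, AC, BC, BD} against t = {A,B,C}
  cands <- list(c(1L, 2L), c(1L, 3L), c(2L, 3L), c(2L, 4L))
  for (branches in c(2L, 3L, 5L)) {
    tr <- build_hash_tree(cands, branches = branches, max_leaf_size = 1)
    count_subsets(tr, c(1L, 2L, 3L))
    got <- hash_tree_counts(tr)
    expect_equal(got$sets, cands)
    expect_equal(got$counts, c(1L, 1L, 1L, 0L))
    # empty transaction changes nothing
    count_subsets(tr, integer(0))
    expect_equal(hash_tree_counts(tr)$counts, c(1L, 1L, 1L, 0L))
  }
})

test_that("mining equals exhaustive enumeration on 100 seeded random databases", {
  for (seed in 1:100) {
    db <- random_db(seed, n_trans = sample(5:25, 1), n_items = sample(3:8, 1))
    L <- mine_frequent(db, 0.2)
    expect_identical(mined_as_keyed(L), oracle_frequent(db, 0.2),
      info = paste("seed", seed))
  }
})

test_that("mined counts respect anti-monotonicity", {
  db <- random_db(2024, n_trans = 25, n_items = 8, p = 0.5)
  L <- mine_frequent(db, 0.15)
  keyed <- mined_as_keyed(L)
  for (k in seq_along(L$levels)[-1]) {
    lev <- L$levels[[as.character(k)]]
    for (i in seq_along(lev$sets)) {
      s <- lev$sets[[i]]
      for (drop in seq_along(s)) {
        sub <- keyed[[paste(s[-drop], collapse = " ")]]
        expect_false(is.null(sub))
        expect_gte(sub, lev$counts[i])
      }
    }
  }
})

test_that("results are invariant to hash-tree parameters and transaction order", {
  db <- random_db(7, n_trans = 30, n_items = 7, p = 0.45)
  ref <- mined_as_keyed(mine_frequent(db, 0.2))
  for (branches in c(2L, 3L, 5L)) {
    for (leaf in c(1L, 4L, 16L)) {
      got <- mined_as_keyed(mine_frequent(db, 0.2, branches, leaf))
      expect_identical(got, ref, info = paste("T", branches, "leaf", leaf))
    }
  }
  db_rev <- db
  db_rev$transactions <- rev(db_rev$transactions)
  expect_identical(mined_as_keyed(mine_frequent(db_rev, 0.2)), ref)
})

test_that("mining at support 1.0 keeps only universal items; termination is clean", {
  db <- transaction_db(list(c("a", "b"), c("a", "c"), "a"))
  L <- mine_frequent(db, 1.0)
  expect_equal(length(L$levels), 1)
  expect_equal(db$items[unlist(L$levels[["1"]]$sets)], "a")
  expect_equal(L$levels[["1"]]$counts, 3L)
})

test_that("itemset_count looks up mined counts", {
  db <- random_db(5, n_trans = 20, n_items = 5, p = 0.6)
  L <- mine_frequent(db, 0.2)
  lev2 <- L$levels[["2"]]
  expect_equal(itemset_count(L, lev2$sets[[1]]), lev2$counts[1])
  expect_true(is.na(itemset_count(L, c(998L, 999L))))
})
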