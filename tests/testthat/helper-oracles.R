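# Independent oracles used across the suite. These deliberately avoid the
# package's mining code paths: counting is done by direct subset scans.

# every frequent itemset (and its exact count) by exhaustive enumeration
# over all 2^m - 1 non-empty vocabulary subsets
oracle_frequent <- function(db, min_support) {
  m <- db$m
  out <- list()
  if (m == 0) return(out)
  for (mask in seq_len(2^m - 1)) {
    ids <- which(bitwAnd(mask, 2^(seq_len(m) - 1)) > 0)
    cnt <- sum(vapply(db$transactions, function(t) all(ids %in% t), logical(1)))
    if (cnt >= db$N * min_support - 1e-9) {
      out[[paste(ids, collapse = " ")]] <- cnt
    }
  }
  out[order(names(out))]
}

# flatten a large_itemsets object into the same keyed form
mined_as_keyed <- function(L) {
  out <- list()
  for (lev in L$levels) {
    for (i in seq_along(lev$sets)) {
      out[[paste(lev$sets[[i]], collapse = " ")]] <- lev$counts[i]
    }
  }
  out[order(names(out))]
}

# direct count of transactions containing a set of item strings
oracle_count <- function(db, item_strings) {
  ids <- match(item_strings, db$items)
  stopifnot(!anyNA(ids))
  sum(vapply(db$transactions, function(t) all(ids %in% t), logical(1)))
}

# seeded random transaction database over items "i01".."iMM"
random_db <- function(seed, n_trans = 20, n_items = 6, p = 0.4) {
  set.seed(seed)
  items <- sprintf("i%02d", seq_len(n_items))
  tx <- lapply(seq_len(n_trans), function(i) items[stats::runif(n_items) < p])
  transaction_db(tx)
}

# a tiny raw-record data frame for cohort tests
make_records <- function(n = 3) {
  data.frame(
    patient_id = sprintf("P%02d", seq_len(n)),
    age = rep(c(45, 71, 28), length.out = n),
    primary_site = rep(c("Tongue", "Gum", "Lip"), length.out = n),
    laterality = rep(c(1, 2, 0), length.out = n),
    grade = rep(c(2, 1, 9), length.out = n),
    nodes_examined = rep(c(4, 7, 12), length.out = n),
    clinical_stage = rep(c(1, 4, 0), length.out = n),
    pathologic_stage = rep(c(2, 4, 1), length.out = n),
    clinical_tumor_size = rep(c(2.0, 4.5, 1.2), length.out = n),
    pathology_tumor_size = rep(c(2.5, 5.0, 1.0), length.out = n),
    treatment_sequence = rep(c("OP", "OP->IA", "OP->RT"), length.out = n),
    survival_months = rep(c(48, 20, 80), length.out = n),
    vital_status = rep(c("dead", "dead", "alive"), length.out = n),
    stringsAsFactors = FALSE
  )
}

expect_table2_rule <- function(report, body, head, confidence, lift, leverage, conviction) {
  i <- which(report$body == body & report$head == head)
  expect_length(i, 1)
  expect_equal(report$confidence_2dp[i], confidence)
  expect_equal(report$lift_2dp[i], lift)
  expect_equal(report$leverage_2dp[i], leverage)
  expect_equal(report$conviction_2dp[i], conviction)
}
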