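# Rule generation, interestingness metrics, ranking.

test_that("the worked metric example reproduces the printed values", {
  m <- rule_metrics(49, 78, 27, 271)
  expect_equal(round_half_up(m$confidence, 2), 0.55) # 27/49
  expect_equal(round_half_up(m$lift, 2), 1.91)
  expect_equal(round_half_up(m$leverage, 2), 0.05)
  expect_equal(round_half_up(m$conviction, 2), 1.52) # laplace default

  expect_equal(round_half_up(rule_metrics(55, 70, 27, 271)$conviction, 2), 1.41)
  # standard conviction for the same counts: 49 * 193 / (271 * 22)
  ms <- rule_metrics(49, 78, 27, 271, conviction_variant = "standard")
  expect_equal(round_half_up(ms$conviction, 3), round_half_up(49 * 193 / (271 * 22), 3))
})

test_that("independence gives lift 1 and leverage 0; degenerate bodies error", {
  m <- rule_metrics(10, 10, 5, 20)
  expect_equal(m$lift, 1)
  expect_equal(m$leverage, 0)
  expect_error(rule_metrics(0, 10, 0, 20), "n_body")
  expect_error(rule_metrics(10, 10, 12, 20), "inconsistent")
})

test_that("metric bounds hold across random rule counts", {
  set.seed(99)
  for (i in 1:200) {
    N <- sample(10:500, 1)
    n_body <- sample(1:N, 1)
    n_head <- sample(1:N, 1)
    # realizable joint counts obey inclusion-exclusion
    rng <- max(0, n_body + n_head - N):min(n_body, n_head)
    n_joint <- rng[sample.int(length(rng), 1)]
    m <- rule_metrics(n_body, n_head, n_joint, N)
    ms <- rule_metrics(n_body, n_head, n_joint, N, "standard")
    expect_gte(m$confidence, 0); expect_lte(m$confidence, 1)
    expect_gte(m$lift, 0)
    expect_gte(m$leverage, -0.25); expect_lte(m$leverage, 0.25)
    expect_lte(m$conviction, ms$conviction)
  }
})

test_that("exception-free rules have infinite standard but finite laplace conviction", {
  ms <- rule_metrics(20, 30, 20, 100, "standard")
  ml <- rule_metrics(20, 30, 20, 100, "laplace")
  expect_equal(ms$conviction, Inf)
  expect_equal(ml$conviction, 20 * 70 / (100 * 1))
})

test_that("free mode emits every ordered partition of each large itemset", {
  db <- transaction_db(lapply(1:10, function(i) c("w=1", "x=1", "y=1", "z=1")))
  L <- mine_frequent(db, 0.5)
  rules <- generate_rules(L, db)
  # one 4-itemset contributes 14 partitions, the four 3-subsets 6 each,
  # the six 2-subsets 2 each
  expect_equal(nrow(rules), 14 + 4 * 6 + 6 * 2)
  # degenerate db: every subset occurs in all transactions
  expect_true(all(rules$n_body == 10 & rules$n_head == 10 & rules$n_joint == 10))
  # a database whose only frequent itemsets are singletons yields no rules
  db1 <- transaction_db(list("a=1", "b=1", "a=1"))
  expect_equal(nrow(generate_rules(mine_frequent(db1, 0.6), db1)), 0)
})

test_that("rule counts agree with direct transaction scans on the fixture", {
  db <- build_table2_fixture()
  L <- mine_frequent(db, 0.09)
  rules <- generate_rules(L, db)
  for (i in seq_len(nrow(rules))) {
    body_items <- strsplit(rules$body[i], " & ", fixed = TRUE)[[1]]
    head_items <- strsplit(rules$head[i], " & ", fixed = TRUE)[[1]]
    expect_equal(rules$n_body[i], oracle_count(db, body_items))
    expect_equal(rules$n_head[i], oracle_count(db, head_items))
    expect_equal(rules$n_joint[i], oracle_count(db, c(body_items, head_items)))
    # metrics recomputed directly from the scanned counts
    m <- rule_metrics(rules$n_body[i], rules$n_head[i], rules$n_joint[i], db$N)
    expect_equal(rules$confidence[i], m$confidence)
    expect_equal(rules$lift[i], m$lift)
    expect_equal(rules$leverage[i], m$leverage)
  }
})

test_that("class-constrained mode restricts heads to the class attribute", {
  db <- build_table2_fixture()
  L <- mine_frequent(db, 0.09)
  rules <- generate_rules(L, db, head_mode = "class", class_attribute = "grade")
  expect_gt(nrow(rules), 0)
  expect_true(all(startsWith(rules$head, "grade=")))
  expect_true(all(!grepl(" & ", rules$head, fixed = TRUE)))
  expect_error(
    generate_rules(L, db, head_mode = "class", class_attribute = "nope"),
    "class attribute"
  )
})

test_that("lift and leverage are symmetric under body/head swap", {
  db <- build_table2_fixture()
  rules <- generate_rules(mine_frequent(db, 0.09), db)
  key <- paste(pmin(rules$body, rules$head), pmax(rules$body, rules$head))
  for (grp in split(seq_len(nrow(rules)), key)) {
    if (length(grp) == 2) {
      expect_identical(rules$lift[grp[1]], rules$lift[grp[2]])
      expect_equal(rules$leverage[grp[1]], rules$leverage[grp[2]])
    }
  }
})

test_that("every emitted rule's support reaches the mining support", {
  db <- random_db(31, n_trans = 40, n_items = 6, p = 0.5)
  rules <- generate_rules(mine_frequent(db, 0.25), db)
  expect_true(all(rules$support >= 0.25 - 1e-9))
})

test_that("ranking filters by lift, sorts with documented tie-breaks, truncates", {
  db <- build_table2_fixture()
  rules <- generate_rules(mine_frequent(db, 0.09), db)
  rep10 <- rank_rules(rules, "lift", min_lift = 1.5, top_k = 10)
  expect_equal(nrow(rep10), 10)
  expect_equal(rep10$lift_2dp,
    c(1.91, 1.91, 1.90, 1.90, 1.88, 1.88, 1.81, 1.81, 1.74, 1.74))
  expect_true(all(diff(rep10$lift) <= 1e-12))
  # within exact lift ties, confidence is non-increasing
  for (i in seq_len(nrow(rep10) - 1)) {
    if (rep10$lift[i] == rep10$lift[i + 1]) {
      expect_gte(rep10$confidence[i], rep10$confidence[i + 1])
    }
  }
  expect_true(all(rep10$lift > 1.5))
  # empty input is an empty report
  expect_equal(nrow(rank_rules(rules[0, ])), 0)
  # cap respected
  expect_equal(nrow(rank_rules(rules, top_k = 3)), 3)
})

test_that("reports serialize to tab-separated text with a metadata header", {
  db <- build_table2_fixture()
  rep10 <- rank_rules(generate_rules(mine_frequent(db, 0.09), db))
  f <- tempfile(fileext = ".tsv")
  write_rule_report(rep10, f, N = db$N)
  lines <- readLines(f)
  expect_true(startsWith(lines[1], "#"))
  expect_match(lines[1], "N=271")
  tab <- utils::read.delim(f, comment.char = "#")
  expect_equal(nrow(tab), 10)
  expect_equal(tab$lift[1], 1.91)
})

test_that("display rounding is half away from zero", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(-0.125, 2), -0.13)
  expect_equal(round_half_up(1.905, 2), 1.91)
})
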