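# Cohort ingestion, discretization, stratification and encoding.

test_that("stage codes 0-3 map to early and 4 to late; bad codes are fatal", {
  expect_equal(stage_group(c(0, 1, 2, 3)), rep("early", 4))
  expect_equal(stage_group(4), "late")
  expect_true(is.na(stage_group(NA)))
  expect_error(stage_group(5), "out of range")
})

test_that("discretization applies the documented bins and codes", {
  rec <- make_records(3)
  coh <- discretize(rec)
  expect_s3_class(coh, "cohort_table")
  expect_equal(coh$age_group, c("30~50", ">70", "<30"))
  expect_equal(coh$grade, c("02", "01", "09"))
  expect_equal(coh$nodes_group, c("<5", "5~10", ">10"))
  # boundary conventions: 2.0 cm is interior, 4.5 above; 50 stays in 30~50
  expect_equal(coh$clinical_size_group, c("2~4 cm", ">4 cm", "<2 cm"))
  expect_equal(discretize(transform(rec, age = c(50, 30, 70)))$age_group,
    c("30~50", "30~50", "50~70"))
  expect_equal(coh$clinical_stage_group, c("early", "late", "early"))
  expect_equal(coh$op_group, c("01", "02", "03"))
  expect_equal(coh$group, rep("OP", 3))
  expect_equal(coh$survived_gt36, c(TRUE, FALSE, TRUE))
  # five-year status: >= 60 months yes; died earlier no
  expect_equal(coh$five_year_survivor, c(FALSE, FALSE, TRUE))
})

test_that("discretization is total and deterministic; unmapped sequences flagged", {
  rec <- make_records(3)
  expect_identical(discretize(rec), discretize(rec))
  rec$treatment_sequence[2] <- "OP->XX"
  expect_message(coh <- discretize(rec), "unmapped treatment")
  expect_true(is.na(coh$op_group[2]))
  expect_false(anyNA(coh$op_group[-2]))
})

test_that("population filters subset by stratum and preserve order", {
  coh <- discretize(make_records(6))
  kept <- suppressMessages(filter_population(coh, "survived_gt36"))
  expect_equal(kept$patient_id, coh$patient_id[coh$survived_gt36])
  comp <- suppressMessages(filter_population(coh, "not_survived_gt36"))
  expect_equal(nrow(kept) + nrow(comp), nrow(coh))
  expect_equal(suppressMessages(filter_population(coh, "all")), coh)
  empty <- coh[0, ]
  expect_equal(nrow(suppressMessages(filter_population(empty, "survived_gt36"))), 0)
  expect_error(filter_population(coh, "bogus"))
})

test_that("transaction encoding builds attribute=value items with stable ids", {
  coh <- discretize(make_records(1))
  db <- encode_transactions(coh, c("grade", "group"))
  expect_equal(db$N, 1)
  expect_setequal(db$items[db$transactions[[1]]], c("grade=02", "group=OP"))
  # vocabulary ids follow lexicographic item order
  expect_equal(db$items, sort(db$items))
  # missing selected attribute drops the record, with a message
  coh2 <- discretize(make_records(3))
  coh2$primary_site[2] <- NA
  expect_message(
    db2 <- encode_transactions(coh2, c("primary_site", "grade")),
    "dropped"
  )
  expect_equal(db2$N, 2)
  expect_error(encode_transactions(coh, character(0)), "non-empty")
  expect_error(encode_transactions(coh, "nope"), "unknown attribute")
})

test_that("well-formed files read fully; malformed rows are excluded with a count", {
  f <- tempfile(fileext = ".csv")
  write_cohort(make_records(3), f)
  got <- read_cohort(f)
  expect_equal(nrow(got), 3)
  expect_equal(attr(got, "n_excluded"), 0)

  raw <- utils::read.csv(f, colClasses = "character", check.names = FALSE)
  raw$survival_months[2] <- "abc"
  utils::write.csv(raw, f, row.names = FALSE)
  expect_message(got2 <- read_cohort(f), "excluded")
  expect_equal(nrow(got2), 2)
  expect_equal(attr(got2, "n_excluded"), 1)

  expect_error(read_cohort(tempfile()), "not found")
})

test_that("a generated cohort round-trips through write and read", {
  rec <- generate_cohort(synthetic_config(), seed = 11)
  f <- tempfile(fileext = ".csv")
  write_cohort(rec, f)
  back <- read_cohort(f)
  attr(back, "n_excluded") <- NULL
  rownames(rec) <- NULL
  expect_equal(back, rec)
})

test_that("schema files map arbitrary column names", {
  rec <- make_records(2)
  names(rec) <- paste0("col_", names(rec))
  f <- tempfile(fileext = ".csv")
  utils::write.csv(rec, f, row.names = FALSE)
  sf <- tempfile()
  writeLines(c("# mapping", sprintf("%s = col_%s",
    c("patient_id", "age", "primary_site", "laterality", "grade",
      "nodes_examined", "clinical_stage", "pathologic_stage",
      "clinical_tumor_size", "pathology_tumor_size", "treatment_sequence",
      "survival_months", "vital_status"),
    c("patient_id", "age", "primary_site", "laterality", "grade",
      "nodes_examined", "clinical_stage", "pathologic_stage",
      "clinical_tumor_size", "pathology_tumor_size", "treatment_sequence",
      "survival_months", "vital_status"))), sf)
  got <- read_cohort(f, schema = read_schema(sf))
  expect_equal(nrow(got), 2)
  expect_equal(got$age, rec$col_age)
  expect_error(read_cohort(f), "lacks column")
})

test_that("category sums over any attribute equal cohort size minus missing", {
  coh <- discretize(generate_cohort(synthetic_config(), seed = 3))
  for (att in c("age_group", "grade", "clinical_stage_group", "op_group")) {
    tab <- table(coh[[att]], useNA = "no")
    expect_equal(sum(tab), nrow(coh) - sum(is.na(coh[[att]])))
  }
})
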