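# Univariate layer: attribute-by-outcome contingency tables, Pearson
# chi-square tests, and per-category survival percentages.

#' Cross-tabulate a clinical attribute against a survival outcome
#'
#' Records missing either variable are excluded (and the exclusion count
#' reported). Categories observed zero times do not appear as rows.
#'
#' @param cohort a `cohort_table` from [discretize()].
#' @param attribute name of a categorical cohort column.
#' @param outcome `"survived_gt36"` (columns `gt36` / `le36`) or
#'   `"five_year_survivor"` (columns `yes` / `no`).
#' @return object of class `contingency_table`: list with `table` (count
#'   matrix, attribute categories x outcome levels), `attribute`,
#'   `outcome`, `N` (retained records) and `n_excluded`.
#' @examples
#' coh <- discretize(generate_cohort(synthetic_config(n = 100), seed = 1))
#' contingency(coh, "grade")
#' @export
contingency <- function(cohort, attribute,
                        outcome = c("survived_gt36", "five_year_survivor")) {
  outcome <- match.arg(outcome)
  if (!attribute %in% names(cohort)) stop("unknown attribute: ", attribute)
  a <- as.character(cohort[[attribute]])
  o <- cohort[[outcome]]
  keep <- !is.na(a) & a != "" & !is.na(o)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    .msg(n_excluded, " record(s) excluded from ", attribute, " x ", outcome,
      " table for missing values")
  }
  lev <- if (outcome == "survived_gt36") c("gt36", "le36") else c("yes", "no")
  ocol <- factor(ifelse(o[keep], lev[1], lev[2]), levels = lev)
  tab <- table(factor(a[keep]), ocol)
  m <- matrix(as.integer(tab), nrow = nrow(tab),
    dimnames = list(rownames(tab), colnames(tab)))
  structure(
    list(table = m, attribute = attribute, outcome = outcome,
      N = sum(m), n_excluded = n_excluded),
    class = "contingency_table"
  )
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("contingency_table: ", x$attribute, " x ", x$outcome,
    " (N = ", x$N, ")\n", sep = "")
  print(x$table)
  invisible(x)
}

#' Pearson chi-square test of a contingency table
#'
#' Pearson's chi-square without continuity correction, with
#' `df = (rows - 1)(cols - 1)` after dropping all-zero rows and columns.
#' Degenerate tables (fewer than two non-empty rows or columns) return a
#' no-test result with `status = "degenerate"` rather than an error.
#' Expected cell counts below 5 trigger a warning only; no exact-test
#' fallback is applied.
#'
#' @param x a `contingency_table` or a count matrix.
#' @return list with `statistic`, `df`, `p_value`, `status` (`"ok"` or
#'   `"degenerate"`), and `min_expected`.
#' @examples
#' chi_square(matrix(c(238, 14, 19, 147, 13, 62), nrow = 3))
#' @export
chi_square <- function(x) {
  m <- if (inherits(x, "contingency_table")) x$table else as.matrix(x)
  m <- m[rowSums(m) > 0, , drop = FALSE]
  m <- m[, colSums(m) > 0, drop = FALSE]
  if (nrow(m) < 2 || ncol(m) < 2) {
    return(list(statistic = NA_real_, df = NA_integer_, p_value = NA_real_,
      status = "degenerate", min_expected = NA_real_))
  }
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  if (min(expected) < 5) {
    warning("chi-square approximation: expected cell count below 5")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p_value = unname(ht$p.value), status = "ok",
    min_expected = min(expected)
  )
}

#' Five-year survival percentage per category
#'
#' Crude percentages: 100 x known five-year survivors over records with a
#' known five-year outcome in each category. Categories with no known
#' outcome report `NA`.
#'
#' @param cohort a `cohort_table`.
#' @param attribute name of a categorical cohort column.
#' @return data frame with `category`, `n` (records with known outcome),
#'   `survivors`, and `pct` (1-decimal display rounding).
#' @examples
#' coh <- discretize(generate_cohort(synthetic_config(n = 100), seed = 1))
#' survival_rate(coh, "op_group")
#' @export
survival_rate <- function(cohort, attribute) {
  if (!attribute %in% names(cohort)) stop("unknown attribute: ", attribute)
  a <- as.character(cohort[[attribute]])
  s <- cohort$five_year_survivor
  keep <- !is.na(a) & a != ""
  a <- a[keep]
  s <- s[keep]
  cats <- sort(unique(a))
  n <- vapply(cats, function(cc) sum(a == cc & !is.na(s)), integer(1))
  surv <- vapply(cats, function(cc) sum(a == cc & s %in% TRUE), integer(1))
  pct <- ifelse(n > 0, round_half_up(100 * surv / n, 1), NA_real_)
  data.frame(category = cats, n = n, survivors = surv, pct = pct,
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Build a full univariate summary table
#'
#' For each listed attribute: per-category totals and survival-stratum
#' counts, the chi-square P value for the attribute-by->36-months table,
#' crude five-year survival percentages, and the chi-square P value for
#' the attribute-by-five-year table.
#'
#' @param cohort a `cohort_table`.
#' @param attributes attribute names; defaults to the full discretized set.
#' @return data frame, one row per attribute category, with columns
#'   `attribute`, `category`, `total`, `gt36`, `le36`, `p_gt36`,
#'   `five_year_pct`, `p_five_year` (P values repeated on each category
#'   row of their attribute).
#' @export
univariate_table <- function(cohort,
                             attributes = c(
                               "age_group", "primary_site", "laterality",
                               "grade", "nodes_group", "clinical_stage_group",
                               "pathologic_stage_group", "clinical_size_group",
                               "pathology_size_group", "op_group"
                             )) {
  out <- list()
  for (att in attributes) {
    ct <- suppressMessages(contingency(cohort, att, "survived_gt36"))
    p1 <- chi_square(ct)$p_value
    ct5 <- suppressMessages(contingency(cohort, att, "five_year_survivor"))
    p5 <- chi_square(ct5)$p_value
    sr <- survival_rate(cohort, att)
    cats <- rownames(ct$table)
    out[[att]] <- data.frame(
      attribute = att, category = cats,
      total = rowSums(ct$table),
      gt36 = ct$table[, "gt36"], le36 = ct$table[, "le36"],
      p_gt36 = p1,
      five_year_pct = sr$pct[match(cats, sr$category)],
      p_five_year = p5,
      row.names = NULL, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
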