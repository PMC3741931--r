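# Association-rule generation and interestingness metrics.

# all non-empty proper subsets of a set of positions (as index vectors)
.proper_subsets <- function(k) {
  out <- list()
  for (mask in seq_len(2^k - 2)) {
    out[[mask]] <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
  }
  out
}

#' Interestingness metrics for an association rule
#'
#' For a rule X => Y counted in a population of `N` transactions, with
#' `n_body` transactions containing X, `n_head` containing Y, and
#' `n_joint` containing both:
#'
#' * confidence = `n_joint / n_body` (the conditional frequency of Y
#'   given X);
#' * support = `n_joint / N`;
#' * lift = confidence / (`n_head / N`): 1 under independence, above 1
#'   when X and Y co-occur more than chance;
#' * leverage = `n_joint/N - (n_body/N)(n_head/N)`: the excess joint
#'   frequency over the independence product, 0 under independence;
#' * conviction = Pr(X) Pr(not Y) / Pr(X, not Y). In counts the standard
#'   form is `n_body (N - n_head) / (N (n_body - n_joint))`, infinite for
#'   exception-free rules; the Laplace-corrected variant adds one
#'   pseudo-count of exceptions, `n_body (N - n_head) /
#'   (N (n_body - n_joint + 1))`, and is always finite. The Laplace
#'   variant is the default (it is what rule-mining toolkits such as Weka
#'   report, and what published clinical rule tables typically contain).
#'
#' All arguments are vectorized.
#'
#' @param n_body,n_head,n_joint,N rule counts; `0 < n_body`,
#'   `0 < n_head`, `0 <= n_joint <= min(n_body, n_head) <= N`.
#' @param conviction_variant `"laplace"` (default) or `"standard"`.
#' @return data frame with columns `confidence`, `support`, `lift`,
#'   `leverage`, `conviction` (unrounded).
#' @examples
#' rule_metrics(49, 78, 27, 271)
#' rule_metrics(49, 78, 27, 271, conviction_variant = "standard")
#' @export
rule_metrics <- function(n_body, n_head, n_joint, N,
                         conviction_variant = c("laplace", "standard")) {
  conviction_variant <- match.arg(conviction_variant)
  if (any(n_body <= 0)) stop("undefined rule: n_body must be positive")
  if (any(n_head <= 0)) stop("undefined rule: n_head must be positive")
  if (any(n_joint < 0 | n_joint > pmin(n_body, n_head)) ||
      any(pmax(n_body, n_head) > N) ||
      any(n_joint < n_body + n_head - N)) { # inclusion-exclusion
    stop("inconsistent rule counts")
  }
  confidence <- n_joint / n_body
  support <- n_joint / N
  # symmetric form: equals confidence / (n_head / N) algebraically, and
  # makes lift(X => Y) and lift(Y => X) identical in floating point too
  lift <- (n_joint * N) / (n_body * n_head)
  leverage <- n_joint / N - (n_body / N) * (n_head / N)
  conviction <- if (conviction_variant == "laplace") {
    (n_body * (N - n_head)) / (N * (n_body - n_joint + 1))
  } else {
    ifelse(n_body == n_joint, Inf,
      (n_body * (N - n_head)) / (N * (n_body - n_joint)))
  }
  data.frame(confidence = confidence, support = support, lift = lift,
    leverage = leverage, conviction = conviction)
}

#' Generate association rules from mined large itemsets
#'
#' Every large itemset of size >= 2 is split into a non-empty body X and
#' head Y = complement. In `"free"` mode all `2^k - 2` ordered partitions
#' are emitted; in class-constrained mode only rules whose head is the
#' single item of the named class attribute. Body and head counts are
#' exact population counts, read from the mined table (every subset of a
#' large itemset is itself large).
#'
#' @param levels a `large_itemsets` object from [mine_frequent()].
#' @param db the [transaction_db()] the itemsets were mined from.
#' @param head_mode `"free"` (default) or `"class"`.
#' @param class_attribute attribute name whose single item must form the
#'   head when `head_mode = "class"`.
#' @param conviction_variant passed to [rule_metrics()].
#' @return data frame of class `rule_set`: one row per rule with `body`,
#'   `head` (item labels joined by `" & "`), `n_body`, `n_head`,
#'   `n_joint`, `N` and the five metric columns.
#' @examples
#' db <- build_table2_fixture()
#' L <- mine_frequent(db, min_support = 0.09)
#' rules <- generate_rules(L, db)
#' nrow(rules)
#' @export
generate_rules <- function(levels, db,
                           head_mode = c("free", "class"),
                           class_attribute = NULL,
                           conviction_variant = c("laplace", "standard")) {
  head_mode <- match.arg(head_mode)
  conviction_variant <- match.arg(conviction_variant)
  stopifnot(inherits(levels, "large_itemsets"), inherits(db, "transaction_db"))
  if (head_mode == "class") {
    if (is.null(class_attribute)) stop("class_attribute required in class mode")
    if (!any(startsWith(db$items, paste0(class_attribute, "=")))) {
      stop("class attribute not in vocabulary: ", class_attribute)
    }
  }

  # count index over all mined itemsets
  cnt <- new.env(parent = emptyenv())
  for (lev in levels$levels) {
    for (i in seq_along(lev$sets)) {
      cnt[[.iset_key(lev$sets[[i]])]] <- lev$counts[i]
    }
  }
  lookup <- function(ids) cnt[[.iset_key(ids)]]

  rows <- list()
  ks <- as.integer(names(levels$levels))
  for (k in ks[ks >= 2]) {
    lev <- levels$levels[[as.character(k)]]
    subsets <- .proper_subsets(k)
    for (i in seq_along(lev$sets)) {
      full <- lev$sets[[i]]
      n_joint <- lev$counts[i]
      for (body_pos in subsets) {
        body <- full[body_pos]
        head <- full[-body_pos]
        if (head_mode == "class") {
          if (length(head) != 1) next
          if (!startsWith(db$items[head], paste0(class_attribute, "="))) next
        }
        rows[[length(rows) + 1L]] <- list(
          body_ids = body, head_ids = head,
          n_body = lookup(body), n_head = lookup(head), n_joint = n_joint
        )
      }
    }
  }
  if (length(rows) == 0) {
    out <- data.frame(
      body = character(0), head = character(0),
      n_body = integer(0), n_head = integer(0), n_joint = integer(0),
      N = integer(0), confidence = numeric(0), support = numeric(0),
      lift = numeric(0), leverage = numeric(0), conviction = numeric(0)
    )
    class(out) <- c("rule_set", "data.frame")
    return(out)
  }
  n_body <- vapply(rows, `[[`, numeric(1), "n_body")
  n_head <- vapply(rows, `[[`, numeric(1), "n_head")
  n_joint <- vapply(rows, `[[`, numeric(1), "n_joint")
  met <- rule_metrics(n_body, n_head, n_joint, db$N, conviction_variant)
  out <- data.frame(
    body = vapply(rows, function(r) paste(db$items[r$body_ids], collapse = " & "),
      character(1)),
    head = vapply(rows, function(r) paste(db$items[r$head_ids], collapse = " & "),
      character(1)),
    n_body = as.integer(n_body), n_head = as.integer(n_head),
    n_joint = as.integer(n_joint), N = db$N,
    met,
    stringsAsFactors = FALSE
  )
  class(out) <- c("rule_set", "data.frame")
  out
}

#' Rank rules into a report
#'
#' Keeps rules with lift strictly above `min_lift`, sorts by the chosen
#' metric (descending; ties broken by confidence descending, then by body
#' label), truncates to `top_k`, and adds 2-decimal display columns
#' (half-away-from-zero rounding).
#'
#' @param rules a `rule_set` from [generate_rules()].
#' @param sort_metric one of `"lift"`, `"confidence"`, `"leverage"`,
#'   `"conviction"`.
#' @param min_lift strict lower bound on lift; rules at or below it are
#'   dropped.
#' @param top_k maximum number of reported rules.
#' @return data frame of class `rule_report`; unrounded metric columns
#'   retained alongside `*_2dp` display columns.
#' @examples
#' db <- build_table2_fixture()
#' L <- mine_frequent(db, min_support = 0.09)
#' rank_rules(generate_rules(L, db))
#' @export
rank_rules <- function(rules,
                       sort_metric = c("lift", "confidence", "leverage", "conviction"),
                       min_lift = 1.5, top_k = 10L) {
  sort_metric <- match.arg(sort_metric)
  keep <- rules[rules$lift > min_lift, , drop = FALSE]
  if (nrow(keep) > 0) {
    o <- order(-keep[[sort_metric]], -keep$confidence, keep$body)
    keep <- keep[o, , drop = FALSE]
    if (nrow(keep) > top_k) keep <- keep[seq_len(top_k), , drop = FALSE]
  }
  rownames(keep) <- NULL
  for (col in c("confidence", "lift", "leverage", "conviction")) {
    keep[[paste0(col, "_2dp")]] <- round_half_up(keep[[col]], 2)
  }
  attr(keep, "sort_metric") <- sort_metric
  attr(keep, "min_lift") <- min_lift
  attr(keep, "top_k") <- top_k
  class(keep) <- c("rule_report", "data.frame")
  keep
}

#' @export
print.rule_report <- function(x, ...) {
  cat("rule_report: ", nrow(x), " rule(s), sorted by ",
    attr(x, "sort_metric"), " (lift > ", attr(x, "min_lift"), ")\n", sep = "")
  if (nrow(x) > 0) {
    show <- data.frame(
      body = x$body, n_body = x$n_body, head = x$head, n_joint = x$n_joint,
      confidence = x$confidence_2dp, lift = x$lift_2dp,
      leverage = x$leverage_2dp, conviction = x$conviction_2dp
    )
    print.data.frame(show, row.names = TRUE)
  }
  invisible(x)
}

#' Write a rule report as tab-separated text
#'
#' Mirrors the eight-column layout (body, body count, head, joint count,
#' confidence, lift, leverage, conviction) with run metadata as leading
#' comment lines.
#'
#' @param report a `rule_report`.
#' @param path output path.
#' @param N population size to record in the header (optional).
#' @return `path`, invisibly.
#' @export
write_rule_report <- function(report, path, N = NULL) {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf(
    "# clinrules report: sort=%s min_lift=%s top_k=%s%s",
    attr(report, "sort_metric"), attr(report, "min_lift"),
    attr(report, "top_k"),
    if (is.null(N)) "" else sprintf(" N=%d", N)
  ), con)
  tab <- data.frame(
    body = report$body, n_body = report$n_body,
    head = report$head, n_joint = report$n_joint,
    confidence = report$confidence_2dp, lift = report$lift_2dp,
    leverage = report$leverage_2dp, conviction = report$conviction_2dp
  )
  utils::write.table(tab, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
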