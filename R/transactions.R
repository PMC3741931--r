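#' Construct a transaction database
#'
#' A transaction database holds one item-id set per patient plus the item
#' vocabulary. Item ids are assigned in lexicographic order of the item
#' strings, so id assignment is stable across runs for the same items.
#'
#' @param transactions list of character vectors, each a set of item
#'   strings (e.g. `"grade=02"`).
#' @return object of class `transaction_db` with fields `transactions`
#'   (list of strictly increasing integer-id vectors), `items` (id ->
#'   string vocabulary), `N` (number of transactions) and `m` (vocabulary
#'   size).
#' @examples
#' db <- transaction_db(list(c("a=1", "b=1"), "a=1"))
#' db$N
#' @export
transaction_db <- function(transactions) {
  stopifnot(is.list(transactions))
  vocab <- sort(unique(unlist(transactions, use.names = FALSE)))
  tx <- lapply(transactions, function(t) {
    sort(match(unique(t), vocab))
  })
  structure(
    list(transactions = tx, items = vocab, N = length(tx), m = length(vocab)),
    class = "transaction_db"
  )
}

#' @export
print.transaction_db <- function(x, ...) {
  cat("transaction_db: ", x$N, " transactions over ", x$m, " items\n", sep = "")
  invisible(x)
}

#' Encode a cohort table as transactions
#'
#' Each retained record becomes one transaction of `attribute=value` items
#' over the selected attributes. Records missing any selected attribute are
#' dropped listwise (the count is reported); no imputation is performed.
#'
#' @param cohort a `cohort_table` from [discretize()].
#' @param attributes non-empty character vector of cohort attribute names;
#'   the default is the four-attribute analysis set used for rule mining.
#' @return a [transaction_db()] with `N` = number of retained records.
#' @examples
#' coh <- discretize(generate_cohort(synthetic_config(n = 60), seed = 1))
#' encode_transactions(coh, c("grade", "group"))
#' @export
encode_transactions <- function(cohort,
                                attributes = c(
                                  "grade", "clinical_stage_group",
                                  "primary_site", "group"
                                )) {
  if (length(attributes) == 0) stop("attribute list must be non-empty")
  absent <- setdiff(attributes, names(cohort))
  if (length(absent) > 0) stop("unknown attribute(s): ", paste(absent, collapse = ", "))

  cols <- lapply(attributes, function(a) as.character(cohort[[a]]))
  complete <- Reduce(`&`, lapply(cols, function(v) !is.na(v) & v != ""))
  if (length(complete) == 0) complete <- logical(0)
  n_drop <- sum(!complete)
  if (n_drop > 0) {
    .msg(n_drop, " record(s) dropped for missing values on selected attributes")
  }
  idx <- which(complete)
  tx <- lapply(idx, function(i) {
    vapply(seq_along(attributes),
      function(j) paste0(attributes[j], "=", cols[[j]][i]), character(1))
  })
  transaction_db(tx)
}

# decode integer ids to item strings
.items_of <- function(db, ids) db$items[ids]
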