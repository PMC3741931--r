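#' Planted-rule recovery experiment
#'
#' Validates the full pipeline on synthetic cohorts: a known association
#' is planted among the >36-month survivors, the stratum is mined, and
#' the experiment measures how often the planted association tops the
#' lift ranking. A seed counts as recovered when both of the top-2
#' lift-ranked rules are generated by the planted association, i.e. each
#' rule's body and head together contain every planted item. (Rules whose
#' itemset strictly contains the planted one -- the planted pair plus an
#' independent attribute -- have the same expected lift as the pair's own
#' partitions, so containment, not exact identity, is the consistent
#' recovery criterion.)
#'
#' @param n cohort size in the mined (>36-month) stratum; the generated
#'   cohort is scaled so its >36 stratum has `n` patients.
#' @param boost planted joint-frequency factor; the planted rule's
#'   population lift equals `boost`.
#' @param seeds number of independent replicates.
#' @param planted_itemset named character vector of planted
#'   `attribute = value` pairs (default grade 02 with tongue).
#' @param attributes attributes to mine over.
#' @param min_support,min_lift mining parameters.
#' @param base_seed seed offset; replicate i uses `base_seed + i`.
#' @return list with `recovery` (fraction of recovered seeds), `n_rules`
#'   (mean number of reported rules) and `planted_lift` (mean mined lift
#'   of the planted pair rule, `NA` when never reported).
#' @examples
#' \donttest{
#' recovery_experiment(n = 271, boost = 1.9, seeds = 20)$recovery
#' }
#' @export
recovery_experiment <- function(n = 271L, boost = 1.9, seeds = 200L,
                                planted_itemset = c(grade = "02", primary_site = "tongue"),
                                attributes = c(
                                  "grade", "clinical_stage_group",
                                  "primary_site", "group"
                                ),
                                min_support = 0.09, min_lift = 1.5,
                                base_seed = 20000L) {
  total <- as.integer(round(n * 493 / 271))
  cfg <- synthetic_config(
    n = total, n_gt36 = as.integer(n),
    planted_itemset = planted_itemset, planted_boost = boost
  )
  planted_items <- paste0(names(planted_itemset), "=", unname(planted_itemset))
  hits <- logical(seeds)
  lifts <- rep(NA_real_, seeds)
  rule_counts <- integer(seeds)
  for (i in seq_len(seeds)) {
    rec <- generate_cohort(cfg, seed = base_seed + i)
    coh <- discretize(rec)
    pop <- suppressMessages(filter_population(coh, "survived_gt36"))
    db <- suppressMessages(encode_transactions(pop, attributes))
    L <- mine_frequent(db, min_support)
    rules <- generate_rules(L, db)
    rep_ <- rank_rules(rules, "lift", min_lift = min_lift, top_k = 10L)
    rule_counts[i] <- nrow(rep_)
    if (nrow(rep_) >= 2) {
      covered <- vapply(seq_len(2), function(r) {
        items <- unlist(strsplit(c(rep_$body[r], rep_$head[r]), " & ", fixed = TRUE))
        all(planted_items %in% items)
      }, logical(1))
      hits[i] <- all(covered)
    }
    pair <- rules$body == planted_items[1] & rules$head == planted_items[2]
    if (any(pair)) lifts[i] <- rules$lift[which(pair)[1]]
  }
  list(
    recovery = mean(hits),
    n_rules = mean(rule_counts),
    planted_lift = if (all(is.na(lifts))) NA_real_ else mean(lifts, na.rm = TRUE)
  )
}
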